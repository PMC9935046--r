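#' Virtual infarct configuration
#'
#' A figure-of-eight VT substrate in UVC space: two transmural inexcitable
#' scar lobes framing a narrow slow-conduction isthmus corridor. The
#' corridor runs apicobasally through the isthmus center; the lobes sit on
#' either rotational side of it.
#'
#' @param center_uvc UVC point of the isthmus center.
#' @param lobe_half_extent Numeric `c(dz, dphi)`: half-extents of each lobe
#'   in z (dimensionless) and phi (radians). Default `c(0.12, 0.25)`.
#' @param isthmus_half_width Rotational half-width of the corridor
#'   (radians). Default 0.08.
#' @param isthmus_cv_multiplier Velocity multiplier inside the corridor,
#'   in (0, 1). Default 0.25.
#' @param transmural Scar spans the full wall. Default `TRUE`.
#' @param seed Integer seed (placement jitter, exit-side choice).
#' @param aha_segment AHA segment (1..16) of the center.
#' @return A `scar_config`.
#' @export
scar_config <- function(center_uvc, lobe_half_extent = c(0.12, 0.25),
                        isthmus_half_width = 0.08,
                        isthmus_cv_multiplier = 0.25,
                        transmural = TRUE, seed = 0L, aha_segment = NA_integer_) {
  stopifnot(isthmus_cv_multiplier > 0, isthmus_cv_multiplier < 1,
            isthmus_half_width > 0, length(lobe_half_extent) == 2,
            all(lobe_half_extent > 0))
  structure(list(center_uvc = center_uvc,
                 lobe_half_extent = lobe_half_extent,
                 isthmus_half_width = isthmus_half_width,
                 isthmus_cv_multiplier = isthmus_cv_multiplier,
                 transmural = transmural, seed = as.integer(seed),
                 aha_segment = as.integer(aha_segment)),
            class = "scar_config")
}

# classify (z, phi) pairs against a scar: 0 = remote, 1 = lobe, 2 = corridor
substrate_class <- function(z, phi, scar) {
  zc <- scar$center_uvc[["z"]]
  pc <- scar$center_uvc[["phi"]]
  dz <- scar$lobe_half_extent[1]
  dphi <- scar$lobe_half_extent[2]
  w <- scar$isthmus_half_width
  dp <- abs(wrap_angle(phi - pc))
  in_z <- abs(z - zc) <= dz
  cls <- integer(length(z))
  cls[in_z & dp <= w] <- 2L
  cls[in_z & dp > w & dp <= w + 2 * dphi] <- 1L
  cls
}

# per-element and per-node substrate classification on a mesh
substrate_masks <- function(mesh, uvc_field, scar) {
  cent <- element_centroids(mesh)
  g <- mesh$geom
  apex_z <- mesh$nodes[mesh$apex_node, 3]
  ez <- pmin(1, pmax(0, (cent[, 3] - apex_z) / (g$z_base - apex_z)))
  ref <- atan2(mesh$septal_ref_dir[2], mesh$septal_ref_dir[1])
  ephi <- wrap_angle(atan2(cent[, 2], cent[, 1]) - ref)
  list(
    elem = substrate_class(ez, ephi, scar),
    node = substrate_class(uvc_field[, "z"], uvc_field[, "phi"], scar)
  )
}

#' Generate a virtual infarct centered in an AHA segment
#'
#' Places the isthmus center at the segment's (z, phi) centroid with a
#' small seeded jitter (kept inside the segment), and frames it with two
#' transmural scar lobes on either rotational side.
#'
#' @param mesh A `ventricular_mesh`.
#' @param uvc_field Its [compute_uvc()] field.
#' @param aha_segment Target segment, 1..16 (the apex cap is excluded).
#' @param seed Integer seed.
#' @param ... Overrides passed to [scar_config()] (extents, multiplier).
#' @return A `scar_config` whose lobes each cover at least 20 mesh nodes.
#' @export
generate_substrate <- function(mesh, uvc_field, aha_segment, seed = 0L, ...) {
  stopifnot(aha_segment %in% 1:16)
  cen <- aha_segment_centroid(aha_segment)
  rs <- local_rng(derive_seed(seed, "substrate", aha_segment))
  for (shrink in c(1, 0.5, 0.25, 0)) {
    jit_z <- rs$runif(1, -0.03, 0.03) * shrink
    jit_p <- rs$runif(1, -0.05, 0.05) * shrink
    z0 <- min(0.95, max(0.25, cen[["z"]] + jit_z))
    p0 <- wrap_angle(cen[["phi"]] + jit_p)
    if (aha_segment_of(z0, p0) == aha_segment) break
  }
  scar <- scar_config(center_uvc = uvc_point(z0, 0.5, p0), seed = seed,
                      aha_segment = aha_segment, ...)
  msk <- substrate_masks(mesh, uvc_field, scar)
  zc <- scar$center_uvc[["z"]]; pc <- scar$center_uvc[["phi"]]
  side_of <- sign(wrap_angle(uvc_field[, "phi"] - pc))
  n_lobe1 <- sum(msk$node == 1L & side_of > 0)
  n_lobe2 <- sum(msk$node == 1L & side_of < 0)
  if (min(n_lobe1, n_lobe2) < 20) {
    stop(sprintf("unresolvable substrate: lobes cover %d/%d nodes (< 20)",
                 n_lobe1, n_lobe2))
  }
  scar
}

#' Apply a scar to a conduction model
#'
#' Returns a new conduction model whose element multipliers are 0 inside
#' the scar lobes, `isthmus_cv_multiplier` inside the corridor and
#' unchanged elsewhere. Pure function: the input model is not modified.
#'
#' @param cm A [conduction_model()].
#' @param mesh A `ventricular_mesh`.
#' @param uvc_field Its UVC field.
#' @param scar A `scar_config`.
#' @return A new `conduction_model`.
#' @export
apply_substrate <- function(cm, mesh, uvc_field, scar) {
  msk <- substrate_masks(mesh, uvc_field, scar)
  mult <- elem_multipliers(cm, nrow(mesh$elements))
  mult[msk$elem == 1L] <- 0
  mult[msk$elem == 2L] <- mult[msk$elem == 2L] * scar$isthmus_cv_multiplier
  conduction_model(cm$cv_long, cm$cv_trans, mult)
}

# excitable corridor-mouth node nearest the corridor axis on one z side
corridor_mouth_node <- function(mesh, uvc_field, cm_scarred, scar, side,
                                band = 0.1) {
  zc <- scar$center_uvc[["z"]]; pc <- scar$center_uvc[["phi"]]
  dz <- scar$lobe_half_extent[1]
  w <- scar$isthmus_half_width
  zlo <- if (side > 0) zc + dz else zc - dz - band
  zhi <- if (side > 0) zc + dz + band else zc - dz
  dp <- abs(wrap_angle(uvc_field[, "phi"] - pc))
  cand <- which(uvc_field[, "z"] > zlo & uvc_field[, "z"] <= zhi & dp <= w)
  if (!length(cand)) return(NA_integer_)
  mult <- elem_multipliers(cm_scarred, nrow(mesh$elements))
  ok <- vapply(cand, function(k) source_excitable(mesh, cm_scarred, k), logical(1))
  cand <- cand[ok]
  if (!length(cand)) return(NA_integer_)
  target_z <- if (side > 0) zc + dz else zc - dz
  d2 <- (uvc_field[cand, "z"] - target_z)^2 +
    (wrap_angle(uvc_field[cand, "phi"] - pc) / pi)^2
  cand[which.min(d2)]
}

# shortest arrival between two nodes on an edge-filtered conduction graph;
# keep = node predicate (logical per node) that both edge endpoints must pass
restricted_path_time <- function(mesh, cm, from, to, keep) {
  ed <- conduction_edges(mesh, cm)
  sel <- keep[ed$a] & keep[ed$b]
  g <- igraph::make_empty_graph(n = ed$n_nodes, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ed$a[sel], ed$b[sel]))
  igraph::E(g)$weight <- ed$weight[sel]
  as.numeric(igraph::distances(g, v = from, to = to))
}

#' Build one figure-of-eight VT episode
#'
#' Selects the exit site as the excitable node at one corridor mouth
#' (side chosen by the scar's seed), simulates the systolic activation of
#' one VT beat as an eikonal solve from the exit on the scarred
#' substrate, and reports the circuit cycle length as metadata: the
#' through-corridor exit-to-entrance path time plus the return path
#' around the scar.
#'
#' @param mesh A `ventricular_mesh`.
#' @param uvc_field Its UVC field.
#' @param cm Baseline [conduction_model()].
#' @param scar A `scar_config`.
#' @return A `vt_episode`: substrate, `exit_node`, `exit_uvc`, `exit_xyz`,
#'   `cycle_length` (ms), `activation` map, `entrance_node`.
#' @export
make_vt_episode <- function(mesh, uvc_field, cm, scar) {
  scarred <- apply_substrate(cm, mesh, uvc_field, scar)
  rs <- local_rng(derive_seed(scar$seed, "exit-side", scar$aha_segment))
  side <- if (rs$runif(1) < 0.5) 1 else -1
  exit_node <- corridor_mouth_node(mesh, uvc_field, scarred, scar, side)
  entrance_node <- corridor_mouth_node(mesh, uvc_field, scarred, scar, -side)
  if (is.na(exit_node) || is.na(entrance_node)) {
    stop("non-viable circuit: corridor mouth not resolvable")
  }
  msk <- substrate_masks(mesh, uvc_field, scar)
  # through-corridor leg: only corridor and mouth-band nodes
  zc <- scar$center_uvc[["z"]]; pc <- scar$center_uvc[["phi"]]
  dz <- scar$lobe_half_extent[1]; w <- scar$isthmus_half_width
  dp <- abs(wrap_angle(uvc_field[, "phi"] - pc))
  in_corridor_zone <- dp <= w &
    abs(uvc_field[, "z"] - zc) <= dz + 0.1
  t_through <- restricted_path_time(mesh, scarred, exit_node, entrance_node,
                                    in_corridor_zone)
  # return leg: outside the corridor, around the scar
  t_return <- restricted_path_time(mesh, scarred, exit_node, entrance_node,
                                   msk$node != 2L)
  if (!is.finite(t_through) || !is.finite(t_return)) {
    stop("non-viable circuit: no exit-entrance path")
  }
  act <- solve_eikonal(mesh, scarred, exit_node)
  excit <- is.finite(act)
  stopifnot(which.min(replace(act, !excit, Inf)) == exit_node)
  structure(list(
    substrate = scar,
    exit_node = exit_node,
    entrance_node = entrance_node,
    exit_uvc = uvc_point(uvc_field[exit_node, "z"], uvc_field[exit_node, "rho"],
                         uvc_field[exit_node, "phi"]),
    exit_xyz = mesh$nodes[exit_node, ],
    cycle_length = t_through + t_return,
    activation = act,
    conduction = scarred
  ), class = "vt_episode")
}
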