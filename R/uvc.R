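#' Universal ventricular coordinates (UVC)
#'
#' Computes the (z, rho, phi) coordinate field on a ventricular mesh:
#' `z` the apicobasal coordinate (0 at the apex node, 1 on the base),
#' `rho` the transmural coordinate (0 endocardium, 1 epicardium) and
#' `phi` the rotational angle in (-pi, pi] measured about the long axis
#' from the septal reference direction, positive toward the anterior
#' wall. On the idealized ellipsoid the coordinates have closed forms:
#' the long-axis height fraction, the transmural layer fraction and the
#' azimuth. `phi` is degenerate (fixed to its azimuthal convention) for
#' nodes on the long axis.
#'
#' @param mesh A `ventricular_mesh` with surface labels.
#' @return A `uvc_field`: an n x 3 matrix with columns `z`, `rho`, `phi`.
#' @export
compute_uvc <- function(mesh) {
  stopifnot(inherits(mesh, "ventricular_mesh"))
  labs <- mesh$surface_labels
  if (!any(labs == "endocardium") || !any(labs == "base") ||
      !any(labs == "apex_node")) {
    stop("labelling error: mesh is missing apex/base/endo labels")
  }
  g <- mesh$geom
  apex_z <- mesh$nodes[mesh$apex_node, 3]
  z <- (mesh$nodes[, 3] - apex_z) / (g$z_base - apex_z)
  z <- pmin(1, pmax(0, z))
  z[mesh$apex_node] <- 0
  z[labs == "base"] <- 1
  rho <- pmin(1, pmax(0, mesh$node_depth))
  ref <- atan2(mesh$septal_ref_dir[2], mesh$septal_ref_dir[1])
  phi <- wrap_angle(atan2(mesh$nodes[, 2], mesh$nodes[, 1]) - ref)
  fld <- cbind(z = z, rho = rho, phi = phi)
  class(fld) <- c("uvc_field", class(fld))
  attr(fld, "anatomy_id") <- mesh$anatomy_id
  fld
}

#' Construct a single UVC point
#'
#' @param z Apicobasal coordinate in `[0, 1]`.
#' @param rho Transmural coordinate in `[0, 1]`.
#' @param phi Rotational coordinate, wrapped to `(-pi, pi]`.
#' @return Named numeric vector of length 3.
#' @export
uvc_point <- function(z, rho, phi) {
  stopifnot(is.finite(z), is.finite(rho), is.finite(phi),
            z >= 0, z <= 1, rho >= 0, rho <= 1)
  c(z = unname(z), rho = unname(rho), phi = unname(wrap_angle(phi)))
}

# accept a named (z, rho, phi) vector or plain positional triple
as_uvc_query <- function(q) {
  if (!is.null(names(q)) && all(c("z", "rho", "phi") %in% names(q))) {
    stats::setNames(as.numeric(q[c("z", "rho", "phi")]), c("z", "rho", "phi"))
  } else {
    stats::setNames(as.numeric(q)[1:3], c("z", "rho", "phi"))
  }
}

# squared UVC distance from one query to all rows of a field;
# weights w_z = w_rho = 1, w_phi = (1/pi)^2 so a half turn counts as 1
uvc_dist2 <- function(field, q) {
  dphi <- wrap_angle(field[, "phi"] - q[["phi"]])
  (field[, "z"] - q[["z"]])^2 + (field[, "rho"] - q[["rho"]])^2 +
    (dphi / pi)^2
}

#' Map a UVC point to the nearest mesh node's Cartesian position
#'
#' Returns the position of the mesh node minimizing the weighted UVC
#' distance `sqrt(dz^2 + drho^2 + (dphi/pi)^2)` with `dphi` wrapped to
#' `(-pi, pi]`. Ties break to the lowest node index.
#'
#' @param mesh A `ventricular_mesh`.
#' @param field Its `uvc_field` (from [compute_uvc()]).
#' @param q A UVC point ([uvc_point()] or any numeric with names
#'   `z`, `rho`, `phi`).
#' @return Numeric length-3 Cartesian position in mm, with attribute
#'   `node` giving the matched node index.
#' @export
uvc_to_point <- function(mesh, field, q) {
  stopifnot(inherits(mesh, "ventricular_mesh"), nrow(field) == nrow(mesh$nodes))
  if (nrow(field) == 0) stop("empty mesh")
  q <- as_uvc_query(q)
  k <- which.min(uvc_dist2(field, q))
  structure(mesh$nodes[k, ], node = k)
}

#' Assign the standard 17-segment AHA label from UVC coordinates
#'
#' Partition of the left ventricle by apicobasal level and rotational
#' sector: apex cap (z < 0.2) is segment 17; the apical ring
#' (0.2 <= z < 0.45) splits into 4 quadrants (13 anterior, 14 septal,
#' 15 inferior, 16 lateral); the mid (0.45 <= z < 0.7) and basal
#' (z >= 0.7) rings split into 6 sextants (anterior, anteroseptal,
#' inferoseptal, inferior, inferolateral, anterolateral). Sector
#' boundaries are fixed so that phi = 0 lies mid-anteroseptum and
#' positive phi runs toward the anterior wall.
#'
#' @param z,phi UVC coordinates (vectors allowed; recycled).
#' @return Integer segment labels in 1..17.
#' @export
aha_segment_of <- function(z, phi) {
  if (is.matrix(z) || (length(z) == 3 && !is.null(names(z)) &&
                       all(c("z", "phi") %in% names(z)))) {
    q <- z
    if (is.matrix(q)) { phi <- q[, "phi"]; z <- q[, "z"] }
    else { phi <- q[["phi"]]; z <- q[["z"]] }
  }
  if (any(!is.finite(z)) || any(!is.finite(phi)) || any(z < 0) || any(z > 1)) {
    stop("validation error: UVC out of range")
  }
  n <- max(length(z), length(phi))
  z <- rep_len(z, n); phi <- wrap_angle(rep_len(phi, n))
  seg <- integer(n)
  sextant <- function(ph) {
    # index 1..6 counterclockwise from the anteroseptal sector at phi = 0
    floor(wrap_angle(ph + pi / 6) %/% (pi / 3)) %% 6 + 1
  }
  quadrant <- function(ph) {
    floor(wrap_angle(ph + pi / 4) %/% (pi / 2)) %% 4 + 1
  }
  basal_tab <- c(2L, 1L, 6L, 5L, 4L, 3L)     # antsept, ant, antlat, inflat, inf, infsept
  mid_tab <- c(8L, 7L, 12L, 11L, 10L, 9L)
  apical_tab <- c(14L, 13L, 16L, 15L)        # septal, anterior, lateral, inferior
  apexc <- z < 0.2
  apical <- !apexc & z < 0.45
  mid <- !apexc & !apical & z < 0.7
  basal <- z >= 0.7
  seg[apexc] <- 17L
  seg[apical] <- apical_tab[quadrant(phi[apical])]
  seg[mid] <- mid_tab[sextant(phi[mid])]
  seg[basal] <- basal_tab[sextant(phi[basal])]
  seg
}

# ring level 1 = basal, 2 = mid, 3 = apical, 4 = apex cap
aha_ring_of <- function(segment) {
  stopifnot(all(segment %in% 1:17))
  ifelse(segment <= 6, 1L, ifelse(segment <= 12, 2L, ifelse(segment <= 16, 3L, 4L)))
}

# (z, phi) centroid of each AHA segment under the declared sector table
aha_segment_centroid <- function(segment) {
  stopifnot(segment %in% 1:16)
  if (segment <= 6) {
    z <- 0.85
    ord <- c(2L, 1L, 6L, 5L, 4L, 3L)
  } else if (segment <= 12) {
    z <- 0.575
    ord <- c(8L, 7L, 12L, 11L, 10L, 9L)
  } else {
    z <- 0.325
    ord <- c(14L, 13L, 16L, 15L)
  }
  k <- match(segment, ord)
  step <- if (segment <= 12) pi / 3 else pi / 2
  c(z = z, phi = wrap_angle((k - 1) * step))
}

#' Localization error between predicted and true sites
#'
#' Euclidean distance in mm between two Cartesian points.
#'
#' @param p_pred,p_true Numeric length-3 positions (mm).
#' @return Distance in mm.
#' @export
localization_error <- function(p_pred, p_true) {
  p_pred <- as.numeric(p_pred); p_true <- as.numeric(p_true)
  if (length(p_pred) != 3 || length(p_true) != 3 ||
      any(!is.finite(p_pred)) || any(!is.finite(p_true))) {
    stop("validation error: non-finite or non-3D input")
  }
  sqrt(sum((p_pred - p_true)^2))
}

#' Summary statistics of localization errors
#'
#' Mean, population standard deviation, minimum, maximum and count of a
#' set of per-case localization errors (mm).
#'
#' @param values Numeric vector of LE values (mm), all `>= 0`.
#' @return An `error_summary` list keeping the raw values.
#' @export
summarize_errors <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty input")
  stopifnot(all(is.finite(values)), all(values >= 0))
  n <- length(values)
  m <- mean(values)
  structure(list(
    values = values,
    mean = m,
    sd = sqrt(sum((values - m)^2) / n),
    min = min(values),
    max = max(values),
    n = n
  ), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("LE over %d cases: mean %.2f +/- %.2f mm, range %.2f - %.2f mm\n",
              x$n, x$mean, x$sd, x$min, x$max))
  invisible(x)
}
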