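#' Geometry parameters for the parametric ventricular mesh
#'
#' Bundles the dimensions of the idealized left ventricle: a truncated
#' prolate-ellipsoid thick wall, meshed with tetrahedra. The long axis is
#' the full apex-to-truncation-mirror length of the endocardial ellipsoid;
#' short axes and wall thickness are in mm. `truncation_fraction` is the
#' fraction of the full ellipsoid height retained (apex upward), so 0.7
#' keeps everything below 40% of the endocardial semi-long-axis above the
#' equator.
#'
#' @param lv_long_axis Endocardial long-axis length (mm). Default 90.
#' @param lv_endo_short_axis Endocardial short semi-axis (mm). Default 25.
#' @param wall_thickness Myocardial wall thickness (mm). Default 10.
#' @param truncation_fraction Retained fraction of ellipsoid height, in
#'   (0, 1). Default 0.7.
#' @param target_edge_length Target tetrahedral edge length (mm). Default 3.
#' @param fiber_angle_endo,fiber_angle_epi Helix angles (degrees) of the
#'   rule-based fiber field at the endocardium and epicardium. Defaults
#'   +60 / -60.
#' @param seed Integer seed controlling meshing jitter only.
#' @return A `geometry_params` list.
#' @export
geometry_params <- function(lv_long_axis = 90,
                            lv_endo_short_axis = 25,
                            wall_thickness = 10,
                            truncation_fraction = 0.7,
                            target_edge_length = 3,
                            fiber_angle_endo = 60,
                            fiber_angle_epi = -60,
                            seed = 1L) {
  p <- list(
    lv_long_axis = lv_long_axis,
    lv_endo_short_axis = lv_endo_short_axis,
    wall_thickness = wall_thickness,
    truncation_fraction = truncation_fraction,
    target_edge_length = target_edge_length,
    fiber_angle_endo = fiber_angle_endo,
    fiber_angle_epi = fiber_angle_epi,
    seed = as.integer(seed)
  )
  class(p) <- "geometry_params"
  validate_geometry_params(p)
  p
}

validate_geometry_params <- function(p) {
  stopifnot(
    p$lv_long_axis > 0, p$lv_endo_short_axis > 0, p$wall_thickness > 0,
    p$target_edge_length > 0,
    p$truncation_fraction > 0, p$truncation_fraction < 1
  )
  invisible(p)
}

#' Build a tetrahedral mesh of a truncated prolate-ellipsoid ventricle
#'
#' Constructs a structured thick-wall mesh between an endocardial and an
#' epicardial ellipsoid, truncated by a flat base plane, and splits the
#' structured cells into tetrahedra. Surfaces are labelled (`endocardium`,
#' `epicardium`, `base`, a unique `apex_node` at the epicardial tip) and a
#' rule-based fiber field is assigned. The epicardial apex sits at the
#' origin with the long axis along +z.
#'
#' The mesh is deterministic for fixed parameters; `seed` drives only a
#' small jitter of interior (non-surface) node positions.
#'
#' @param params A [geometry_params()] object.
#' @param anatomy_id Identifier string stored with the mesh.
#' @return A `ventricular_mesh` object: `nodes` (n x 3 mm), `elements`
#'   (m x 4, 1-based), `fiber_dirs` (m x 3 unit vectors), `surface_labels`
#'   (character per node), `apex_node`, `septal_ref_dir`, `anatomy_id`,
#'   plus cached parametric coordinates used by the coordinate module.
#' @export
build_ventricle_mesh <- function(params = geometry_params(), anatomy_id = "anat") {
  validate_geometry_params(params)
  a_endo <- params$lv_endo_short_axis
  c_endo <- params$lv_long_axis / 2
  w <- params$wall_thickness
  edge <- params$target_edge_length
  if (w >= a_endo) stop("self-intersecting wall: wall_thickness >= endo short axis")
  if (edge > w) stop("unresolvable wall: target_edge_length > wall_thickness")
  a_epi <- a_endo + w
  c_epi <- c_endo + w
  zc <- c_epi                       # ellipsoid centre height (epi apex at z = 0)
  z_base <- zc + c_endo * (2 * params$truncation_fraction - 1)

  # resolution of the structured grid
  n_d <- max(2L, round(w / edge))
  theta_max_endo <- acos(-(z_base - zc) / c_endo)
  arc <- 0.5 * (a_endo + c_endo) * theta_max_endo
  n_t <- max(4L, round(arc / edge))
  n_p <- max(8L, round(2 * pi * a_endo / edge))
  if (n_p %% 2L == 1L) n_p <- n_p + 1L  # even sector count for alternating tet split

  d_levels <- seq(0, 1, length.out = n_d + 1L)
  phi_levels <- seq(0, 2 * pi, length.out = n_p + 1L)[-(n_p + 1L)]

  # node table: for each layer, apex point + n_t rings of n_p nodes
  idx <- function(j, i, p) {
    # j layer 0..n_d, i ring 0..n_t (0 = apex point), p sector 0..n_p-1
    per_layer <- 1L + n_t * n_p
    base <- j * per_layer
    if (i == 0L) base + 1L else base + 1L + (i - 1L) * n_p + (p %% n_p) + 1L
  }
  n_nodes <- (n_d + 1L) * (1L + n_t * n_p)
  nodes <- matrix(0, n_nodes, 3)
  node_d <- numeric(n_nodes)   # transmural fraction
  node_t <- numeric(n_nodes)   # apicobasal grid fraction (0 apex ring .. 1 base)
  for (j in 0:n_d) {
    d <- d_levels[j + 1L]
    a_j <- a_endo + d * w
    c_j <- c_endo + d * w
    theta_max <- acos(min(1, max(-1, -(z_base - zc) / c_j)))
    k <- idx(j, 0L, 0L)
    nodes[k, ] <- c(0, 0, zc - c_j)
    node_d[k] <- d
    node_t[k] <- 0
    for (i in 1:n_t) {
      th <- theta_max * i / n_t
      r <- a_j * sin(th)
      z <- zc - c_j * cos(th)
      for (p in 0:(n_p - 1L)) {
        k <- idx(j, i, p)
        ph <- phi_levels[p + 1L]
        nodes[k, ] <- c(r * cos(ph), r * sin(ph), z)
        node_d[k] <- d
        node_t[k] <- i / n_t
      }
    }
  }

  # surface labels; priority apex > base > endo > epi > interior
  labels <- rep("interior", n_nodes)
  for (j in 0:n_d) {
    labels[idx(j, n_t, 0L):(idx(j, n_t, n_p - 1L))] <- "base"
  }
  for (i in 0:(n_t - 1L)) {
    if (i == 0L) {
      labels[idx(0L, 0L, 0L)] <- "endocardium"
      labels[idx(n_d, 0L, 0L)] <- "epicardium"
    } else {
      for (p in 0:(n_p - 1L)) {
        labels[idx(0L, i, p)] <- "endocardium"
        labels[idx(n_d, i, p)] <- "epicardium"
      }
    }
  }
  apex_node <- idx(n_d, 0L, 0L)
  labels[apex_node] <- "apex_node"

  # seeded jitter on interior nodes only
  interior <- which(labels == "interior" & node_t < 1 - 1e-12)
  if (length(interior)) {
    rs <- local_rng(params$seed)
    jit <- matrix(rs$runif(3L * length(interior), -0.05 * edge, 0.05 * edge),
                  ncol = 3)
    nodes[interior, ] <- nodes[interior, ] + jit
  }

  # cells: apex prisms (ring 0-1) then hexes (rings 1..n_t-1), split to tets
  elems <- vector("list", n_d * n_p * n_t)
  ne <- 0L
  prism_tets <- function(a1, a2, a3, b1, b2, b3) {
    list(c(a1, a2, a3, b1), c(a2, a3, b1, b2), c(a3, b1, b2, b3))
  }
  hex_tets <- function(v, parity) {
    # v = c(A,B,C,D,E,F,G,H): bottom ring A-D, top ring E-H (same winding)
    if (parity == 0L) {
      list(v[c(1, 2, 4, 5)], v[c(2, 3, 4, 7)], v[c(2, 5, 6, 7)],
           v[c(4, 5, 7, 8)], v[c(2, 4, 5, 7)])
    } else {
      list(v[c(2, 3, 1, 6)], v[c(3, 4, 1, 8)], v[c(3, 6, 7, 8)],
           v[c(1, 6, 8, 5)], v[c(3, 1, 6, 8)])
    }
  }
  for (j in 0:(n_d - 1L)) {
    for (p in 0:(n_p - 1L)) {
      tets <- prism_tets(idx(j, 0L, 0L), idx(j, 1L, p), idx(j, 1L, p + 1L),
                         idx(j + 1L, 0L, 0L), idx(j + 1L, 1L, p), idx(j + 1L, 1L, p + 1L))
      for (tt in tets) { ne <- ne + 1L; elems[[ne]] <- tt }
      for (i in 1:(n_t - 1L)) {
        v <- c(idx(j, i, p), idx(j, i + 1L, p), idx(j, i + 1L, p + 1L), idx(j, i, p + 1L),
               idx(j + 1L, i, p), idx(j + 1L, i + 1L, p), idx(j + 1L, i + 1L, p + 1L),
               idx(j + 1L, i, p + 1L))
        tets <- hex_tets(v, (i + p + j) %% 2L)
        for (tt in tets) { ne <- ne + 1L; elems[[ne]] <- tt }
      }
    }
  }
  elements <- do.call(rbind, elems[seq_len(ne)])
  storage.mode(elements) <- "integer"
  vol <- tet_volumes(nodes, elements)
  keep <- vol > 1e-9
  elements <- elements[keep, , drop = FALSE]
  apex_node <- as.integer(apex_node)

  mesh <- structure(list(
    nodes = nodes,
    elements = elements,
    fiber_dirs = NULL,
    surface_labels = labels,
    apex_node = apex_node,
    septal_ref_dir = c(-1, 0, 0),
    anatomy_id = anatomy_id,
    params = params,
    node_depth = node_d,
    node_tfrac = node_t,
    geom = list(a_endo = a_endo, c_endo = c_endo, a_epi = a_epi, c_epi = c_epi,
                zc = zc, z_base = z_base, n_d = n_d, n_t = n_t, n_p = n_p)
  ), class = "ventricular_mesh")
  mesh$fiber_dirs <- compute_fiber_field(mesh, params$fiber_angle_endo,
                                         params$fiber_angle_epi)
  mesh
}

#' @export
print.ventricular_mesh <- function(x, ...) {
  cat(sprintf("ventricular_mesh '%s': %d nodes, %d tetrahedra\n",
              x$anatomy_id, nrow(x$nodes), nrow(x$elements)))
  cat(sprintf("  endo %d / epi %d / base %d nodes; apex node %d\n",
              sum(x$surface_labels == "endocardium"),
              sum(x$surface_labels == "epicardium"),
              sum(x$surface_labels == "base"), x$apex_node))
  invisible(x)
}

# signed tet volumes (absolute value), vectorized over elements
tet_volumes <- function(nodes, elements) {
  p1 <- nodes[elements[, 1], , drop = FALSE]
  d2 <- nodes[elements[, 2], , drop = FALSE] - p1
  d3 <- nodes[elements[, 3], , drop = FALSE] - p1
  d4 <- nodes[elements[, 4], , drop = FALSE] - p1
  det <- d2[, 1] * (d3[, 2] * d4[, 3] - d3[, 3] * d4[, 2]) -
         d2[, 2] * (d3[, 1] * d4[, 3] - d3[, 3] * d4[, 1]) +
         d2[, 3] * (d3[, 1] * d4[, 2] - d3[, 2] * d4[, 1])
  abs(det) / 6
}

element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elements[, 1], ] + mesh$nodes[mesh$elements[, 2], ] +
   mesh$nodes[mesh$elements[, 3], ] + mesh$nodes[mesh$elements[, 4], ]) / 4
}

element_depths <- function(mesh) {
  (mesh$node_depth[mesh$elements[, 1]] + mesh$node_depth[mesh$elements[, 2]] +
   mesh$node_depth[mesh$elements[, 3]] + mesh$node_depth[mesh$elements[, 4]]) / 4
}

#' Analytic volume of the truncated ellipsoid shell
#'
#' Closed-form reference volume of the wall between the endocardial and
#' epicardial ellipsoids below the base plane, used as an oracle for the
#' meshed volume.
#'
#' @param params A [geometry_params()] object.
#' @return Volume in mm^3.
#' @export
analytic_shell_volume <- function(params) {
  a_endo <- params$lv_endo_short_axis
  c_endo <- params$lv_long_axis / 2
  w <- params$wall_thickness
  zc <- c_endo + w
  z_base <- zc + c_endo * (2 * params$truncation_fraction - 1)
  cap_vol <- function(a, c) {
    # volume of ellipsoid slice from z = zc - c to z_base
    zl <- -c
    zu <- z_base - zc
    pi * a^2 * ((zu - zu^3 / (3 * c^2)) - (zl - zl^3 / (3 * c^2)))
  }
  cap_vol(a_endo + w, c_endo + w) - cap_vol(a_endo, c_endo)
}

# local transmural (outward) axis at a set of points, from the ellipsoid
# family normal; horizontal circumferential direction z x n
local_frames <- function(mesh, pts, depths) {
  zc <- mesh$geom$zc
  a <- mesh$geom$a_endo + depths * mesh$params$wall_thickness
  cc <- mesh$geom$c_endo + depths * mesh$params$wall_thickness
  n <- cbind(2 * pts[, 1] / a^2, 2 * pts[, 2] / a^2, 2 * (pts[, 3] - zc) / cc^2)
  n <- n / sqrt(rowSums(n^2))
  circ <- cbind(-n[, 2], n[, 1], 0)           # z-hat cross n
  nrm <- sqrt(rowSums(circ^2))
  deg <- nrm < 1e-6
  if (any(deg)) {                             # apex cap: pick any horizontal dir
    circ[deg, ] <- matrix(rep(c(0, 1, 0), sum(deg)), ncol = 3, byrow = TRUE)
    nrm[deg] <- 1
  }
  circ <- circ / nrm
  # re-orthogonalize circ against n
  dp <- rowSums(circ * n)
  circ <- circ - dp * n
  circ <- circ / sqrt(rowSums(circ^2))
  list(transmural = n, circumferential = circ)
}

compute_fiber_field <- function(mesh, angle_endo, angle_epi) {
  cent <- element_centroids(mesh)
  dep <- pmin(1, pmax(0, element_depths(mesh)))
  fr <- local_frames(mesh, cent, dep)
  ang <- (angle_endo + dep * (angle_epi - angle_endo)) * pi / 180
  # Rodrigues rotation of circumferential about transmural axis
  n <- fr$transmural
  v <- fr$circumferential
  nxv <- cbind(n[, 2] * v[, 3] - n[, 3] * v[, 2],
               n[, 3] * v[, 1] - n[, 1] * v[, 3],
               n[, 1] * v[, 2] - n[, 2] * v[, 1])
  f <- v * cos(ang) + nxv * sin(ang)
  f / sqrt(rowSums(f^2))
}

#' Assign a rule-based transmural fiber field
#'
#' Rotates the local circumferential direction about the local transmural
#' axis by a helix angle interpolated linearly in normalized wall depth
#' from `angle_endo` (endocardium) to `angle_epi` (epicardium).
#'
#' @param mesh A `ventricular_mesh`.
#' @param angle_endo,angle_epi Helix angles in degrees.
#' @return The mesh with `fiber_dirs` replaced (one unit vector per element).
#' @export
assign_fibers <- function(mesh, angle_endo = 60, angle_epi = -60) {
  stopifnot(inherits(mesh, "ventricular_mesh"))
  if (!any(mesh$surface_labels == "endocardium") ||
      !any(mesh$surface_labels %in% c("epicardium", "apex_node"))) {
    stop("mesh lacks endo/epi surface labels")
  }
  dep <- element_depths(mesh)
  if (any(!is.finite(dep)) || any(dep < -1e-9) || any(dep > 1 + 1e-9)) {
    stop("element with undefined transmural depth (outside wall)")
  }
  mesh$fiber_dirs <- compute_fiber_field(mesh, angle_endo, angle_epi)
  mesh$params$fiber_angle_endo <- angle_endo
  mesh$params$fiber_angle_epi <- angle_epi
  mesh
}

electrode_set <- function(names, positions, kind) {
  stopifnot(!anyDuplicated(names), nrow(positions) == length(names),
            all(is.finite(positions)), kind %in% c("surface", "device"))
  rownames(positions) <- names
  structure(list(names = names, positions = positions, kind = kind),
            class = "electrode_set")
}

SURFACE_ELECTRODE_NAMES <- c("RA", "LA", "LL", paste0("V", 1:6))
DEVICE_ELECTRODE_NAMES <- c("CAN", "SVC_COIL", "RV_COIL", "RV_TIP", "RV_RING",
                            paste0("LV", 1:4))

# unit template directions on the virtual torso (anterior = +x, left = +y,
# superior = +z), scaled by torso_scale
surface_template <- function() {
  dirs <- rbind(
    RA = c(0.15, -0.70, 0.70),
    LA = c(0.15, 0.70, 0.70),
    LL = c(0.10, 0.50, -1.00),
    V1 = c(0.90, -0.25, -0.10),
    V2 = c(0.95, -0.05, -0.10),
    V3 = c(0.90, 0.15, -0.15),
    V4 = c(0.85, 0.35, -0.20),
    V5 = c(0.70, 0.55, -0.20),
    V6 = c(0.50, 0.75, -0.20)
  )
  dirs / sqrt(rowSums(dirs^2))
}

# TRUE for points strictly inside the myocardial wall (between the two
# ellipsoids and below the base plane); points on the surfaces — where
# device electrodes legitimately sit — are outside
inside_myocardium <- function(mesh, pts, tol = 1e-3) {
  g <- mesh$geom
  if (is.null(g)) return(rep(FALSE, nrow(pts)))  # imported/stub meshes
  lev <- function(a, c) (pts[, 1]^2 + pts[, 2]^2) / a^2 +
    (pts[, 3] - g$zc)^2 / c^2
  below <- pts[, 3] <= g$z_base - tol
  lev(g$a_epi, g$c_epi) < 1 - tol & lev(g$a_endo, g$c_endo) > 1 + tol & below
}

#' Place the 9 surface-ECG measurement electrodes
#'
#' Positions the limb electrodes RA, LA, LL and precordial V1..V6 at fixed
#' anatomical template directions scaled by `torso_scale` on a virtual
#' torso sphere around the ventricle (anterior = +x, left = +y,
#' superior = +z; the right-leg ground is not modelled).
#'
#' @param mesh A `ventricular_mesh`.
#' @param torso_scale Radius of the virtual torso (mm). Must exceed the
#'   maximal mesh radius.
#' @return An `electrode_set` of kind `"surface"`.
#' @export
place_surface_electrodes <- function(mesh, torso_scale = 120) {
  stopifnot(inherits(mesh, "ventricular_mesh"))
  rmax <- max(sqrt(rowSums(mesh$nodes^2)))
  if (torso_scale <= rmax) stop("placement error: torso_scale inside mesh radius")
  pos <- surface_template() * torso_scale
  if (any(inside_myocardium(mesh, pos))) {
    stop("placement error: electrode inside myocardium")
  }
  electrode_set(SURFACE_ELECTRODE_NAMES, pos, "surface")
}

# point on the layer-d ellipsoid surface at polar angle theta (from apex)
# and azimuth phi
shell_point <- function(mesh, d, theta, phi) {
  a <- mesh$geom$a_endo + d * mesh$params$wall_thickness
  cc <- mesh$geom$c_endo + d * mesh$params$wall_thickness
  c(a * sin(theta) * cos(phi), a * sin(theta) * sin(phi),
    mesh$geom$zc - cc * cos(theta))
}

#' Place the 9 implanted-device electrodes
#'
#' Places a generic implanted device: a left-pectoral active can, an
#' apical dual-coil RV lead (tip, ring, RV coil, SVC coil) on the septal
#' side, and a quadripolar LV lead (LV1..LV4, ~10 mm apart) on the
#' lateral epicardium. Placement is purely geometric and bit-reproducible
#' for a fixed mesh.
#'
#' @param mesh A `ventricular_mesh`.
#' @return An `electrode_set` of kind `"device"`.
#' @export
place_device_electrodes <- function(mesh) {
  stopifnot(inherits(mesh, "ventricular_mesh"))
  g <- mesh$geom
  w <- mesh$params$wall_thickness
  septal_phi <- atan2(mesh$septal_ref_dir[2], mesh$septal_ref_dir[1])
  lateral_phi <- septal_phi + pi
  rv_tip <- c(0, 0, w)                              # endocardial apex
  rv_ring <- shell_point(mesh, 0, 9 / g$c_endo, septal_phi)
  rv_coil <- c(0, 0, w + 0.45 * (g$z_base - w))     # intracavitary, on axis
  svc_coil <- c(0, -20, g$z_base + 25)
  can <- c(40, 70, g$z_base + 60)
  # LV quadripole: walk the lateral epicardial meridian in ~10 mm arc steps
  lv <- matrix(0, 4, 3)
  th <- 1.45
  for (k in 1:4) {
    lv[k, ] <- shell_point(mesh, 1, th, lateral_phi)
    m <- sqrt((g$a_epi * cos(th))^2 + (g$c_epi * sin(th))^2)  # meridian speed
    th <- th - 10 / m
  }
  pos <- rbind(can, svc_coil, rv_coil, rv_tip, rv_ring, lv)
  electrode_set(DEVICE_ELECTRODE_NAMES, pos, "device")
}

#' Export an electrode set as JSON
#'
#' @param electrodes An `electrode_set`.
#' @param path Output file path.
#' @export
write_electrodes_json <- function(electrodes, path) {
  lst <- lapply(seq_along(electrodes$names),
                function(i) unname(electrodes$positions[i, ]))
  names(lst) <- electrodes$names
  jsonlite::write_json(lst, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Perturb geometry parameters to emulate a cohort of anatomies
#'
#' Draws a "virtual patient" by perturbing the axes and wall thickness of
#' the default geometry by up to +/-10%, seeded. Used to stand in for a
#' cohort of image-derived anatomies.
#'
#' @param base A [geometry_params()] object.
#' @param seed Integer seed for the perturbation.
#' @return A new `geometry_params` object.
#' @export
perturb_geometry <- function(base = geometry_params(), seed = 1L) {
  rs <- local_rng(seed)
  f <- rs$runif(3L, 0.9, 1.1)
  geometry_params(
    lv_long_axis = base$lv_long_axis * f[1],
    lv_endo_short_axis = base$lv_endo_short_axis * f[2],
    wall_thickness = base$wall_thickness * f[3],
    truncation_fraction = base$truncation_fraction,
    target_edge_length = base$target_edge_length,
    fiber_angle_endo = base$fiber_angle_endo,
    fiber_angle_epi = base$fiber_angle_epi,
    seed = seed
  )
}
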