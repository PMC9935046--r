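#' Multichannel trace container
#'
#' Fixed-rate extracellular time traces (ECG leads or EGM vectors) for one
#' beat.
#'
#' @param channel_names Ordered channel names.
#' @param samples channels x time numeric matrix (mV).
#' @param dt Sample interval (ms).
#' @param beat_kind `"paced"` or `"vt"`.
#' @return A `trace_set`.
#' @export
trace_set <- function(channel_names, samples, dt = 1, beat_kind = "paced") {
  samples <- as.matrix(samples)
  stopifnot(length(channel_names) == nrow(samples), dt > 0,
            all(is.finite(samples)), beat_kind %in% c("paced", "vt"))
  rownames(samples) <- channel_names
  structure(list(channel_names = channel_names, samples = samples,
                 dt = dt, beat_kind = beat_kind), class = "trace_set")
}

# per-element linear shape-function gradient operators and volumes
element_gradients <- function(mesh) {
  el <- mesh$elements
  m <- nrow(el)
  p1 <- mesh$nodes[el[, 1], , drop = FALSE]
  e2 <- mesh$nodes[el[, 2], , drop = FALSE] - p1
  e3 <- mesh$nodes[el[, 3], , drop = FALSE] - p1
  e4 <- mesh$nodes[el[, 4], , drop = FALSE] - p1
  G <- vector("list", m)
  vol <- numeric(m)
  for (i in seq_len(m)) {
    M <- rbind(e2[i, ], e3[i, ], e4[i, ])
    deti <- det(M)
    vol[i] <- abs(deti) / 6
    gi <- solve(M)               # columns = gradients of shape fns 2..4
    G[[i]] <- cbind(-rowSums(gi), gi)
  }
  list(G = G, vol = vol, centroid = element_centroids(mesh))
}

#' Pseudo-ECG lead-field matrix for a set of electrodes
#'
#' Precomputes the linear operator `W` mapping per-node transmembrane
#' potentials to extracellular electrode potentials under the homogeneous
#' infinite-volume-conductor pseudo-ECG model:
#' `phi_e(x, t) = k * sum_el vol_el * grad(Vm)|_el . grad(1 / |x - c_el|)`,
#' with element-wise linear shape-function gradients and element
#' centroids `c_el`. Electrode potentials for any beat are then
#' `W %*% Vm`.
#'
#' @param mesh A `ventricular_mesh`.
#' @param electrodes An `electrode_set`; positions must lie strictly
#'   outside the myocardium.
#' @param gain Fixed gain constant `k` absorbing conductivity ratios.
#' @return electrodes x nodes matrix with electrode-name rownames.
#' @export
lead_field_matrix <- function(mesh, electrodes, gain = 1) {
  pos <- electrodes$positions
  if (any(inside_myocardium(mesh, pos))) {
    stop("singularity error: electrode inside the myocardium")
  }
  eg <- element_gradients(mesh)
  m <- nrow(mesh$elements)
  n <- nrow(mesh$nodes)
  # sparse stack of vol-weighted gradient operators: (3m x n)
  rows <- rep(3 * (seq_len(m) - 1), each = 12) + rep(1:3, times = 4 * m)
  cols <- rep(t(mesh$elements), each = 3)
  vals <- unlist(lapply(seq_len(m), function(i) as.numeric(eg$G[[i]] * eg$vol[i])))
  B <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(3 * m, n))
  W <- matrix(0, nrow(pos), n)
  for (e in seq_len(nrow(pos))) {
    dvec <- matrix(pos[e, ], m, 3, byrow = TRUE) - eg$centroid
    r <- sqrt(rowSums(dvec^2))
    if (any(r < 1e-9)) stop("singularity error: electrode on an element centroid")
    g <- dvec / r^3                       # grad_c (1/|x - c|)
    W[e, ] <- as.numeric(Matrix::crossprod(B, as.numeric(t(g))))
  }
  W <- gain * W
  rownames(W) <- electrodes$names
  W
}

#' Extracellular potentials at electrodes from transmembrane traces
#'
#' Applies the pseudo-ECG lead-field operator to a nodes x time matrix of
#' transmembrane potentials.
#'
#' @param mesh A `ventricular_mesh`.
#' @param vm_traces nodes x time matrix (mV), e.g. from
#'   [synthesize_vm_traces()].
#' @param electrodes An `electrode_set` outside the myocardium.
#' @param sigma_ratio Gain constant (conductivity ratio), default 1.
#' @param lf Optional precomputed [lead_field_matrix()] for these
#'   electrodes.
#' @return electrodes x time matrix of potentials.
#' @export
compute_electrode_potentials <- function(mesh, vm_traces, electrodes,
                                         sigma_ratio = 1, lf = NULL) {
  if (is.null(lf)) lf <- lead_field_matrix(mesh, electrodes, gain = sigma_ratio)
  lf %*% vm_traces
}

new_lead_definition <- function(name, coeffs) {
  if (abs(sum(coeffs)) > 1e-12) {
    stop(sprintf("lead '%s' is not reference-invariant (coefficients sum %g)",
                 name, sum(coeffs)))
  }
  list(name = name, coeffs = coeffs)
}

#' Definitions of the 16 ECG channels
#'
#' The standard 12 leads (limb, augmented, precordial with the Wilson
#' central terminal as reference) plus four derived vector combinations:
#' `X = V6 - V1` (approximate horizontal axis), `Y = aVF` (vertical),
#' `Z = V2 - (V6 + I)/2` (approximate anteroposterior axis) and
#' `M = V1 + V2 + V3 - V4 - V5 - V6` (precordial balance). Every channel
#' is a zero-sum combination of the 9 measurement electrodes, asserted at
#' construction.
#'
#' @return Named list of lead definitions (electrode-coefficient vectors).
#' @export
ecg_lead_definitions <- function() {
  e <- SURFACE_ELECTRODE_NAMES
  base <- function() stats::setNames(numeric(length(e)), e)
  lead <- function(...) {
    cf <- base()
    add <- list(...)
    for (nm in names(add)) cf[nm] <- cf[nm] + add[[nm]]
    cf
  }
  wct <- lead(RA = 1 / 3, LA = 1 / 3, LL = 1 / 3)
  defs <- list(
    I   = lead(LA = 1, RA = -1),
    II  = lead(LL = 1, RA = -1),
    III = lead(LL = 1, LA = -1),
    aVR = lead(RA = 1, LA = -0.5, LL = -0.5),
    aVL = lead(LA = 1, RA = -0.5, LL = -0.5),
    aVF = lead(LL = 1, RA = -0.5, LA = -0.5)
  )
  for (k in 1:6) {
    cf <- base()
    cf[paste0("V", k)] <- 1
    defs[[paste0("V", k)]] <- cf - wct
  }
  # derived vector combinations, composed algebraically from the above
  defs$X <- defs$V6 - defs$V1
  defs$Y <- defs$aVF
  defs$Z <- defs$V2 - (defs$V6 + defs$I) / 2
  defs$M <- defs$V1 + defs$V2 + defs$V3 - defs$V4 - defs$V5 - defs$V6
  Map(new_lead_definition, names(defs), defs)
}

#' Definitions of the 8 implanted-device EGM vectors
#'
#' Bipolar sensing vectors mixing near-field (RV tip-ring, LV bipoles)
#' and far-field (coil-can) combinations, using every device electrode:
#' RV_TIP-RV_RING, RV_COIL-CAN, SVC_COIL-CAN, RV_COIL-SVC_COIL, LV1-LV2,
#' LV2-LV3, LV3-LV4, LV4-CAN.
#'
#' @return Named list of lead definitions over the 9 device electrodes.
#' @export
egm_vector_definitions <- function() {
  e <- DEVICE_ELECTRODE_NAMES
  pairs <- list(
    c("RV_TIP", "RV_RING"), c("RV_COIL", "CAN"), c("SVC_COIL", "CAN"),
    c("RV_COIL", "SVC_COIL"), c("LV1", "LV2"), c("LV2", "LV3"),
    c("LV3", "LV4"), c("LV4", "CAN")
  )
  defs <- lapply(pairs, function(p) {
    cf <- stats::setNames(numeric(length(e)), e)
    cf[p[1]] <- 1; cf[p[2]] <- -1
    cf
  })
  names(defs) <- vapply(pairs, function(p) paste0(p[1], "-", p[2]), character(1))
  Map(new_lead_definition, names(defs), defs)
}

lead_matrix <- function(defs, electrode_names) {
  L <- t(vapply(defs, function(d) d$coeffs[electrode_names], numeric(length(electrode_names))))
  rownames(L) <- names(defs)
  L
}

#' Derive the 16 ECG channels from surface-electrode potentials
#'
#' @param electrode_potentials 9 x time matrix with surface electrode
#'   rownames (RA, LA, LL, V1..V6).
#' @param dt Sample interval (ms).
#' @param beat_kind `"paced"` or `"vt"`.
#' @return A 16-channel `trace_set` (I, II, III, aVR, aVL, aVF, V1..V6,
#'   X, Y, Z, M).
#' @export
derive_ecg_leads <- function(electrode_potentials, dt = 1, beat_kind = "paced") {
  if (!all(SURFACE_ELECTRODE_NAMES %in% rownames(electrode_potentials))) {
    stop("missing surface electrode(s)")
  }
  defs <- ecg_lead_definitions()
  L <- lead_matrix(defs, SURFACE_ELECTRODE_NAMES)
  samples <- L %*% electrode_potentials[SURFACE_ELECTRODE_NAMES, , drop = FALSE]
  trace_set(names(defs), samples, dt = dt, beat_kind = beat_kind)
}

#' Derive the 8 device EGM vectors from device-electrode potentials
#'
#' @param electrode_potentials 9 x time matrix with device electrode
#'   rownames (CAN, SVC_COIL, RV_COIL, RV_TIP, RV_RING, LV1..LV4).
#' @param dt Sample interval (ms).
#' @param beat_kind `"paced"` or `"vt"`.
#' @return An 8-channel `trace_set`.
#' @export
derive_egm_vectors <- function(electrode_potentials, dt = 1, beat_kind = "paced") {
  if (!all(DEVICE_ELECTRODE_NAMES %in% rownames(electrode_potentials))) {
    stop("missing device electrode(s)")
  }
  defs <- egm_vector_definitions()
  L <- lead_matrix(defs, DEVICE_ELECTRODE_NAMES)
  samples <- L %*% electrode_potentials[DEVICE_ELECTRODE_NAMES, , drop = FALSE]
  trace_set(names(defs), samples, dt = dt, beat_kind = beat_kind)
}
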