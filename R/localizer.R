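#' Localizer model specification
#'
#' Declares the reference architecture of the trace-to-UVC regressor: the
#' beat window is block-averaged in time (temporal downsampling), the
#' channels are flattened, and a fully connected encoder (two hidden
#' layers) followed by a small regression head maps the result to the
#' 4-vector target (z, rho, sin phi, cos phi). The rotational coordinate
#' is regressed through its sine/cosine pair so that the loss respects
#' the phi wraparound.
#'
#' @param mode `"ecg"` (16 channels) or `"egm"` (8 channels).
#' @param window Beat window in samples. Default 350.
#' @param downsample Block-average factor; `window` must be a multiple.
#'   Default 10.
#' @param hidden Encoder layer widths. Default `c(96, 96)`.
#' @param head_hidden Head hidden width. Default 32.
#' @param seed Parameter-initialization seed.
#' @return A `model_spec`.
#' @export
model_spec <- function(mode = c("ecg", "egm"), window = 350, downsample = 10,
                       hidden = c(96, 96), head_hidden = 32, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(window %% downsample == 0, length(hidden) == 2)
  structure(list(mode = mode,
                 n_channels = if (mode == "ecg") 16L else 8L,
                 window = window, downsample = downsample,
                 hidden = hidden, head_hidden = head_hidden,
                 seed = as.integer(seed)), class = "model_spec")
}

#' Training configuration
#'
#' @param epochs Maximum epochs. Default 200.
#' @param batch_size Minibatch size. Default 64.
#' @param lr Adam learning rate. Default 1e-3.
#' @param val_fraction Validation fraction in (0, 0.5]. Default 0.15.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement). Default 30.
#' @param freeze_policy `"none"`, `"freeze_encoder"` or
#'   `"freeze_all_but_last"` (used by [transfer_finetune()]).
#' @param seed Seed for splits, shuffling and initialization draws.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 200, batch_size = 64, lr = 1e-3,
                         val_fraction = 0.15, patience = 30,
                         freeze_policy = c("none", "freeze_encoder",
                                           "freeze_all_but_last"),
                         seed = 1L) {
  freeze_policy <- match.arg(freeze_policy)
  stopifnot(epochs >= 1, val_fraction > 0, val_fraction <= 0.5)
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 val_fraction = val_fraction, patience = patience,
                 freeze_policy = freeze_policy, seed = as.integer(seed)),
            class = "train_config")
}

# ---- features and targets ------------------------------------------------

# block-averaged, flattened feature vector of one trace_set
trace_features <- function(ts, spec) {
  x <- ts$samples
  if (nrow(x) != spec$n_channels) {
    stop(sprintf("channel mismatch: %d channels, %s mode expects %d",
                 nrow(x), spec$mode, spec$n_channels))
  }
  tlen <- ncol(x)
  if (tlen > spec$window) x <- x[, seq_len(spec$window), drop = FALSE]
  if (tlen < spec$window) {               # pad with zeros (post-beat quiet)
    x <- cbind(x, matrix(0, nrow(x), spec$window - tlen))
  }
  k <- spec$downsample
  nb <- spec$window %/% k
  # per channel: mean over consecutive blocks of k samples
  xm <- matrix(0, nrow(x), nb)
  for (b in seq_len(nb)) {
    xm[, b] <- rowMeans(x[, ((b - 1) * k + 1):(b * k), drop = FALSE])
  }
  as.numeric(t(xm))
}

library_dataset <- function(lib, spec) {
  smp <- lib$samples
  X <- t(vapply(smp, function(s) {
    trace_features(if (spec$mode == "ecg") s$ecg else s$egm, spec)
  }, numeric(spec$n_channels * spec$window %/% spec$downsample)))
  Y <- t(vapply(smp, function(s) {
    c(s$site_uvc[["z"]], s$site_uvc[["rho"]],
      sin(s$site_uvc[["phi"]]), cos(s$site_uvc[["phi"]]))
  }, numeric(4)))
  list(X = X, Y = Y, ids = names(smp),
       anatomy = vapply(smp, `[[`, character(1), "anatomy_id"))
}

# ---- plain dense network with Adam --------------------------------------

relu <- function(x) (x > 0) * x

init_mlp <- function(fdim, spec) {
  rs <- local_rng(derive_seed(spec$seed, "mlp-init"))
  sizes <- c(fdim, spec$hidden, spec$head_hidden, 4L)
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    params[[paste0("W", l)]] <- matrix(
      rs$rnorm(fan_in * sizes[l + 1L], 0, sqrt(2 / fan_in)),
      fan_in, sizes[l + 1L])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1L])
  }
  params
}

mlp_forward <- function(params, X) {
  n_layers <- length(params) / 2L
  A <- list(X)
  for (l in seq_len(n_layers)) {
    Z <- A[[l]] %*% params[[paste0("W", l)]] +
      matrix(params[[paste0("b", l)]], nrow(A[[l]]), ncol = length(params[[paste0("b", l)]]), byrow = TRUE)
    A[[l + 1L]] <- if (l < n_layers) relu(Z) else Z
  }
  A
}

mlp_backward <- function(params, A, Y) {
  n_layers <- length(params) / 2L
  n <- nrow(Y)
  grads <- vector("list", length(params))
  names(grads) <- names(params)
  delta <- 2 * (A[[n_layers + 1L]] - Y) / (n * ncol(Y))
  for (l in n_layers:1) {
    grads[[paste0("W", l)]] <- crossprod(A[[l]], delta)
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(params[[paste0("W", l)]])) * (A[[l]] > 0)
    }
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, frozen,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    if (isTRUE(frozen[[nm]])) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

mse_loss <- function(params, X, Y) {
  A <- mlp_forward(params, X)
  mean((A[[length(A)]] - Y)^2)
}

frozen_mask <- function(params, policy) {
  n_layers <- length(params) / 2L
  frozen <- stats::setNames(as.list(rep(FALSE, length(params))), names(params))
  freeze_layers <- switch(policy,
    none = integer(0),
    freeze_encoder = seq_len(n_layers - 2L),       # all but the 2-layer head
    freeze_all_but_last = seq_len(n_layers - 1L))
  for (l in freeze_layers) {
    frozen[[paste0("W", l)]] <- TRUE
    frozen[[paste0("b", l)]] <- TRUE
  }
  if (all(unlist(frozen))) stop("freeze policy leaves no trainable parameters")
  frozen
}

fit_mlp <- function(params, X, Y, tc, policy = "none") {
  rs <- local_rng(derive_seed(tc$seed, "train"))
  n <- nrow(X)
  n_val <- max(1L, round(tc$val_fraction * n))
  perm <- rs$sample(n, n)
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  Xval <- X[val_idx, , drop = FALSE]; Yval <- Y[val_idx, , drop = FALSE]
  frozen <- frozen_mask(params, policy)
  state <- adam_init(params)
  # the returned parameters always come from a trained epoch: the incoming
  # parameters only seed the optimization, they never win the selection
  best <- list(params = NULL, val = Inf, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  stall <- 0L
  for (ep in seq_len(tc$epochs)) {
    ord <- rs$sample(length(tr_idx), length(tr_idx))
    for (start in seq(1, length(ord), by = tc$batch_size)) {
      b <- ord[start:min(start + tc$batch_size - 1L, length(ord))]
      A <- mlp_forward(params, Xtr[b, , drop = FALSE])
      grads <- mlp_backward(params, A, Ytr[b, , drop = FALSE])
      upd <- adam_step(params, grads, state, tc$lr, frozen)
      params <- upd$params; state <- upd$state
    }
    trl <- mse_loss(params, Xtr, Ytr)
    vl <- mse_loss(params, Xval, Yval)
    log <- rbind(log, data.frame(epoch = ep, train_loss = trl, val_loss = vl))
    if (vl < best$val - 1e-9) {
      best <- list(params = params, val = vl, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tc$patience) break
    }
  }
  list(params = best$params, log = log, best_epoch = best$epoch,
       val_loss = best$val, train_ids = tr_idx, val_ids = val_idx)
}

# ---- user-facing training / prediction ----------------------------------

#' Train the base localizer on paced beats
#'
#' Fits the regressor to (z, rho, sin phi, cos phi) targets with
#' minibatch Adam, a seeded train/validation split, and early stopping on
#' the validation loss (best-epoch parameters retained).
#'
#' @param library A `beat_library` of paced beats.
#' @param spec A [model_spec()].
#' @param tc A [train_config()].
#' @return A `vt_localizer` model (parameters, spec, training log).
#' @export
train_base <- function(library, spec, tc = train_config()) {
  if (length(library$samples) == 0) stop("empty library")
  ds <- library_dataset(library, spec)
  params <- init_mlp(ncol(ds$X), spec)
  fit <- fit_mlp(params, ds$X, ds$Y, tc, policy = "none")
  structure(list(spec = spec, params = fit$params, train_log = fit$log,
                 val_loss = fit$val_loss,
                 train_ids = ds$ids[fit$train_ids],
                 val_ids = ds$ids[fit$val_ids],
                 stage = "base"), class = "vt_localizer")
}

#' Fine-tune a trained localizer on VT beats (transfer learning)
#'
#' Continues training on VT-beat data, updating only the parameter
#' subset selected by the freeze policy: `"freeze_encoder"` freezes the
#' encoder layers (the regression head adapts), `"freeze_all_but_last"`
#' trains only the output layer, `"none"` is ordinary continued
#' training. Frozen tensors are bit-identical before and after.
#'
#' @param model A trained `vt_localizer`.
#' @param library A `beat_library` of VT beats.
#' @param tc A [train_config()]; its `freeze_policy` selects the subset.
#' @return The fine-tuned `vt_localizer`.
#' @export
transfer_finetune <- function(model, library, tc = train_config(freeze_policy = "freeze_encoder")) {
  if (length(library$samples) == 0) stop("empty library")
  ds <- library_dataset(library, model$spec)
  fit <- fit_mlp(model$params, ds$X, ds$Y, tc, policy = tc$freeze_policy)
  frozen <- frozen_mask(model$params, tc$freeze_policy)
  for (nm in names(frozen)) {
    if (isTRUE(frozen[[nm]])) {
      stopifnot(identical(model$params[[nm]], fit$params[[nm]]))
    }
  }
  structure(list(spec = model$spec, params = fit$params, train_log = fit$log,
                 val_loss = fit$val_loss,
                 train_ids = ds$ids[fit$train_ids],
                 val_ids = ds$ids[fit$val_ids],
                 stage = "transfer", freeze_policy = tc$freeze_policy),
            class = "vt_localizer")
}

# raw network outputs -> UVC matrix (z, rho, phi), with clipping count
outputs_to_uvc <- function(out) {
  z <- out[, 1]; rho <- out[, 2]
  clipped <- sum(z < 0 | z > 1 | rho < 0 | rho > 1)
  cbind(z = pmin(1, pmax(0, z)), rho = pmin(1, pmax(0, rho)),
        phi = atan2(out[, 3], out[, 4])) -> m
  attr(m, "n_clipped") <- clipped
  m
}

predict_uvc_matrix <- function(model, X) {
  A <- mlp_forward(model$params, X)
  outputs_to_uvc(A[[length(A)]])
}

#' Predict a VT exit site from one beat's traces
#'
#' Forward pass of the localizer, giving the exit site in UVC; the
#' Cartesian position follows by nearest-node lookup on the stated
#' anatomy. When the true site is supplied the localization error (mm)
#' is attached.
#'
#' @param model A `vt_localizer`.
#' @param traces A `trace_set` with the channel set of the model's mode.
#' @param mesh The anatomy for back-mapping.
#' @param uvc_field Its UVC field.
#' @param true_xyz Optional true site (mm) for LE computation.
#' @param sample_id Optional identifier carried through.
#' @return A `prediction_result`: `pred_uvc`, `pred_xyz`, `le_mm` (or
#'   `NA`), `n_clipped`, `sample_id`.
#' @export
predict_exit_site <- function(model, traces, mesh, uvc_field,
                              true_xyz = NULL, sample_id = NA_character_) {
  if (!identical(traces$channel_names,
                 if (model$spec$mode == "ecg") names(ecg_lead_definitions())
                 else names(egm_vector_definitions()))) {
    stop("channel mismatch: trace channels do not match the model's mode")
  }
  X <- matrix(trace_features(traces, model$spec), 1)
  u <- predict_uvc_matrix(model, X)
  q <- uvc_point(u[1, "z"], u[1, "rho"], u[1, "phi"])
  p <- uvc_to_point(mesh, uvc_field, q)
  le <- if (is.null(true_xyz)) NA_real_ else localization_error(p, true_xyz)
  structure(list(pred_uvc = q, pred_xyz = as.numeric(p), le_mm = le,
                 n_clipped = attr(u, "n_clipped"), sample_id = sample_id),
            class = "prediction_result")
}
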