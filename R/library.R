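#' Build a complete anatomy bundle for one virtual patient
#'
#' Convenience constructor tying the geometry, coordinate and forward
#' stages together: builds the mesh, its UVC field, the surface and
#' device electrode sets (with an optional seeded placement jitter
#' emulating inter-patient electrode variability) and the precomputed
#' channel-to-node forward operators for the 16 ECG channels and the 8
#' EGM vectors.
#'
#' @param params A [geometry_params()] object.
#' @param anatomy_id Identifier string.
#' @param electrode_jitter Half-range (mm) of the uniform electrode
#'   placement jitter. Default 10; 0 disables it.
#' @param torso_scale Virtual torso radius (mm) for surface electrodes.
#' @return An `anatomy_bundle`: mesh, uvc, electrode sets, forward
#'   operators `fw_ecg` (16 x nodes) and `fw_egm` (8 x nodes).
#' @export
build_anatomy <- function(params = geometry_params(), anatomy_id = "anat",
                          electrode_jitter = 10, torso_scale = 120) {
  mesh <- build_ventricle_mesh(params, anatomy_id = anatomy_id)
  uvc <- compute_uvc(mesh)
  surf <- place_surface_electrodes(mesh, torso_scale = torso_scale)
  dev <- place_device_electrodes(mesh)
  if (electrode_jitter > 0) {
    rs <- local_rng(derive_seed(params$seed, "electrodes"))
    jit <- function(es, amp) {
      p <- es$positions + matrix(rs$runif(3 * length(es$names), -amp, amp),
                                 ncol = 3)
      bad <- inside_myocardium(mesh, p)
      p[bad, ] <- es$positions[bad, , drop = FALSE]
      electrode_set(es$names, p, es$kind)
    }
    surf <- jit(surf, electrode_jitter)
    dev <- jit(dev, min(electrode_jitter, 3))  # leads move less than patches
  }
  W_surf <- lead_field_matrix(mesh, surf)
  W_dev <- lead_field_matrix(mesh, dev)
  fw_ecg <- lead_matrix(ecg_lead_definitions(), SURFACE_ELECTRODE_NAMES) %*%
    W_surf[SURFACE_ELECTRODE_NAMES, , drop = FALSE]
  fw_egm <- lead_matrix(egm_vector_definitions(), DEVICE_ELECTRODE_NAMES) %*%
    W_dev[DEVICE_ELECTRODE_NAMES, , drop = FALSE]
  structure(list(mesh = mesh, uvc = uvc, surface_electrodes = surf,
                 device_electrodes = dev, fw_ecg = fw_ecg, fw_egm = fw_egm,
                 anatomy_id = anatomy_id),
            class = "anatomy_bundle")
}

#' Configuration of a beat library
#'
#' @param anatomies Named list of [geometry_params()], one per virtual
#'   anatomy (names are the anatomy ids).
#' @param n_paced_per_anatomy Paced beats per anatomy. Desk-scale default
#'   500 (scaled down from the ~3000/model study protocol).
#' @param n_vt_per_anatomy VT beats per anatomy. Default 60.
#' @param global_seed Single seed deriving all per-stage seeds.
#' @param trace_normalization `"zscore"` (per-channel, default) or
#'   `"none"`.
#' @param noise_sd Additive Gaussian trace noise (mV, pre-normalization).
#'   Default 0 (off).
#' @param window Beat window length in samples. Default 350.
#' @param dt Sample interval (ms). Default 1.
#' @param cv Baseline [conduction_model()].
#' @param ap [ap_template()] for trace synthesis.
#' @return A `library_config`.
#' @export
library_config <- function(anatomies,
                           n_paced_per_anatomy = 500,
                           n_vt_per_anatomy = 60,
                           global_seed = 1L,
                           trace_normalization = c("zscore", "none"),
                           noise_sd = 0,
                           window = 350, dt = 1,
                           cv = conduction_model(),
                           ap = ap_template()) {
  trace_normalization <- match.arg(trace_normalization)
  stopifnot(n_paced_per_anatomy > 0, n_vt_per_anatomy > 0,
            length(anatomies) >= 1, !is.null(names(anatomies)),
            !anyDuplicated(names(anatomies)))
  structure(list(anatomies = anatomies,
                 n_paced_per_anatomy = n_paced_per_anatomy,
                 n_vt_per_anatomy = n_vt_per_anatomy,
                 global_seed = as.integer(global_seed),
                 trace_normalization = trace_normalization,
                 noise_sd = noise_sd, window = window, dt = dt,
                 cv = cv, ap = ap), class = "library_config")
}

#' Default five-anatomy virtual cohort
#'
#' Five geometry-parameter perturbations (axes and wall +/-10%) of the
#' default ventricle, standing in for a cohort of image-derived
#' anatomies.
#'
#' @param n Number of anatomies. Default 5.
#' @param base Base [geometry_params()].
#' @param global_seed Seed for the perturbations.
#' @return Named list of `geometry_params`.
#' @export
make_cohort <- function(n = 5, base = geometry_params(), global_seed = 1L) {
  out <- lapply(seq_len(n), function(i) {
    perturb_geometry(base, seed = derive_seed(global_seed, "cohort", i))
  })
  names(out) <- sprintf("anat%02d", seq_len(n))
  out
}

#' Sample focal pacing sites on a mesh
#'
#' Uniform seeded sample of myocardial nodes without replacement.
#'
#' @param mesh A `ventricular_mesh`.
#' @param n Number of sites; at most the node count.
#' @param seed Integer seed.
#' @return Integer vector of node indices.
#' @export
sample_pacing_sites <- function(mesh, n, seed = 0L) {
  n_nodes <- nrow(mesh$nodes)
  if (n > n_nodes) stop("n exceeds node count")
  rs <- local_rng(seed)
  rs$sample(n_nodes, n)
}

# Vm synthesis for exactly n_samples columns (window cropping allowed);
# same waveform as synthesize_vm_traces without its coverage contract
synth_vm_window <- function(act, tpl, dt, n_samples) {
  times <- seq(0, by = dt, length.out = n_samples)
  a <- as.numeric(act)
  amp <- tpl$plateau - tpl$resting
  s <- outer(-a, times, `+`)
  vm <- tpl$resting + amp * (clamp01(s / tpl$upstroke) -
                             clamp01((s - tpl$apd) / tpl$repol))
  vm[!is.finite(a), ] <- tpl$resting
  vm
}

normalize_traces <- function(x, how) {
  if (how == "none") return(x)
  mu <- rowMeans(x)
  x <- x - mu
  s <- sqrt(rowMeans(x^2))
  zero <- s < 1e-12
  s[zero] <- 1
  x <- x / s
  x[zero, ] <- 0
  x
}

make_beat_sample <- function(bundle, act, cfg, site_node, sample_id,
                             beat_kind, seed, rs_noise = NULL) {
  vm <- synth_vm_window(act, cfg$ap, cfg$dt, cfg$window)
  ecg <- bundle$fw_ecg %*% vm
  egm <- bundle$fw_egm %*% vm
  if (cfg$noise_sd > 0 && !is.null(rs_noise)) {
    ecg <- ecg + matrix(rs_noise$rnorm(length(ecg), 0, cfg$noise_sd), nrow(ecg))
    egm <- egm + matrix(rs_noise$rnorm(length(egm), 0, cfg$noise_sd), nrow(egm))
  }
  ecg <- normalize_traces(ecg, cfg$trace_normalization)
  egm <- normalize_traces(egm, cfg$trace_normalization)
  u <- bundle$uvc[site_node, ]
  list(
    sample_id = sample_id,
    anatomy_id = bundle$anatomy_id,
    beat_kind = beat_kind,
    site_node = site_node,
    site_uvc = uvc_point(u[["z"]], u[["rho"]], u[["phi"]]),
    site_xyz = bundle$mesh$nodes[site_node, ],
    seed = seed,
    ecg = trace_set(rownames(bundle$fw_ecg), ecg, cfg$dt, beat_kind),
    egm = trace_set(rownames(bundle$fw_egm), egm, cfg$dt, beat_kind)
  )
}

library_manifest <- function(samples) {
  do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, anatomy_id = s$anatomy_id,
               kind = s$beat_kind,
               z = s$site_uvc[["z"]], rho = s$site_uvc[["rho"]],
               phi = s$site_uvc[["phi"]],
               x = s$site_xyz[1], y = s$site_xyz[2], z_mm = s$site_xyz[3],
               segment = aha_segment_of(s$site_uvc[["z"]], s$site_uvc[["phi"]]),
               seed = s$seed, stringsAsFactors = FALSE)
  }))
}

new_beat_library <- function(samples, cfg, bundles) {
  structure(list(samples = samples, manifest = library_manifest(samples),
                 config = cfg, bundles = bundles),
            class = "beat_library")
}

#' @export
print.beat_library <- function(x, ...) {
  tab <- table(x$manifest$kind, x$manifest$anatomy_id)
  cat(sprintf("beat_library: %d samples over %d anatomies\n",
              nrow(x$manifest), length(unique(x$manifest$anatomy_id))))
  print(tab)
  invisible(x)
}

#' Build the focal paced-beat library
#'
#' For every anatomy and sampled pacing site: one eikonal solve, Vm
#' synthesis, the 16-channel ECG and 8-channel EGM trace sets, and the
#' site's UVC/Cartesian label. Deterministic for a fixed configuration.
#'
#' @param cfg A [library_config()].
#' @param bundles Optional prebuilt [build_anatomy()] bundles (named as
#'   the config anatomies); built on demand otherwise.
#' @param out_dir Optional directory; when given the library is saved
#'   there ([save_beat_library()]).
#' @return A `beat_library`.
#' @export
build_pacing_library <- function(cfg, bundles = NULL, out_dir = NULL) {
  bundles <- bundles %||% build_bundles(cfg)
  samples <- list()
  for (ai in seq_along(cfg$anatomies)) {
    id <- names(cfg$anatomies)[ai]
    bundle <- bundles[[id]]
    seed_a <- derive_seed(cfg$global_seed, "pacing-sites", ai)
    sites <- sample_pacing_sites(bundle$mesh, cfg$n_paced_per_anatomy, seed_a)
    acts <- eikonal_many(bundle$mesh, cfg$cv, sites)
    rs_noise <- if (cfg$noise_sd > 0)
      local_rng(derive_seed(cfg$global_seed, "pacing-noise", ai)) else NULL
    for (i in seq_along(sites)) {
      sid <- sprintf("%s_paced_%04d", id, i)
      samples[[sid]] <- make_beat_sample(bundle, acts[i, ], cfg, sites[i],
                                         sid, "paced", seed_a, rs_noise)
    }
  }
  lib <- new_beat_library(samples, cfg, bundles)
  if (!is.null(out_dir)) save_beat_library(lib, out_dir)
  lib
}

#' Build every anatomy bundle of a library configuration
#'
#' @param cfg A [library_config()].
#' @return Named list of [build_anatomy()] bundles.
#' @export
build_bundles <- function(cfg) {
  out <- lapply(seq_along(cfg$anatomies), function(i) {
    build_anatomy(cfg$anatomies[[i]], anatomy_id = names(cfg$anatomies)[i])
  })
  names(out) <- names(cfg$anatomies)
  out
}

#' Build the post-infarct VT-beat library
#'
#' Per anatomy, `n_vt_per_anatomy` substrates are generated round-robin
#' over AHA segments 1..16 with seeded jitter; each yields one VT episode
#' ([make_vt_episode()]) whose systolic activation produces the ECG/EGM
#' traces, labelled with the exit site. Non-viable circuits are resampled
#' with bounded retries.
#'
#' @inheritParams build_pacing_library
#' @return A `beat_library` of kind `"vt"` samples (with `episode`
#'   metadata: cycle length, substrate).
#' @export
build_vt_library <- function(cfg, bundles = NULL, out_dir = NULL) {
  bundles <- bundles %||% build_bundles(cfg)
  samples <- list()
  for (ai in seq_along(cfg$anatomies)) {
    id <- names(cfg$anatomies)[ai]
    bundle <- bundles[[id]]
    for (i in seq_len(cfg$n_vt_per_anatomy)) {
      seg <- (i - 1L) %% 16L + 1L
      ep <- NULL
      for (try in 0:9) {
        seed_i <- derive_seed(cfg$global_seed, "vt-substrate",
                              ai * 100000L + i + try * 1000L)
        ep <- tryCatch({
          scar <- generate_substrate(bundle$mesh, bundle$uvc, seg, seed = seed_i)
          make_vt_episode(bundle$mesh, bundle$uvc, cfg$cv, scar)
        }, error = function(e) NULL)
        if (!is.null(ep)) break
      }
      if (is.null(ep)) stop(sprintf("no viable VT circuit in segment %d of %s",
                                    seg, id))
      sid <- sprintf("%s_vt_%04d", id, i)
      s <- make_beat_sample(bundle, ep$activation, cfg, ep$exit_node, sid,
                            "vt", ep$substrate$seed)
      s$episode <- list(aha_segment = ep$substrate$aha_segment,
                        cycle_length = ep$cycle_length,
                        substrate = ep$substrate)
      samples[[sid]] <- s
    }
  }
  lib <- new_beat_library(samples, cfg, bundles)
  if (!is.null(out_dir)) save_beat_library(lib, out_dir)
  lib
}

#' Subset a beat library by anatomy and kind
#'
#' @param lib A `beat_library`.
#' @param anatomy_ids Anatomies to keep (default all).
#' @param kinds Beat kinds to keep (default all).
#' @param sample_ids Specific sample ids to keep (default all).
#' @return A `beat_library` with the matching samples.
#' @export
subset_library <- function(lib, anatomy_ids = NULL, kinds = NULL,
                           sample_ids = NULL) {
  keep <- rep(TRUE, nrow(lib$manifest))
  if (!is.null(anatomy_ids)) keep <- keep & lib$manifest$anatomy_id %in% anatomy_ids
  if (!is.null(kinds)) keep <- keep & lib$manifest$kind %in% kinds
  if (!is.null(sample_ids)) keep <- keep & lib$manifest$sample_id %in% sample_ids
  new_beat_library(lib$samples[lib$manifest$sample_id[keep]], lib$config,
                   lib$bundles)
}

#' Save / load a beat library
#'
#' Writes the library object (RDS), a plain-text CSV manifest and a JSON
#' snapshot of the scalar configuration.
#'
#' @param lib A `beat_library`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly (`load_beat_library` returns the library).
#' @export
save_beat_library <- function(lib, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(lib, file.path(dir, "library.rds"))
  utils::write.csv(lib$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  cfgsnap <- lib$config
  cfgsnap$anatomies <- lapply(cfgsnap$anatomies, unclass)
  cfgsnap$cv <- unclass(cfgsnap$cv)
  cfgsnap$ap <- unclass(cfgsnap$ap)
  jsonlite::write_json(cfgsnap, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @rdname save_beat_library
#' @export
load_beat_library <- function(dir) {
  readRDS(file.path(dir, "library.rds"))
}
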