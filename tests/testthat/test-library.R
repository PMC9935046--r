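test_that("pacing-site sampling is uniform, seeded and exhaustive", {
  mesh <- coarse_mesh()
  n <- nrow(mesh$nodes)
  expect_setequal(sample_pacing_sites(mesh, n, seed = 1), seq_len(n))
  expect_identical(sample_pacing_sites(mesh, 50, seed = 2),
                   sample_pacing_sites(mesh, 50, seed = 2))
  expect_false(identical(sample_pacing_sites(mesh, 50, seed = 2),
                         sample_pacing_sites(mesh, 50, seed = 3)))
  expect_error(sample_pacing_sites(mesh, n + 1), "exceeds")
  # the z-distribution of many sites tracks the node z-distribution
  u <- coarse_uvc()
  sites <- sample_pacing_sites(mesh, min(400, n), seed = 4)
  ks <- suppressWarnings(stats::ks.test(u[sites, "z"], u[, "z"]))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("the pacing library fulfils its cardinality and label contract", {
  libs <- tiny_libs()
  plib <- libs$pacing
  cfg <- libs$cfg
  expect_identical(nrow(plib$manifest),
                   2L * as.integer(cfg$n_paced_per_anatomy))
  s <- plib$samples[[1]]
  expect_identical(dim(s$ecg$samples), c(16L, as.integer(cfg$window)))
  expect_identical(dim(s$egm$samples), c(8L, as.integer(cfg$window)))
  expect_true(all(plib$manifest$z >= 0 & plib$manifest$z <= 1))
  expect_true(all(plib$manifest$rho >= 0 & plib$manifest$rho <= 1))
  expect_true(all(plib$manifest$segment %in% 1:17))
  # label consistency: stored xyz is the labelled node's position
  b <- plib$bundles[[s$anatomy_id]]
  expect_equal(as.numeric(s$site_xyz), as.numeric(b$mesh$nodes[s$site_node, ]))
})

test_that("library construction is deterministic in the global seed", {
  libs <- tiny_libs()
  cfg <- libs$cfg
  plib2 <- build_pacing_library(cfg, libs$pacing$bundles)
  expect_identical(libs$pacing$manifest, plib2$manifest)
  expect_identical(libs$pacing$samples[[5]]$ecg$samples,
                   plib2$samples[[5]]$ecg$samples)
})

test_that("z-score normalization holds channel-wise on stored traces", {
  libs <- tiny_libs()
  for (s in libs$pacing$samples[1:5]) {
    for (ts in list(s$ecg, s$egm)) {
      mu <- rowMeans(ts$samples)
      sd <- sqrt(rowMeans(ts$samples^2))
      const <- sd < 1e-12
      expect_true(all(abs(mu) < 1e-9))
      expect_true(all(abs(sd[!const] - 1) < 1e-6))
    }
  }
})

test_that("VT library labels the activation argmin and covers segments", {
  libs <- tiny_libs()
  vlib <- libs$vt
  expect_identical(nrow(vlib$manifest), 2L * 8L)
  # round-robin over segments 1..16: 8 episodes cover segments 1..8
  segs <- vapply(vlib$samples, function(s) s$episode$aha_segment, integer(1))
  expect_identical(unname(segs[1:8]), 1:8)
  cl <- vapply(vlib$samples, function(s) s$episode$cycle_length, numeric(1))
  expect_true(all(is.finite(cl) & cl > 0))
  expect_true(all(vlib$manifest$kind == "vt"))
})

test_that("VT morphology differs from a paced beat at the same site", {
  libs <- tiny_libs()
  vlib <- libs$vt
  cfg <- libs$cfg
  s <- vlib$samples[[3]]
  b <- vlib$bundles[[s$anatomy_id]]
  act <- solve_eikonal(b$mesh, cfg$cv, s$site_node)  # unscarred pacing
  paced <- vtlocalizer:::make_beat_sample(b, act, cfg, s$site_node, "tmp",
                                          "paced", 0L)
  expect_gt(sqrt(mean((paced$ecg$samples - s$ecg$samples)^2)), 0)
})

test_that("libraries round-trip through disk with intact manifests", {
  libs <- tiny_libs()
  dir <- withr::local_tempdir()
  save_beat_library(libs$pacing, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- load_beat_library(dir)
  expect_identical(back$manifest, libs$pacing$manifest)
  disk_manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(disk_manifest$z, libs$pacing$manifest$z, tolerance = 1e-12)
})

test_that("mesh and fields round-trip through the VTK writer", {
  mesh <- coarse_mesh()
  u <- coarse_uvc()
  path <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, path, point_data = list(z = u[, "z"], uvc_rho = u[, "rho"]))
  back <- read_mesh_vtk(path)
  expect_equal(back$nodes, unname(mesh$nodes), tolerance = 1e-9)
  expect_identical(back$elements, matrix(as.numeric(mesh$elements),
                                         nrow(mesh$elements)))
  expect_equal(back$point_data$z, unname(u[, "z"]), tolerance = 1e-9)
  expect_equal(back$cell_data$fiber, unname(mesh$fiber_dirs), tolerance = 1e-9)
})
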