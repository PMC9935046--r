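test_that("mesh construction satisfies its structural contract", {
  mesh <- coarse_mesh()
  n <- nrow(mesh$nodes)
  expect_true(all(mesh$elements >= 1) && all(mesh$elements <= n))
  expect_true(all(tet_volumes(mesh$nodes, mesh$elements) > 0))
  labs <- mesh$surface_labels
  expect_gt(sum(labs == "endocardium"), 0)
  expect_gt(sum(labs == "epicardium"), 0)
  expect_identical(sum(labs == "apex_node"), 1L)
  expect_identical(which(labs == "apex_node"), mesh$apex_node)
  # endo and epi node sets disjoint by construction of single labels
  expect_length(intersect(which(labs == "endocardium"),
                          which(labs == "epicardium")), 0)
  expect_equal(sqrt(rowSums(mesh$fiber_dirs^2)), rep(1, nrow(mesh$elements)),
               tolerance = 1e-9)
})

test_that("mesh generation is deterministic for fixed params and seed", {
  p <- coarse_params()
  m1 <- build_ventricle_mesh(p, "a")
  m2 <- build_ventricle_mesh(p, "a")
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elements, m2$elements)
  m3 <- build_ventricle_mesh(geometry_params(target_edge_length = 7, seed = 99L), "a")
  expect_false(identical(m1$nodes, m3$nodes))  # jitter moved interior nodes
})

test_that("meshed volume matches the analytic truncated-shell volume", {
  for (p in list(coarse_params(),
                 geometry_params(target_edge_length = 4),
                 geometry_params(lv_long_axis = 80, lv_endo_short_axis = 22,
                                 wall_thickness = 8, target_edge_length = 5))) {
    mesh <- build_ventricle_mesh(p)
    vol <- sum(tet_volumes(mesh$nodes, mesh$elements))
    expect_lt(abs(vol / analytic_shell_volume(p) - 1), 0.05)
  }
})

test_that("invalid geometry is rejected with the declared errors", {
  expect_error(build_ventricle_mesh(geometry_params(lv_endo_short_axis = 9,
                                                    wall_thickness = 10,
                                                    target_edge_length = 2)),
               "self-intersecting wall")
  expect_error(build_ventricle_mesh(geometry_params(wall_thickness = 4,
                                                    target_edge_length = 5)),
               "unresolvable wall")
})

test_that("fiber field follows the transmural helix-angle ramp", {
  mesh <- coarse_mesh()
  # zero rotation: fibers orthogonal to the local transmural axis
  m0 <- assign_fibers(mesh, 0, 0)
  cent <- element_centroids(m0)
  dep <- element_depths(m0)
  fr <- vtlocalizer:::local_frames(m0, cent, pmin(1, pmax(0, dep)))
  expect_lt(max(abs(rowSums(m0$fiber_dirs * fr$transmural))), 1e-6)

  # default ramp: recompute the helix angle from the stored fibers
  m <- assign_fibers(mesh, 60, -60)
  ang <- asin(pmin(1, pmax(-1, rowSums(m$fiber_dirs *
    vtlocalizer:::cross3(fr$transmural, fr$circumferential))))) * 180 / pi
  expected <- 60 + pmin(1, pmax(0, dep)) * (-120)
  # mid-wall elements are near 0 degrees
  mid <- abs(dep - 0.5) < 0.05
  if (any(mid)) expect_lt(max(abs(ang[mid])), 5 + 1e-9)
  # the ramp holds across depth deciles
  dec <- cut(dep, breaks = seq(0, 1, by = 0.1), include.lowest = TRUE)
  err <- tapply(ang - expected, dec, function(x) mean(abs(x)))
  expect_true(all(err[!is.na(err)] < 5))
})

test_that("surface electrodes follow the template and scaling contract", {
  mesh <- coarse_mesh()
  es <- place_surface_electrodes(mesh)
  expect_identical(es$names, c("RA", "LA", "LL", paste0("V", 1:6)))
  expect_identical(es$kind, "surface")
  # precordial leads anterior (+x) of the mesh
  expect_true(all(es$positions[paste0("V", 1:6), 1] > 0))
  es2 <- place_surface_electrodes(mesh, torso_scale = 240)
  expect_equal(sqrt(rowSums(es2$positions^2)),
               2 * sqrt(rowSums(es$positions^2)), tolerance = 1e-12)
  # no electrode closer than 10 mm to the epicardium
  epi <- mesh$nodes[mesh$surface_labels %in% c("epicardium", "apex_node"), ]
  dmin <- min(apply(es$positions, 1, function(p) {
    min(sqrt(colSums((t(epi) - p)^2)))
  }))
  expect_gt(dmin, 10)
  expect_error(place_surface_electrodes(mesh, torso_scale = 10),
               "placement error")
})

test_that("device electrodes are placed per the implanted-device layout", {
  mesh <- coarse_mesh()
  es <- place_device_electrodes(mesh)
  expect_setequal(es$names, c("CAN", "SVC_COIL", "RV_COIL", "RV_TIP",
                              "RV_RING", paste0("LV", 1:4)))
  apex <- mesh$nodes[mesh$apex_node, ]
  expect_lte(localization_error(es$positions["RV_TIP", ], apex), 10 + 1e-9)
  lv <- es$positions[paste0("LV", 1:4), ]
  gaps <- sqrt(rowSums((lv[-1, ] - lv[-4, ])^2))
  expect_true(all(abs(gaps - 10) <= 2))
  expect_identical(es$positions, place_device_electrodes(mesh)$positions)
})
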