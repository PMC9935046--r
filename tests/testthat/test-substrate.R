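test_that("substrate construction is segment-consistent and seeded", {
  mesh <- fine_mesh()
  u <- fine_uvc()
  s0 <- generate_substrate(mesh, u, 10, seed = 0)
  expect_identical(aha_segment_of(s0$center_uvc), 10L)
  s1 <- generate_substrate(mesh, u, 10, seed = 1)
  expect_identical(aha_segment_of(s1$center_uvc), 10L)
  expect_false(identical(s0$center_uvc, s1$center_uvc))  # jitter differs
  expect_identical(generate_substrate(mesh, u, 10, seed = 0), s0)
  expect_error(generate_substrate(mesh, u, 17, seed = 0))
})

test_that("lobes, corridor and remote tissue partition as declared", {
  mesh <- fine_mesh()
  u <- fine_uvc()
  scar <- generate_substrate(mesh, u, 8, seed = 3)
  msk <- vtlocalizer:::substrate_masks(mesh, u, scar)
  cm <- apply_substrate(conduction_model(), mesh, u, scar)
  expect_equal(sort(unique(cm$element_multiplier)), c(0, 0.25, 1))
  expect_true(all(cm$element_multiplier[msk$elem == 1L] == 0))
  expect_true(all(cm$element_multiplier[msk$elem == 2L] == 0.25))
  expect_true(all(cm$element_multiplier[msk$elem == 0L] == 1))
  # lobe and corridor node sets are disjoint
  expect_length(intersect(which(msk$node == 1L), which(msk$node == 2L)), 0)
  # pure function: baseline model untouched
  base <- conduction_model()
  apply_substrate(base, mesh, u, scar)
  expect_null(base$element_multiplier)
})

test_that("scar lobes never activate from a remote source", {
  mesh <- fine_mesh()
  u <- fine_uvc()
  scar <- generate_substrate(mesh, u, 12, seed = 2)
  cm <- apply_substrate(conduction_model(), mesh, u, scar)
  msk <- vtlocalizer:::substrate_masks(mesh, u, scar)
  # pace from the apex (remote from a mid-ring scar)
  act <- solve_eikonal(mesh, cm, mesh$apex_node)
  lobe_nodes <- which(msk$node == 1L)
  interior_lobe <- lobe_nodes[vapply(lobe_nodes, function(k) {
    els <- which(rowSums(mesh$elements == k) > 0)
    all(cm$element_multiplier[els] == 0)
  }, logical(1))]
  expect_gt(length(interior_lobe), 0)
  expect_true(all(!is.finite(act[interior_lobe])))
})

test_that("the corridor slows conduction by 1/multiplier", {
  mesh <- fine_mesh()
  u <- fine_uvc()
  scar <- generate_substrate(mesh, u, 10, seed = 4)
  cm0 <- conduction_model()
  cm1 <- apply_substrate(cm0, mesh, u, scar)
  # edge level: edges whose fastest incident element is corridor tissue
  # are slowed by exactly 1/multiplier; remote edges are untouched
  ed0 <- vtlocalizer:::conduction_edges(mesh, cm0)
  ed1 <- vtlocalizer:::conduction_edges(mesh, cm1)
  n <- nrow(mesh$nodes)
  k0 <- (ed0$a - 1) * n + ed0$b
  k1 <- (ed1$a - 1) * n + ed1$b
  common <- match(k1, k0)
  ratio <- ed1$weight / ed0$weight[common]
  expect_true(all(ratio >= 1 - 1e-12))       # the scar only ever slows
  expect_gt(sum(abs(ratio - 4) < 1e-9), 3)   # fully slowed corridor edges
  expect_gt(mean(abs(ratio - 1) < 1e-12), 0.9)  # most tissue is remote
  # path level: transit along the corridor is slowed close to 4x; edges at
  # the mouths (bordering healthy or scarred elements) shift the factor
  msk <- vtlocalizer:::substrate_masks(mesh, u, scar)
  corridor <- which(msk$node == 2L)
  expect_gt(length(corridor), 3)
  zc <- u[corridor, "z"]
  from <- corridor[which.min(zc)]
  to <- corridor[which.max(zc)]
  keep <- msk$node == 2L
  t0 <- vtlocalizer:::restricted_path_time(mesh, cm0, from, to, keep)
  t1 <- vtlocalizer:::restricted_path_time(mesh, cm1, from, to, keep)
  expect_true(is.finite(t0))
  expect_gte(t1 / t0, 3)
  expect_lte(t1 / t0, 4.5)
})

test_that("uniform slowing scales whole-mesh activation exactly", {
  mesh <- coarse_mesh()
  cm0 <- conduction_model()
  cm1 <- conduction_model(element_multiplier = rep(0.25, nrow(mesh$elements)))
  a0 <- solve_eikonal(mesh, cm0, 25L)
  a1 <- solve_eikonal(mesh, cm1, 25L)
  expect_equal(as.numeric(a1), 4 * as.numeric(a0), tolerance = 1e-9)
})

test_that("VT episodes expose the exit site as earliest activation", {
  mesh <- fine_mesh()
  u <- fine_uvc()
  cm <- conduction_model()
  for (seg in c(2, 7, 15)) {
    scar <- generate_substrate(mesh, u, seg, seed = seg)
    ep <- make_vt_episode(mesh, u, cm, scar)
    expect_identical(ep$activation[ep$exit_node], 0)
    excitable <- is.finite(ep$activation)
    expect_identical(which.min(replace(ep$activation, !excitable, Inf)),
                     ep$exit_node)
    # exit coordinates mutually consistent
    expect_equal(as.numeric(ep$exit_xyz), as.numeric(mesh$nodes[ep$exit_node, ]))
    expect_equal(unname(ep$exit_uvc["z"]), unname(u[ep$exit_node, "z"]))
    expect_gt(ep$cycle_length, 0)
  }
})

test_that("VT circuits across segments give physiological cycle lengths", {
  mesh <- fine_mesh()
  u <- fine_uvc()
  cm <- conduction_model()
  cls <- vapply(1:16, function(seg) {
    make_vt_episode(mesh, u, cm,
                    generate_substrate(mesh, u, seg, seed = 7))$cycle_length
  }, numeric(1))
  expect_true(all(is.finite(cls)))
  # mid-ring circuits (~40 mm path at multiplier 0.25) sit in the
  # physiological window; basal circuits run longer return paths
  expect_true(all(cls[7:12] >= 200 & cls[7:12] <= 450))
  expect_true(all(cls >= 150 & cls <= 550))
})

test_that("the two exit sides produce distinct activation patterns", {
  mesh <- fine_mesh()
  u <- fine_uvc()
  cm <- conduction_model()
  scar <- generate_substrate(mesh, u, 9, seed = 1)
  scarred <- apply_substrate(cm, mesh, u, scar)
  up <- vtlocalizer:::corridor_mouth_node(mesh, u, scarred, scar, 1)
  dn <- vtlocalizer:::corridor_mouth_node(mesh, u, scarred, scar, -1)
  expect_false(is.na(up) || is.na(dn))
  expect_true(up != dn)
  a1 <- solve_eikonal(mesh, scarred, up)
  a2 <- solve_eikonal(mesh, scarred, dn)
  expect_gt(max(abs(a1 - a2), na.rm = TRUE), 1)
})
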