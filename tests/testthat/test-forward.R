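test_that("zero-gradient sources produce zero electrode potentials", {
  bundle <- fine_bundle()
  mesh <- bundle$mesh
  n <- nrow(mesh$nodes)
  vm_flat <- matrix(-85, n, 5)              # uniform resting potential
  pot <- compute_electrode_potentials(mesh, vm_flat, bundle$surface_electrodes)
  expect_lt(max(abs(pot)), 1e-9)
  # after full repolarization every node is back at rest
  tpl <- ap_template()
  act <- solve_eikonal(mesh, conduction_model(), mesh$apex_node)
  dur <- max(act) + tpl$apd + tpl$repol + 10
  vm <- synthesize_vm_traces(act, tpl, 1, dur)
  pot2 <- compute_electrode_potentials(mesh, vm[, ncol(vm), drop = FALSE],
                                       bundle$surface_electrodes)
  expect_lt(max(abs(pot2)), 1e-9)
})

test_that("pseudo-ECG is linear in Vm and decays with distance", {
  bundle <- fine_bundle()
  mesh <- bundle$mesh
  act <- solve_eikonal(mesh, conduction_model(), 50L)
  vm <- vtlocalizer:::synth_vm_window(act, ap_template(), 1, 120)
  W <- lead_field_matrix(mesh, bundle$surface_electrodes)
  expect_equal(W %*% (3 * vm), 3 * (W %*% vm), tolerance = 1e-12)
  # doubling an electrode's distance from the centroid reduces RMS potential
  ctr <- colMeans(mesh$nodes)
  e1 <- electrode_set("P1", matrix(ctr + c(120, 0, 0), 1), "surface")
  e2 <- electrode_set("P1", matrix(ctr + c(240, 0, 0), 1), "surface")
  r1 <- sqrt(mean((lead_field_matrix(mesh, e1) %*% vm)^2))
  r2 <- sqrt(mean((lead_field_matrix(mesh, e2) %*% vm)^2))
  expect_lt(r2, r1)
})

test_that("electrodes inside the wall are rejected", {
  bundle <- fine_bundle()
  mesh <- bundle$mesh
  g <- mesh$geom
  inside <- matrix(c(0, 0, 0.5 * (g$z_base)), 1)
  inside[1] <- (g$a_endo + g$a_epi) / 2 * 0.98   # mid-wall at the equator
  inside[3] <- g$zc
  es <- electrode_set("BAD", inside, "surface")
  expect_error(lead_field_matrix(mesh, es), "singularity")
})

test_that("mirror-symmetric electrodes see a symmetric wavefront equally", {
  # one tetrahedral source and its mirror image in the y = 0 plane
  tetA <- rbind(c(0, -8, 0), c(4, -6, 0), c(0, -6, 4), c(1, -5, 1))
  tetB <- tetA; tetB[, 2] <- -tetB[, 2]
  nodes <- rbind(tetA, tetB)
  el <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8))
  mesh <- structure(list(nodes = nodes, elements = el,
                         fiber_dirs = matrix(rep(c(1, 0, 0), 2), ncol = 3,
                                             byrow = TRUE),
                         surface_labels = rep("interior", 8), apex_node = 1L,
                         septal_ref_dir = c(-1, 0, 0), anatomy_id = "slab",
                         node_depth = rep(0.5, 8), node_tfrac = rep(0.5, 8),
                         geom = NULL), class = "ventricular_mesh")
  # Vm pattern identical on mirrored node pairs
  vm <- matrix(c(20, -40, 5, -85, 20, -40, 5, -85), 8, 3)
  es <- electrode_set(c("A", "B"),
                      rbind(c(10, -50, 10), c(10, 50, 10)), "surface")
  pot <- compute_electrode_potentials(mesh, vm, es)
  expect_equal(pot["A", ], pot["B", ], tolerance = 1e-6)
})

test_that("ECG lead algebra closes and is reference invariant", {
  set.seed(5)
  pot <- matrix(rnorm(9 * 50), 9, 50,
                dimnames = list(vtlocalizer:::SURFACE_ELECTRODE_NAMES, NULL))
  ts <- derive_ecg_leads(pot)
  expect_identical(ts$channel_names,
                   c("I", "II", "III", "aVR", "aVL", "aVF",
                     paste0("V", 1:6), "X", "Y", "Z", "M"))
  s <- ts$samples
  expect_lt(max(abs(s["II", ] - s["I", ] - s["III", ])), 1e-12)
  expect_lt(max(abs(s["aVR", ] + s["aVL", ] + s["aVF", ])), 1e-12)
  # adding a constant to all electrodes changes nothing
  ts2 <- derive_ecg_leads(pot + 17.3)
  expect_equal(ts2$samples, s, tolerance = 1e-9)
  # every lead definition has zero-sum coefficients
  for (d in ecg_lead_definitions()) expect_lt(abs(sum(d$coeffs)), 1e-12)
})

test_that("EGM vectors are bipolar, complete and reference invariant", {
  defs <- egm_vector_definitions()
  expect_length(defs, 8)
  expect_identical(names(defs),
                   c("RV_TIP-RV_RING", "RV_COIL-CAN", "SVC_COIL-CAN",
                     "RV_COIL-SVC_COIL", "LV1-LV2", "LV2-LV3", "LV3-LV4",
                     "LV4-CAN"))
  for (d in defs) {
    expect_identical(sort(unname(d$coeffs[d$coeffs != 0])), c(-1, 1))
  }
  set.seed(6)
  pot <- matrix(rnorm(9 * 30), 9, 30,
                dimnames = list(vtlocalizer:::DEVICE_ELECTRODE_NAMES, NULL))
  expect_equal(derive_egm_vectors(pot + 5)$samples,
               derive_egm_vectors(pot)$samples, tolerance = 1e-9)
  expect_error(derive_egm_vectors(pot[1:7, ]), "missing")
})
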