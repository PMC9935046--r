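test_that("edge traversal time follows the anisotropic speed law", {
  cm <- conduction_model(cv_long = 1, cv_trans = 0.5)
  f <- c(1, 0, 0)
  expect_equal(edge_traversal_time(c(0, 0, 0), c(10, 0, 0), f, cm, 1), 10)
  expect_equal(edge_traversal_time(c(0, 0, 0), c(0, 10, 0), f, cm, 1), 20)
  # isotropy limit: any orientation gives the same time
  iso <- conduction_model(cv_long = 0.7, cv_trans = 0.7)
  for (d in list(c(1, 0, 0), c(1, 1, 0) / sqrt(2), c(1, 2, 3) / sqrt(14))) {
    expect_equal(edge_traversal_time(c(0, 0, 0), 10 * d, f, iso, 1), 10 / 0.7,
                 tolerance = 1e-12)
  }
  expect_identical(edge_traversal_time(c(0, 0, 0), c(10, 0, 0), f, cm, 0), Inf)
  # slowing multiplier scales time inversely
  expect_equal(edge_traversal_time(c(0, 0, 0), c(10, 0, 0), f, cm, 0.25), 40)
})

test_that("eikonal solution matches a chain sum and min-superposition", {
  # 1D chain of nodes 1 mm apart embedded as degenerate tets
  n <- 12
  nodes <- cbind(seq_len(n), 0, 0)
  elements <- cbind(seq_len(n - 3), 2:(n - 2), 3:(n - 1), 4:n)
  nodes[, 2] <- c(0, rep(0.001, n - 1))  # avoid exactly zero volumes
  nodes[, 2] <- seq(0, by = 1e-3, length.out = n)^2
  mesh <- structure(list(nodes = nodes, elements = elements,
                         fiber_dirs = matrix(rep(c(1, 0, 0), nrow(elements)),
                                             ncol = 3, byrow = TRUE),
                         surface_labels = rep("interior", n), apex_node = 1L,
                         septal_ref_dir = c(-1, 0, 0), anatomy_id = "chain",
                         node_depth = rep(0.5, n), node_tfrac = rep(0.5, n),
                         geom = NULL), class = "ventricular_mesh")
  cm <- conduction_model(cv_long = 1, cv_trans = 1)
  act <- solve_eikonal(mesh, cm, 1L)
  # consecutive nodes ~1 mm apart at 1 m/s: node k activates near (k-1) ms
  expect_equal(as.numeric(act), sqrt(rowSums((nodes - rep(nodes[1, ],
    each = n))^2)), tolerance = 0.05)
  # two offset sources: per-node min over single-source solutions
  a1 <- solve_eikonal(mesh, cm, list(list(node = 1L, offset = 0)))
  a2 <- solve_eikonal(mesh, cm, list(list(node = n, offset = 5)))
  both <- solve_eikonal(mesh, cm, list(list(node = 1L, offset = 0),
                                       list(node = n, offset = 5)))
  expect_equal(as.numeric(both), pmin(as.numeric(a1), as.numeric(a2)),
               tolerance = 1e-12)
})

test_that("eikonal equals the Bellman-Ford oracle on random meshes", {
  for (rep_i in 1:6) {
    mesh <- random_tet_mesh(60, seed = 100 + rep_i)
    mult <- rep(1, nrow(mesh$elements))
    set.seed(200 + rep_i)
    mult[sample(length(mult), 40)] <- 0      # some inexcitable patches
    cm <- conduction_model(0.8, 0.3, mult)
    src <- sample(60, 2)
    act <- solve_eikonal(mesh, cm, src)
    ed <- vtlocalizer:::conduction_edges(mesh, cm)
    oracle <- bellman_ford_times(60, ed$a, ed$b, ed$weight, src)
    expect_equal(as.numeric(act), oracle, tolerance = 1e-9)
  }
})

test_that("arrival times satisfy the edge relaxation property", {
  mesh <- coarse_mesh()
  cm <- conduction_model()
  act <- solve_eikonal(mesh, cm, 37L)
  ed <- vtlocalizer:::conduction_edges(mesh, cm)
  slack <- act[ed$b] - act[ed$a] - ed$weight
  expect_lte(max(slack), 1e-9)
  slack2 <- act[ed$a] - act[ed$b] - ed$weight
  expect_lte(max(slack2), 1e-9)
})

test_that("velocity scaling divides activation times exactly", {
  mesh <- coarse_mesh()
  a1 <- solve_eikonal(mesh, conduction_model(0.6, 0.24), 10L)
  a2 <- solve_eikonal(mesh, conduction_model(1.2, 0.48), 10L)
  expect_equal(as.numeric(a1), 2 * as.numeric(a2), tolerance = 1e-9)
})

test_that("graph arrival overestimates the continuum time within 15%", {
  # isotropic medium: graph distance vs straight-line distance
  mesh <- coarse_mesh()
  cm <- conduction_model(cv_long = 0.6, cv_trans = 0.6)
  src <- mesh$apex_node
  act <- solve_eikonal(mesh, cm, src)
  straight <- sqrt(rowSums((mesh$nodes -
    rep(mesh$nodes[src, ], each = nrow(mesh$nodes)))^2)) / 0.6
  far <- straight > 20 / 0.6                 # ignore the near field
  ratio <- act / straight
  expect_true(all(ratio[far] >= 1 - 1e-9))   # never faster than straight line
  expect_lt(max(ratio[far]), 1.35)           # geodesic around the cavity wall
  # on a quasi-straight path (same meridian) the overestimate is small
  u <- coarse_uvc()
  same_meridian <- abs(wrap_angle(u[, "phi"] - u[src, "phi"])) < 0.2 &
    u[, "rho"] > 0.9 & far
  expect_gt(sum(same_meridian), 0)
  expect_lt(max(ratio[same_meridian]), 1.15)
})

test_that("vm synthesis follows the template and its invariants", {
  tpl <- ap_template()
  act <- structure(c(0, 10, Inf), class = "activation_map")
  vm <- synthesize_vm_traces(act, tpl, dt = 1, duration = 340)
  expect_equal(vm[1, 3], 20)                   # t = 2 ms: upstroke complete
  expect_equal(unname(vm[3, ]), rep(-85, 340)) # unreached stays at rest
  expect_true(all(vm >= -85 & vm <= 20))
  # time invariance: a shift by 10 samples
  expect_equal(vm[2, 11:340], vm[1, 1:330])
  expect_error(synthesize_vm_traces(act, tpl, 1, duration = 100),
               "truncation")
})
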