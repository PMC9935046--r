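# Shared fixtures, built once per test run and memoised in this
# environment. Coarse meshes keep the unit suite fast; the acceptance
# tests build their own study-scale objects via helper-study.R.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

coarse_params <- function(edge = 7, seed = 11L) {
  geometry_params(target_edge_length = edge, seed = seed)
}

coarse_mesh <- function() memo("coarse_mesh", function() {
  build_ventricle_mesh(coarse_params(), "fix-coarse")
})

coarse_uvc <- function() memo("coarse_uvc", function() compute_uvc(coarse_mesh()))

# 4 mm mesh: fine enough to resolve scar lobes
fine_mesh <- function() memo("fine_mesh", function() {
  build_ventricle_mesh(geometry_params(target_edge_length = 4, seed = 5L),
                       "fix-fine")
})

fine_uvc <- function() memo("fine_uvc", function() compute_uvc(fine_mesh()))

fine_bundle <- function() memo("fine_bundle", function() {
  build_anatomy(geometry_params(target_edge_length = 4, seed = 5L),
                "fix-fine", electrode_jitter = 0)
})

# tiny two-anatomy library pair for localizer plumbing tests
tiny_libs <- function() memo("tiny_libs", function() {
  cohort <- make_cohort(2, geometry_params(target_edge_length = 4), 21L)
  cfg <- library_config(cohort, n_paced_per_anatomy = 40,
                        n_vt_per_anatomy = 8, global_seed = 21L)
  bundles <- build_bundles(cfg)
  list(cfg = cfg,
       pacing = build_pacing_library(cfg, bundles),
       vt = build_vt_library(cfg, bundles))
})

# independent Bellman-Ford relaxation oracle over an explicit edge list
bellman_ford_times <- function(n_nodes, edges_a, edges_b, weights, sources,
                               offsets = NULL) {
  offsets <- offsets %||% rep(0, length(sources))
  dist <- rep(Inf, n_nodes)
  dist[sources] <- pmin(dist[sources], offsets)
  repeat {
    changed <- FALSE
    for (k in seq_along(edges_a)) {
      a <- edges_a[k]; b <- edges_b[k]; w <- weights[k]
      if (dist[a] + w < dist[b] - 1e-12) { dist[b] <- dist[a] + w; changed <- TRUE }
      if (dist[b] + w < dist[a] - 1e-12) { dist[a] <- dist[b] + w; changed <- TRUE }
    }
    if (!changed) break
  }
  dist
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random tetrahedral "mesh" stub over scattered points (graph-level tests)
random_tet_mesh <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- matrix(runif(n_nodes * 3, 0, 40), n_nodes, 3)
  # connect via random tetrahedra over nearby nodes
  elements <- t(replicate(3 * n_nodes, sample(n_nodes, 4)))
  fibers <- matrix(rnorm(nrow(elements) * 3), ncol = 3)
  fibers <- fibers / sqrt(rowSums(fibers^2))
  structure(list(nodes = nodes, elements = elements, fiber_dirs = fibers,
                 surface_labels = rep("interior", n_nodes),
                 apex_node = 1L, septal_ref_dir = c(-1, 0, 0),
                 anatomy_id = "random", params = NULL,
                 node_depth = rep(0.5, n_nodes),
                 node_tfrac = rep(0.5, n_nodes), geom = NULL),
            class = "ventricular_mesh")
}
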