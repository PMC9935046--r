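#' Anisotropic conduction model
#'
#' Conduction velocities along (`cv_long`) and across (`cv_trans`) the
#' fiber direction, in m/s (equivalently mm/ms), plus a per-element
#' multiplier in `[0, 1]` scaling local velocity: 0 marks inexcitable
#' tissue (scar), values below 1 slow conduction (isthmus).
#'
#' @param cv_long Longitudinal conduction velocity (m/s). Default 0.6.
#' @param cv_trans Transverse conduction velocity (m/s). Default 0.24.
#' @param element_multiplier Optional numeric per-element multiplier; when
#'   `NULL` all elements conduct at full speed.
#' @return A `conduction_model` list.
#' @export
conduction_model <- function(cv_long = 0.6, cv_trans = 0.24,
                             element_multiplier = NULL) {
  stopifnot(cv_long >= cv_trans, cv_trans > 0)
  if (!is.null(element_multiplier)) {
    stopifnot(all(element_multiplier >= 0), all(element_multiplier <= 1))
  }
  structure(list(cv_long = cv_long, cv_trans = cv_trans,
                 element_multiplier = element_multiplier),
            class = "conduction_model")
}

elem_multipliers <- function(cm, n_elem) {
  if (is.null(cm$element_multiplier)) rep(1, n_elem) else {
    stopifnot(length(cm$element_multiplier) == n_elem)
    cm$element_multiplier
  }
}

#' Traversal time of one mesh edge under anisotropic conduction
#'
#' The edge is traversed at speed `mult * v(theta)` where
#' `v(theta) = sqrt((cv_long cos(theta))^2 + (cv_trans sin(theta))^2)`
#' and `theta` is the angle between the edge and the local fiber
#' direction. With positions in mm and velocities in m/s the result is
#' in ms. A zero multiplier marks the edge absent (`Inf`).
#'
#' @param p_a,p_b Edge endpoint positions (mm).
#' @param fiber Unit fiber direction of the local element.
#' @param cm A [conduction_model()].
#' @param mult Local velocity multiplier in `[0, 1]`.
#' @return Traversal time in ms (`Inf` when `mult = 0`).
#' @export
edge_traversal_time <- function(p_a, p_b, fiber, cm, mult = 1) {
  d <- as.numeric(p_b) - as.numeric(p_a)
  len <- sqrt(sum(d^2))
  if (mult <= 0) return(Inf)
  if (len == 0) return(0)
  ct <- sum(d * fiber) / len
  ct2 <- min(1, ct^2)
  v <- sqrt((cm$cv_long^2) * ct2 + (cm$cv_trans^2) * (1 - ct2))
  len / (mult * v)
}

# Unique undirected edge list of the tet mesh with anisotropic weights.
# Each tet contributes its 6 edges; an edge shared by several elements
# takes the fastest incident traversal (so a fully conductive neighbour
# suffices for local conduction, matching the max-multiplier rule).
conduction_edges <- function(mesh, cm) {
  el <- mesh$elements
  n <- nrow(mesh$nodes)
  mult <- elem_multipliers(cm, nrow(el))
  pairs <- rbind(el[, c(1, 2)], el[, c(1, 3)], el[, c(1, 4)],
                 el[, c(2, 3)], el[, c(2, 4)], el[, c(3, 4)])
  eid <- rep(seq_len(nrow(el)), 6)
  a <- pmin(pairs[, 1], pairs[, 2])
  b <- pmax(pairs[, 1], pairs[, 2])
  dvec <- mesh$nodes[b, , drop = FALSE] - mesh$nodes[a, , drop = FALSE]
  len <- sqrt(rowSums(dvec^2))
  f <- mesh$fiber_dirs[eid, , drop = FALSE]
  ct2 <- pmin(1, (rowSums(dvec * f) / pmax(len, 1e-12))^2)
  v <- mult[eid] * sqrt(cm$cv_long^2 * ct2 + cm$cv_trans^2 * (1 - ct2))
  key <- (a - 1) * n + b
  o <- order(key, -v)
  first <- !duplicated(key[o])
  sel <- o[first]
  keep <- v[sel] > 0
  sel <- sel[keep]
  list(a = a[sel], b = b[sel], weight = len[sel] / v[sel], n_nodes = n)
}

conduction_graph <- function(mesh, cm) {
  ed <- conduction_edges(mesh, cm)
  g <- igraph::make_empty_graph(n = ed$n_nodes, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ed$a, ed$b))
  igraph::E(g)$weight <- ed$weight
  g
}

source_excitable <- function(mesh, cm, node) {
  mult <- elem_multipliers(cm, nrow(mesh$elements))
  hit <- mesh$elements == node
  any(mult[which(rowSums(hit) > 0)] > 0)
}

#' Solve the graph-eikonal activation problem
#'
#' Computes earliest arrival times over the mesh edge graph from one or
#' more sources with per-source onset offsets, using Dijkstra shortest
#' paths with anisotropic edge traversal times. Nodes unreachable through
#' excitable tissue are `Inf`.
#'
#' @param mesh A `ventricular_mesh`.
#' @param cm A [conduction_model()].
#' @param sources List of `list(node =, offset =)` entries, or an integer
#'   vector of source nodes (zero offsets).
#' @return An `activation_map`: numeric per-node activation time (ms)
#'   with attribute `sources`.
#' @export
solve_eikonal <- function(mesh, cm, sources) {
  if (is.numeric(sources)) {
    sources <- lapply(as.integer(sources), function(k) list(node = k, offset = 0))
  }
  stopifnot(length(sources) >= 1)
  nodes <- vapply(sources, function(s) as.integer(s$node), integer(1))
  offs <- vapply(sources, function(s) as.numeric(s$offset %||% 0), numeric(1))
  stopifnot(all(nodes >= 1), all(nodes <= nrow(mesh$nodes)), all(offs >= 0))
  if (!any(vapply(nodes, function(k) source_excitable(mesh, cm, k), logical(1)))) {
    stop("all sources inexcitable")
  }
  g <- conduction_graph(mesh, cm)
  d <- igraph::distances(g, v = nodes, algorithm = "dijkstra")
  act <- do.call(pmin, lapply(seq_along(nodes), function(i) offs[i] + d[i, ]))
  structure(as.numeric(act), class = "activation_map", sources = sources)
}

# activation times from many independent single sources in one call;
# returns sources x nodes matrix
eikonal_many <- function(mesh, cm, source_nodes) {
  g <- conduction_graph(mesh, cm)
  igraph::distances(g, v = source_nodes, algorithm = "dijkstra")
}

#' Stereotyped action-potential template
#'
#' Piecewise-linear upstroke/plateau/repolarization waveform used to turn
#' activation times into transmembrane potential traces.
#'
#' @param resting Resting potential (mV). Default -85.
#' @param plateau Plateau potential (mV). Default +20.
#' @param upstroke Upstroke duration (ms). Default 2.
#' @param apd Action potential duration (ms). Default 280.
#' @param repol Repolarization duration (ms). Default 40.
#' @return An `ap_template` list.
#' @export
ap_template <- function(resting = -85, plateau = 20, upstroke = 2,
                        apd = 280, repol = 40) {
  stopifnot(plateau > resting, upstroke > 0, apd > 0, repol > 0)
  structure(list(resting = resting, plateau = plateau, upstroke = upstroke,
                 apd = apd, repol = repol), class = "ap_template")
}

#' Synthesize transmembrane potential traces from an activation map
#'
#' Every activated node follows the template shifted by its activation
#' time: resting before activation, a linear upstroke, a plateau until
#' `act + apd`, then a linear return to rest. Unreached nodes stay at the
#' resting potential.
#'
#' @param act An `activation_map` (ms; `Inf` = unreached).
#' @param tpl An [ap_template()].
#' @param dt Sample interval (ms). Default 1.
#' @param duration Trace duration (ms); must cover the latest activation
#'   plus the action potential duration.
#' @return nodes x time matrix of potentials (mV); attribute `dt`.
#' @export
synthesize_vm_traces <- function(act, tpl, dt = 1, duration) {
  stopifnot(dt > 0)
  a <- as.numeric(act)
  amax <- suppressWarnings(max(a[is.finite(a)]))
  if (!is.finite(amax)) amax <- 0
  if (duration < amax + tpl$apd) {
    stop("truncation error: duration shorter than latest activation + APD")
  }
  times <- seq(0, duration - dt, by = dt)
  amp <- tpl$plateau - tpl$resting
  s <- outer(-a, times, `+`)                 # time since activation
  up <- clamp01(s / tpl$upstroke)
  down <- clamp01((s - tpl$apd) / tpl$repol)
  vm <- tpl$resting + amp * (up - down)
  vm[!is.finite(a), ] <- tpl$resting
  attr(vm, "dt") <- dt
  vm
}
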