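#' Write a mesh as a legacy ASCII VTK unstructured grid
#'
#' Plain-text export of the tetrahedral mesh with optional per-node
#' (point-data) and per-element (cell-data) scalar or vector arrays; the
#' fiber field is written as cell-data vectors and the surface labels as
#' point-data scalars by default.
#'
#' @param mesh A `ventricular_mesh`.
#' @param path Output file (.vtk).
#' @param point_data Named list of per-node arrays (length n vectors or
#'   n x 3 matrices), e.g. UVC columns or an activation map.
#' @param cell_data Named list of per-element arrays.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("ventricular mesh %s", mesh$anatomy_id)
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS %d double", n)
  utils::write.table(format(mesh$nodes, digits = 10, trim = TRUE,
                            scientific = FALSE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  wl("CELLS %d %d", m, 5L * m)
  utils::write.table(cbind(4L, mesh$elements - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  wl("CELL_TYPES %d", m)
  writeLines(rep("10", m), con)
  lab_codes <- match(mesh$surface_labels,
                     c("interior", "endocardium", "epicardium", "base",
                       "apex_node")) - 1L
  point_data <- c(list(surface_label = lab_codes), point_data)
  wl("POINT_DATA %d", n)
  write_vtk_arrays(con, point_data, n)
  cell_data <- c(list(fiber = mesh$fiber_dirs), cell_data)
  wl("CELL_DATA %d", m)
  write_vtk_arrays(con, cell_data, m)
  invisible(path)
}

write_vtk_arrays <- function(con, arrays, n_expect) {
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    if (is.matrix(a) && ncol(a) == 3) {
      stopifnot(nrow(a) == n_expect)
      writeLines(sprintf("VECTORS %s double", nm), con)
      utils::write.table(format(a, digits = 10, trim = TRUE), con,
                         row.names = FALSE, col.names = FALSE, quote = FALSE)
    } else {
      a <- as.numeric(a)
      stopifnot(length(a) == n_expect)
      writeLines(sprintf("SCALARS %s double 1", nm), con)
      writeLines("LOOKUP_TABLE default", con)
      writeLines(format(a, digits = 10, trim = TRUE), con)
    }
  }
}

#' Read back a legacy ASCII VTK unstructured grid
#'
#' Minimal reader for the files written by [write_mesh_vtk()] (points,
#' tetrahedral cells and scalar/vector data arrays).
#'
#' @param path A .vtk file.
#' @return List with `nodes`, `elements` (1-based), `point_data`,
#'   `cell_data`.
#' @export
read_mesh_vtk <- function(path) {
  ln <- readLines(path)
  toks <- function(i) strsplit(trimws(ln[i]), "\\s+")[[1]]
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(toks(ip)[2])
  nodes <- matrix(scan(text = ln[(ip + 1):(ip + n)], quiet = TRUE),
                  n, 3, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1]
  m <- as.integer(toks(ic)[2])
  cells <- matrix(scan(text = ln[(ic + 1):(ic + m)], quiet = TRUE),
                  m, 5, byrow = TRUE)
  elements <- cells[, 2:5, drop = FALSE] + 1L
  read_arrays <- function(start, count, stop_at) {
    out <- list()
    i <- start
    while (i <= length(ln) && !grepl(stop_at, ln[i])) {
      if (grepl("^SCALARS", ln[i])) {
        nm <- toks(i)[2]
        vals <- scan(text = ln[(i + 2):(i + 1 + count)], quiet = TRUE)
        out[[nm]] <- vals
        i <- i + 2 + count
      } else if (grepl("^VECTORS", ln[i])) {
        nm <- toks(i)[2]
        vals <- matrix(scan(text = ln[(i + 1):(i + count)], quiet = TRUE),
                       count, 3, byrow = TRUE)
        out[[nm]] <- vals
        i <- i + 1 + count
      } else i <- i + 1
    }
    out
  }
  ipd <- grep("^POINT_DATA", ln)
  icd <- grep("^CELL_DATA", ln)
  point_data <- if (length(ipd)) read_arrays(ipd[1] + 1, n, "^CELL_DATA") else list()
  cell_data <- if (length(icd)) read_arrays(icd[1] + 1, m, "$^") else list()
  list(nodes = nodes, elements = elements, point_data = point_data,
       cell_data = cell_data)
}
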