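# Plain-text mesh and field writers. No VTK/STL bindings ship with the
# supported R stack, so the (simple, stable) legacy ASCII formats are
# emitted directly.

REGION_CODES <- c(ascending = 0L, arch = 1L, branch1 = 2L, branch2 = 3L,
                  branch3 = 4L, TL = 5L, FL = 6L, tear_margin = 7L)

#' Write a surface mesh as ASCII STL (geometry only)
#'
#' @param mesh an \code{aorta_mesh}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_mesh_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "aorta_mesh"))
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c3 <- v[tr[, 3], , drop = FALSE]
  ab <- b - a; ac <- c3 - a
  nrm <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
               ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
               ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  ln <- sqrt(rowSums(nrm^2)); ln[ln == 0] <- 1
  nrm <- nrm / ln
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid aorta", con)
  blocks <- sprintf(
    "facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet",
    nrm[, 1], nrm[, 2], nrm[, 3],
    a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3], c3[, 1], c3[, 2], c3[, 3])
  writeLines(blocks, con)
  writeLines("endsolid aorta", con)
  invisible(path)
}

vtk_header <- function(con, mesh) {
  writeLines(c("# vtk DataFile Version 3.0", "aorta surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(mesh$vertices))), con)
  writeLines(apply(mesh$vertices, 1, function(p) paste(p, collapse = " ")), con)
  tr <- mesh$triangles - 1L
  writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4L * nrow(tr)), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
}

#' Write a labeled surface mesh as legacy VTK PolyData
#'
#' Geometry plus the region label as integer point data (\code{region}:
#' ascending 0, arch 1, branch1..3 2-4, TL 5, FL 6, tear margin 7), and
#' optionally a vector point-data field.
#'
#' @param mesh an \code{aorta_mesh}.
#' @param path output path.
#' @param vectors optional n_vertices x 3 matrix written as point vectors
#'   named \code{vectors_name}.
#' @param vectors_name name of the vector array.
#' @return invisibly, \code{path}.
#' @export
write_mesh_vtk <- function(mesh, path, vectors = NULL,
                           vectors_name = "wss_pa") {
  stopifnot(inherits(mesh, "aorta_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  vtk_header(con, mesh)
  writeLines(sprintf("POINT_DATA %d", nrow(mesh$vertices)), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(REGION_CODES[mesh$vertex_region]), con)
  if (!is.null(vectors)) {
    stopifnot(nrow(vectors) == nrow(mesh$vertices), ncol(vectors) == 3)
    writeLines(sprintf("VECTORS %s float", vectors_name), con)
    writeLines(apply(vectors, 1, function(p) paste(p, collapse = " ")), con)
  }
  invisible(path)
}

#' Write a wall-shear time series
#'
#' \code{write_wss_vtk_series} writes one VTK PolyData file per time step
#' (\code{prefix_NNNN.vtk}, vector point data \code{wss_pa}) plus a
#' \code{prefix.series} index file listing file names and times.
#' \code{write_wss_csv} writes one long-format CSV with columns
#' \code{vertex}, \code{t_s}, \code{tau_x_pa}, \code{tau_y_pa},
#' \code{tau_z_pa}.
#'
#' @param series a \code{\link{wss_series}}.
#' @param mesh the matching \code{aorta_mesh}.
#' @param prefix output path prefix for the VTK series.
#' @return invisibly, the written path(s).
#' @export
write_wss_vtk_series <- function(series, mesh, prefix) {
  stopifnot(inherits(series, "wss_series"))
  paths <- character(0)
  for (i in seq_along(series$times)) {
    p <- sprintf("%s_%04d.vtk", prefix, i - 1)
    write_mesh_vtk(mesh, p, vectors = series$values[, i, ])
    paths <- c(paths, p)
  }
  idx <- sprintf("%s.series", prefix)
  writeLines(c("# file time_s",
               sprintf("%s %g", basename(paths), series$times)), idx)
  invisible(c(paths, idx))
}

#' @rdname write_wss_vtk_series
#' @param path CSV output path for \code{write_wss_csv}.
#' @export
write_wss_csv <- function(series, path) {
  stopifnot(inherits(series, "wss_series"))
  n_v <- dim(series$values)[1]
  n_t <- dim(series$values)[2]
  d <- data.frame(
    vertex = rep(seq_len(n_v), times = n_t),
    t_s = rep(series$times, each = n_v),
    tau_x_pa = as.vector(series$values[, , 1]),
    tau_y_pa = as.vector(series$values[, , 2]),
    tau_z_pa = as.vector(series$values[, , 3]))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a wall-descriptor map
#'
#' CSV columns \code{vertex}, \code{tawss_pa}, \code{osi}, \code{rrt_inv_pa}
#' (and VTK PolyData with the same arrays as scalar point data via
#' \code{write_hwd_vtk}).
#'
#' @param map an \code{hwd_map}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_hwd_csv <- function(map, path) {
  stopifnot(inherits(map, "hwd_map"))
  utils::write.csv(data.frame(vertex = seq_along(map$tawss),
                              tawss_pa = map$tawss, osi = map$osi,
                              rrt_inv_pa = map$rrt),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hwd_csv
#' @param mesh the matching \code{aorta_mesh}.
#' @export
write_hwd_vtk <- function(map, mesh, path) {
  stopifnot(inherits(map, "hwd_map"), inherits(mesh, "aorta_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  vtk_header(con, mesh)
  writeLines(sprintf("POINT_DATA %d", nrow(mesh$vertices)), con)
  arrays <- list(tawss_pa = map$tawss, osi = map$osi, rrt_inv_pa = map$rrt)
  for (nm in names(arrays)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(as.character(arrays[[nm]]), con)
  }
  invisible(path)
}

#' Write per-plane pressure/flux series as CSV
#'
#' Long format: \code{s_mm}, \code{t_s}, \code{p_tl_pa}, \code{p_fl_pa},
#' \code{q_tl_m3s}, \code{q_fl_m3s}.
#'
#' @param planes a \code{\link{plane_series}}.
#' @param path CSV path.
#' @return invisibly, \code{path}.
#' @export
write_plane_series_csv <- function(planes, path) {
  stopifnot(inherits(planes, "plane_series"))
  n_p <- length(planes$s_mm); n_t <- length(planes$times)
  d <- data.frame(
    s_mm = rep(planes$s_mm, times = n_t),
    t_s = rep(planes$times, each = n_p),
    p_tl_pa = as.vector(planes$p_tl),
    p_fl_pa = as.vector(planes$p_fl),
    q_tl_m3s = as.vector(planes$q_tl),
    q_fl_m3s = as.vector(planes$q_fl))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a VTK PolyData surface written by this package
#'
#' Minimal reader for round-tripping the package's own legacy ASCII output:
#' points, polygons and the integer \code{region} point data.
#'
#' @param path VTK file path.
#' @return list: \code{vertices}, \code{triangles}, \code{vertex_region}.
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  pts <- matrix(scan(text = lines[(ip + 1):(ip + np)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  it <- grep("^POLYGONS", lines)[1]
  nt <- as.integer(strsplit(lines[it], " ")[[1]][2])
  tri <- matrix(scan(text = lines[(it + 1):(it + nt)], quiet = TRUE),
                ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  ir <- grep("^SCALARS region", lines)
  region <- NULL
  if (length(ir)) {
    codes <- as.integer(lines[(ir[1] + 2):(ir[1] + 1 + np)])
    region <- names(REGION_CODES)[match(codes, REGION_CODES)]
  }
  list(vertices = pts, triangles = tri, vertex_region = region)
}
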