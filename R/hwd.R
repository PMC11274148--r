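#' Hemodynamic wall descriptors from a wall-shear time series
#'
#' Computes, per vertex, the standard cycle descriptors of the wall-shear
#' vector \eqn{\tau(t)}:
#' \deqn{TAWSS = \frac{1}{T}\int_0^T |\tau|\,dt, \qquad
#'       OSI = \frac{1}{2}\left(1 -
#'         \frac{|\int_0^T \tau\,dt|}{\int_0^T |\tau|\,dt}\right), \qquad
#'       RRT = \frac{1}{(1 - 2\,OSI)\,TAWSS}.}
#' Time integrals use the composite trapezoid on the uniform periodic grid
#' (equivalent to the rectangle sum once the period wrap is included).
#' Vertices with \eqn{\int |\tau| dt = 0} get OSI 0 and an undefined
#' (infinite) RRT, flagged in \code{undefined}; the same flag marks perfect
#' reversal (OSI = 0.5), where the residence time diverges.
#'
#' @param series a \code{\link{wss_series}} spanning one period with at
#'   least 8 samples.
#' @param period cycle period (s); defaults to the series period.
#' @return object of class \code{hwd_map}: numeric vectors \code{tawss}
#'   (Pa), \code{osi}, \code{rrt} (1/Pa, possibly \code{Inf}) and logical
#'   \code{undefined}.
#' @export
compute_hwd <- function(series, period = series$period) {
  stopifnot(inherits(series, "wss_series"))
  v <- series$values
  if (dim(v)[2] < 8) stop("need at least 8 time samples spanning one period")
  if (anyNA(v)) {
    bad <- which(apply(is.na(v), 1, any))
    stop("NaN/NA wall shear at vertex id(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  dt <- period / dim(v)[2]
  mag <- sqrt(v[, , 1]^2 + v[, , 2]^2 + v[, , 3]^2)
  if (is.null(dim(mag))) mag <- matrix(mag, nrow = dim(v)[1])
  int_mag <- rowSums(mag) * dt
  ix <- rowSums(v[, , 1, drop = FALSE]) * dt
  iy <- rowSums(v[, , 2, drop = FALSE]) * dt
  iz <- rowSums(v[, , 3, drop = FALSE]) * dt
  mean_norm <- sqrt(ix^2 + iy^2 + iz^2)
  tawss <- int_mag / period
  osi <- numeric(length(tawss))
  pos <- int_mag > 0
  osi[pos] <- 0.5 * (1 - mean_norm[pos] / int_mag[pos])
  osi <- pmin(pmax(osi, 0), 0.5)
  denom <- (1 - 2 * osi) * tawss
  rrt <- ifelse(denom > 0, 1 / denom, Inf)
  structure(list(tawss = tawss, osi = osi, rrt = rrt,
                 undefined = !(denom > 0)),
            class = "hwd_map")
}

# 1/3 of the summed incident-triangle areas per vertex
vertex_area_weights <- function(mesh) {
  tr <- mesh$triangles
  a <- mesh$vertices[tr[, 1], , drop = FALSE]
  b <- mesh$vertices[tr[, 2], , drop = FALSE]
  c3 <- mesh$vertices[tr[, 3], , drop = FALSE]
  ab <- b - a; ac <- c3 - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  t_area <- sqrt(rowSums(cr^2)) / 2
  w <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    acc <- tapply(t_area, tr[, k], sum)
    ii <- as.integer(names(acc))
    w[ii] <- w[ii] + acc / 3
  }
  w
}

#' Per-region summaries of the wall descriptors
#'
#' Area-weighted means (one-third incident-triangle-area vertex weights) and
#' peaks of TAWSS, OSI and RRT for each labeled mesh region. RRT means are
#' taken over vertices with finite RRT. Requested regions with no vertices
#' are reported present = FALSE with NA summaries rather than zeros.
#'
#' @param map an \code{\link{compute_hwd}} result.
#' @param mesh the matching \code{aorta_mesh} (labels and areas).
#' @param regions regions to summarize; defaults to all labels in the mesh.
#' @return data.frame: region, present, n_vertices, mean_tawss, peak_tawss,
#'   mean_osi, mean_rrt.
#' @export
region_summary <- function(map, mesh, regions = NULL) {
  stopifnot(inherits(map, "hwd_map"), inherits(mesh, "aorta_mesh"))
  if (length(map$tawss) != nrow(mesh$vertices)) {
    stop("descriptor map and mesh have different vertex counts")
  }
  if (is.null(regions)) regions <- unique(mesh$vertex_region)
  w <- vertex_area_weights(mesh)
  rows <- lapply(regions, function(rg) {
    idx <- which(mesh$vertex_region == rg)
    if (length(idx) == 0) {
      return(data.frame(region = rg, present = FALSE, n_vertices = 0L,
                        mean_tawss = NA_real_, peak_tawss = NA_real_,
                        mean_osi = NA_real_, mean_rrt = NA_real_))
    }
    wi <- w[idx]
    fin <- is.finite(map$rrt[idx])
    data.frame(
      region = rg, present = TRUE, n_vertices = length(idx),
      mean_tawss = sum(wi * map$tawss[idx]) / sum(wi),
      peak_tawss = max(map$tawss[idx]),
      mean_osi = sum(wi * map$osi[idx]) / sum(wi),
      mean_rrt = if (any(fin)) {
        sum(wi[fin] * map$rrt[idx][fin]) / sum(wi[fin])
      } else NA_real_)
  })
  do.call(rbind, rows)
}

#' Entry-tear-margin TAWSS statistic
#'
#' Peak TAWSS over the tear-margin vertices distributed over the tear
#' perimeter: the default statistic is (peak margin TAWSS) x (tear
#' perimeter), in Pa mm. A line-integral style alternative uses the mean
#' margin TAWSS instead of the peak (\code{method = "line_integral"},
#' approximating \eqn{\oint TAWSS\, dl}).
#'
#' @param map an \code{\link{compute_hwd}} result.
#' @param tear a \code{\link{tear_metrics}} result (supplies the perimeter).
#' @param mesh the matching \code{aorta_mesh} (supplies margin labels).
#' @param method "peak_perimeter" (default) or "line_integral".
#' @return statistic in Pa mm.
#' @export
tear_margin_tawss <- function(map, tear, mesh,
                              method = c("peak_perimeter", "line_integral")) {
  method <- match.arg(method)
  stopifnot(inherits(map, "hwd_map"), inherits(tear, "tear_geometry"))
  if (tear$perimeter <= 0) stop("tear perimeter must be > 0")
  idx <- which(mesh$vertex_region == "tear_margin")
  if (length(idx) == 0) stop("mesh has no tear_margin vertices")
  stat <- switch(method,
                 peak_perimeter = max(map$tawss[idx]),
                 line_integral = mean(map$tawss[idx]))
  stat * tear$perimeter
}
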