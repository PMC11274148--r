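#' Vessel centerline
#'
#' Ordered polyline of centerline points (mm) with cumulative arclength.
#' Consecutive duplicate points are rejected so the arclength is strictly
#' increasing.
#'
#' @param points numeric matrix, one row per point, columns x,y,z in mm.
#' @return object of class \code{vessel_centerline} with \code{points} and
#'   \code{arclength} (mm, starting at 0).
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2 || ncol(points) != 3) {
    stop("centerline needs >= 2 points with x,y,z columns")
  }
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg <= 0)) stop("centerline arclength must be strictly increasing")
  structure(list(points = points, arclength = c(0, cumsum(seg))),
            class = "vessel_centerline")
}

#' Centerline tortuosity
#'
#' Arc-chord ratio: total centerline arclength divided by the straight-line
#' distance between its first and last points. Always >= 1; equals 1 only for
#' a straight path.
#'
#' @param cl a \code{\link{centerline}}.
#' @return single numeric tortuosity.
#' @export
tortuosity <- function(cl) {
  stopifnot(inherits(cl, "vessel_centerline"))
  p <- cl$points
  chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  if (chord < 1e-9) stop("tortuosity undefined: coincident endpoints")
  cl$arclength[length(cl$arclength)] / chord
}

# linear interpolation of point and unit tangent at arclength s (mm)
centerline_at <- function(cl, s) {
  al <- cl$arclength
  if (s < al[1] - 1e-9 || s > al[length(al)] + 1e-9) {
    stop("arclength ", s, " outside centerline span [",
         al[1], ", ", al[length(al)], "]")
  }
  s <- min(max(s, al[1]), al[length(al)])
  i <- max(1, findInterval(s, al, rightmost.closed = TRUE))
  i <- min(i, length(al) - 1)
  w <- (s - al[i]) / (al[i + 1] - al[i])
  p <- (1 - w) * cl$points[i, ] + w * cl$points[i + 1, ]
  tg <- cl$points[i + 1, ] - cl$points[i, ]
  list(point = p, tangent = tg / sqrt(sum(tg^2)))
}

#' Read / write centerline CSV (columns x_mm, y_mm, z_mm)
#'
#' @param path CSV file path.
#' @return \code{read_centerline_csv} returns a \code{centerline}.
#' @export
read_centerline_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(d))) {
    stop("centerline CSV must have columns ", paste(need, collapse = ", "))
  }
  centerline(as.matrix(d[, need]))
}

#' @rdname read_centerline_csv
#' @param cl a \code{centerline} to write.
#' @export
write_centerline_csv <- function(cl, path) {
  p <- cl$points
  utils::write.csv(data.frame(x_mm = p[, 1], y_mm = p[, 2], z_mm = p[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}
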