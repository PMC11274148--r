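#' Entry tear geometry from height and width
#'
#' The tear opening is summarized by a circle of effective diameter
#' \eqn{d = (h + w)/2} (the mean of the measured height and width), giving
#' area \eqn{\pi d^2/4} and perimeter \eqn{\pi d}. For \code{h == w} this is
#' the exact circle. An elliptical alternative (area \eqn{\pi h w / 4},
#' Ramanujan perimeter) is available via \code{method = "ellipse"}.
#'
#' @param height tear height, distance between upper and lower edges (mm).
#' @param width tear width, maximal transverse size (mm).
#' @param method "circle" (mean-diameter circle, default) or "ellipse".
#' @param location optional arclength of the tear center along the
#'   descending centerline (mm).
#' @return list of class \code{tear_geometry}: \code{height}, \code{width},
#'   \code{area} (mm^2), \code{perimeter} (mm), \code{location}.
#' @export
tear_metrics <- function(height, width, method = c("circle", "ellipse"),
                         location = NA_real_) {
  method <- match.arg(method)
  if (height <= 0 || width <= 0) stop("tear height and width must be > 0")
  if (method == "circle") {
    d <- (height + width) / 2
    area <- pi * d^2 / 4
    perim <- pi * d
  } else {
    a <- height / 2; b <- width / 2
    area <- pi * a * b
    h <- ((a - b) / (a + b))^2
    perim <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  }
  structure(list(height = height, width = width, area = area,
                 perimeter = perim, location = location, method = method),
            class = "tear_geometry")
}

# --- mesh-plane slicing ----------------------------------------------------

# intersect a set of triangles with the plane through p0 with unit normal nrm;
# returns list of 2x2 matrices of (u,v) in-plane coordinates plus the
# originating triangle row index
slice_triangles <- function(vertices, triangles, p0, nrm, basis) {
  d <- as.vector((vertices - matrix(p0, nrow(vertices), 3, byrow = TRUE)) %*% nrm)
  d[abs(d) < 1e-9] <- 1e-9
  dv <- matrix(d[t(triangles)], ncol = 3, byrow = TRUE)
  cross <- which(!(rowSums(dv > 0) %in% c(0L, 3L)))
  segs <- vector("list", length(cross))
  for (k in seq_along(cross)) {
    tri <- triangles[cross[k], ]
    dd <- dv[cross[k], ]
    pts <- matrix(0, 0, 2)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      if (dd[e[1]] * dd[e[2]] < 0) {
        w <- dd[e[1]] / (dd[e[1]] - dd[e[2]])
        pp <- (1 - w) * vertices[tri[e[1]], ] + w * vertices[tri[e[2]], ]
        rel <- pp - p0
        pts <- rbind(pts, c(sum(rel * basis[, 1]), sum(rel * basis[, 2])))
      }
    }
    if (nrow(pts) == 2) segs[[k]] <- pts
  }
  keep <- !vapply(segs, is.null, logical(1))
  list(segments = segs[keep], tri_index = cross[keep])
}

# chain 2D segments into a single closed polygon; error if open
chain_loop <- function(segs, tol, what = "wall") {
  n <- length(segs)
  if (n < 3) stop("plane misses mesh (", what, "): too few intersections")
  ends <- do.call(rbind, lapply(segs, function(s) c(s[1, ], s[2, ])))
  used <- rep(FALSE, n)
  loop <- segs[[1]]
  used[1] <- TRUE
  cur <- loop[2, ]
  for (step in seq_len(n - 1)) {
    d1 <- (ends[, 1] - cur[1])^2 + (ends[, 2] - cur[2])^2
    d2 <- (ends[, 3] - cur[1])^2 + (ends[, 4] - cur[2])^2
    d1[used] <- Inf; d2[used] <- Inf
    if (min(d1) <= min(d2)) {
      j <- which.min(d1)
      if (d1[j] > tol^2) stop("open contour after slicing region '", what, "'")
      nxt <- segs[[j]][2, ]
    } else {
      j <- which.min(d2)
      if (d2[j] > tol^2) stop("open contour after slicing region '", what, "'")
      nxt <- segs[[j]][1, ]
    }
    used[j] <- TRUE
    loop <- rbind(loop, nxt)
    cur <- nxt
  }
  if (sum((loop[nrow(loop), ] - loop[1, ])^2) > tol^2) {
    stop("open contour after slicing region '", what, "': loop does not close")
  }
  loop
}

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# clip polygon to the half-plane {x : dot(x - a, m) >= 0} (Sutherland-Hodgman)
clip_halfplane <- function(poly, a, m) {
  n <- nrow(poly)
  out <- matrix(0, 0, 2)
  s <- as.vector((poly - matrix(a, n, 2, byrow = TRUE)) %*% m)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (s[i] >= 0) out <- rbind(out, poly[i, ])
    if (s[i] * s[j] < 0) {
      w <- s[i] / (s[i] - s[j])
      out <- rbind(out, (1 - w) * poly[i, ] + w * poly[j, ])
    }
  }
  out
}

#' Cross-sectional lumen areas at an arclength station
#'
#' Slices the descending-aorta wall with the plane normal to the centerline
#' at arclength \code{s}, chains the intersection into a closed contour, and
#' measures areas by the planar shoelace formula. When the intimal flap is
#' present at \code{s} the wall contour is split by the flap chord into true
#' and false lumen; otherwise the whole section is reported as TL.
#'
#' @param mesh an \code{aorta_mesh} from \code{\link{build_dissected_geometry}}.
#' @param cl the matching descending-aorta \code{\link{centerline}}.
#' @param s arclength station (mm along the descending centerline).
#' @return list: \code{tl_area}, \code{fl_area}, \code{total_area} (mm^2),
#'   \code{equiv_diameter} (mm).
#' @export
section_areas <- function(mesh, cl, s) {
  stopifnot(inherits(mesh, "aorta_mesh"), inherits(cl, "vessel_centerline"))
  loc <- centerline_at(cl, s)
  nrm <- loc$tangent
  ref <- c(1, 0, 0)
  if (abs(sum(ref * nrm)) > 0.9) ref <- c(0, 1, 0)
  u <- ref - sum(ref * nrm) * nrm; u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  basis <- cbind(u, v)

  desc_regions <- c("TL", "FL")
  tri_lab <- matrix(mesh$vertex_region[t(mesh$triangles)] %in% desc_regions,
                    ncol = 3, byrow = TRUE)
  wall_rows <- which(mesh$triangle_component == "wall" & rowSums(tri_lab) == 3)
  # keep triangles near the station so the infinite plane cannot pick up
  # other segments of the vessel
  tri_s <- matrix(mesh$vertex_s[t(mesh$triangles[wall_rows, , drop = FALSE])],
                  ncol = 3, byrow = TRUE)
  near <- abs(rowMeans(tri_s) - s) < 6 * mesh$params$ds
  wall_rows <- wall_rows[near]
  if (length(wall_rows) == 0) stop("plane misses mesh: no descending wall near s = ", s)

  sl <- slice_triangles(mesh$vertices, mesh$triangles[wall_rows, , drop = FALSE],
                        loc$point, nrm, basis)
  tol <- max(1.0, mesh$params$ds) * 1.5
  loop <- chain_loop(sl$segments, tol, "wall")
  total <- shoelace_area(loop)

  flap_rows <- which(mesh$triangle_component == "flap")
  tl_area <- total; fl_area <- 0
  if (length(flap_rows) > 0) {
    tri_sf <- matrix(mesh$vertex_s[t(mesh$triangles[flap_rows, , drop = FALSE])],
                     ncol = 3, byrow = TRUE)
    nearf <- abs(rowMeans(tri_sf) - s) < 6 * mesh$params$ds
    slf <- slice_triangles(mesh$vertices,
                           mesh$triangles[flap_rows[nearf], , drop = FALSE],
                           loc$point, nrm, basis)
    if (length(slf$segments) > 0) {
      fp <- do.call(rbind, slf$segments)
      # chord through the two extreme flap intersection points
      dmat <- as.matrix(stats::dist(fp))
      ij <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
      a <- fp[ij[1], ]; b <- fp[ij[2], ]
      dir <- (b - a) / sqrt(sum((b - a)^2))
      m <- c(-dir[2], dir[1])
      # which side is TL: majority vote of wall intersection points from
      # TL-labeled triangles
      tl_tri <- vapply(seq_along(sl$tri_index), function(k) {
        labs <- mesh$vertex_region[mesh$triangles[wall_rows[sl$tri_index[k]], ]]
        sum(labs == "TL") >= 2
      }, logical(1))
      if (any(tl_tri)) {
        tl_pts <- do.call(rbind, sl$segments[tl_tri])
        side <- mean((tl_pts[, 1] - a[1]) * m[1] + (tl_pts[, 2] - a[2]) * m[2])
        mm <- if (side >= 0) m else -m
        tl_poly <- clip_halfplane(loop, a, mm)
        tl_area <- if (nrow(tl_poly) >= 3) shoelace_area(tl_poly) else 0
        fl_area <- total - tl_area
      }
    }
  }
  list(tl_area = tl_area, fl_area = fl_area, total_area = total,
       equiv_diameter = 2 * sqrt(total / pi))
}

#' True-lumen to descending-aorta area ratio
#'
#' Mean of TL/(TL+FL) over three cross-section planes. By default the planes
#' sit at configurable fractions of the descending arclength standing in for
#' the proximal (above the left pulmonary artery), mid (left inferior
#' pulmonary vein) and distal (diaphragm) anatomical stations.
#'
#' @inheritParams section_areas
#' @param s_planes arclengths of the three planes (mm); default
#'   \code{fractions} of the descending span.
#' @param fractions plane locations as fractions of descending arclength.
#' @return mean TL/DA area ratio in [0, 1].
#' @export
tl_da_ratio <- function(mesh, cl, s_planes = NULL,
                        fractions = c(0.15, 0.5, 0.85)) {
  if (is.null(s_planes)) {
    s_planes <- fractions * max(cl$arclength)
  }
  ratios <- vapply(s_planes, function(s) {
    a <- section_areas(mesh, cl, s)
    a$tl_area / (a$tl_area + a$fl_area)
  }, numeric(1))
  mean(ratios)
}

# --- diameter tables and growth --------------------------------------------

#' Longitudinal diameter table
#'
#' Diameters (mm) at the three descending-aorta surveillance planes across
#' follow-up scans.
#'
#' @param times scan times in years from baseline (>= 2 scans).
#' @param diameters numeric matrix, one row per scan, one column per plane.
#' @param planes plane names.
#' @return data.frame of class \code{diameter_table} with column
#'   \code{t_years} then one column per plane.
#' @export
diameter_table <- function(times, diameters,
                           planes = c("d_prox", "d_mid", "d_dist")) {
  diameters <- as.matrix(diameters)
  if (length(times) < 2) stop("need at least 2 scans to assess growth")
  if (nrow(diameters) != length(times)) stop("one diameter row per scan time")
  if (any(diameters <= 0)) stop("diameters must be > 0")
  if (any(diff(times) <= 0)) stop("scan times must be increasing")
  d <- data.frame(t_years = times)
  d[planes] <- diameters
  class(d) <- c("diameter_table", "data.frame")
  d
}

#' Classify aortic growth as rapid or stable
#'
#' Per-plane growth rate is the endpoint slope (last minus first diameter
#' over elapsed time). The aorta is labeled \code{rapid} when at least one
#' plane grows at or above the threshold (inclusive), by default 3 mm/year,
#' and \code{stable} otherwise.
#'
#' @param table a \code{\link{diameter_table}}.
#' @param threshold rapid-growth threshold (mm/year).
#' @return list of class \code{growth_result}: \code{rates} (per plane,
#'   mm/yr), \code{max_rate}, \code{label}.
#' @export
classify_growth <- function(table, threshold = 3) {
  stopifnot(inherits(table, "diameter_table"))
  if (nrow(table) < 2) stop("need at least 2 scans to assess growth")
  tt <- table$t_years
  dcols <- setdiff(names(table), "t_years")
  rates <- vapply(dcols, function(cn) {
    (table[[cn]][nrow(table)] - table[[cn]][1]) / (tt[length(tt)] - tt[1])
  }, numeric(1))
  mx <- max(rates)
  structure(list(rates = rates, max_rate = mx,
                 label = if (mx >= threshold) "rapid" else "stable",
                 threshold = threshold),
            class = "growth_result")
}

#' Read / write a diameter table CSV (t_years, d_prox, d_mid, d_dist)
#' @param path CSV path.
#' @return \code{read_diameter_csv} returns a \code{diameter_table}.
#' @export
read_diameter_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("t_years", "d_prox", "d_mid", "d_dist")
  if (!all(need %in% names(d))) {
    stop("diameter CSV must have columns ", paste(need, collapse = ", "))
  }
  diameter_table(d$t_years, as.matrix(d[, need[-1]]))
}

#' @rdname read_diameter_csv
#' @param table a \code{diameter_table} to write.
#' @export
write_diameter_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
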