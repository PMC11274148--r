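#' Parameters of the idealized dissected aorta
#'
#' Describes one synthetic residual type B dissection geometry: a tube of
#' radius \code{da_radius} swept along an ascending segment, an arch
#' semicircle carrying three supra-aortic branch tubes, and a descending
#' segment whose cross-section is split by a zero-thickness planar intimal
#' flap into true lumen (TL) and false lumen (FL). The flap carries one
#' elliptical entry tear; \code{centerline_amplitude}/\code{wavelength}
#' impose a sinusoidal out-of-plane perturbation on the descending
#' centerline that controls tortuosity.
#'
#' \code{flap_angle_fraction} is the fraction of the descending cross-section
#' assigned to the TL; the boundary value 1 builds an undissected tube (no
#' flap, no tear), useful as a control geometry.
#'
#' @param da_radius descending-aorta lumen radius (mm).
#' @param centerline_amplitude amplitude of the sinusoidal perturbation (mm).
#' @param wavelength wavelength of the perturbation (mm).
#' @param flap_angle_fraction TL area fraction of the descending section,
#'   in (0, 1]; 1 means no dissection.
#' @param tear_height entry tear height, axial extent (mm).
#' @param tear_width entry tear width, transverse extent (mm).
#' @param tear_arclength tear center location, mm distal to the arch along
#'   the descending centerline.
#' @param n_reentry_tears number of distal re-entry communications (recorded
#'   as a feature; not meshed).
#' @param branch_radii radii of the three arch branch tubes (mm).
#' @param waveform_scale multiplicative factor applied to the inflow
#'   waveform when synthesizing fields.
#' @param noise_sd standard deviation of additive Gaussian noise on
#'   synthesized wall-shear vectors (Pa).
#' @param seed integer seed; fully determines all generated output.
#' @param asc_length,arch_radius,desc_length segment dimensions (mm).
#' @param n_theta circumferential resolution of the swept tube.
#' @param ds axial ring spacing (mm).
#' @param flap_n transverse resolution of the flap strip.
#' @return validated list of class \code{dissection_params}.
#' @export
dissection_params <- function(da_radius = 15,
                              centerline_amplitude = 8,
                              wavelength = 120,
                              flap_angle_fraction = 0.4,
                              tear_height = 12,
                              tear_width = 10,
                              tear_arclength = 40,
                              n_reentry_tears = 1,
                              branch_radii = c(6, 4, 5),
                              waveform_scale = 1,
                              noise_sd = 0.05,
                              seed = 1L,
                              asc_length = 60,
                              arch_radius = 40,
                              desc_length = 200,
                              n_theta = 64,
                              ds = 2,
                              flap_n = 16) {
  p <- list(da_radius = da_radius, centerline_amplitude = centerline_amplitude,
            wavelength = wavelength, flap_angle_fraction = flap_angle_fraction,
            tear_height = tear_height, tear_width = tear_width,
            tear_arclength = tear_arclength,
            n_reentry_tears = as.integer(n_reentry_tears),
            branch_radii = branch_radii, waveform_scale = waveform_scale,
            noise_sd = noise_sd, seed = as.integer(seed),
            asc_length = asc_length, arch_radius = arch_radius,
            desc_length = desc_length, n_theta = as.integer(n_theta),
            ds = ds, flap_n = as.integer(flap_n))
  lens <- c(da_radius, wavelength, tear_height, tear_width, tear_arclength,
            branch_radii, asc_length, arch_radius, desc_length, ds)
  if (any(lens <= 0)) stop("all length parameters must be > 0")
  if (centerline_amplitude < 0) stop("centerline_amplitude must be >= 0")
  if (flap_angle_fraction <= 0 || flap_angle_fraction > 1) {
    stop("flap_angle_fraction must be in (0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(branch_radii) != 3) stop("branch_radii must have length 3")
  if (p$n_theta < 12 || p$flap_n < 4) stop("mesh resolution too coarse")
  class(p) <- "dissection_params"
  p
}

# chord offset d (in units of radius r) so the circular segment {x > d}
# has area fraction frac of the full disc
chord_offset_for_fraction <- function(frac, r) {
  if (frac <= 0) return(r)
  if (frac >= 1) return(-r)
  f <- function(theta) (theta - sin(theta)) / (2 * pi) - frac
  theta <- stats::uniroot(f, c(1e-9, 2 * pi - 1e-9), tol = 1e-12)$root
  r * cos(theta / 2)
}

# parallel-transport orthonormal frames along a polyline
transport_frames <- function(points) {
  n <- nrow(points)
  tg <- matrix(0, n, 3)
  tg[1, ] <- points[2, ] - points[1, ]
  tg[n, ] <- points[n, ] - points[n - 1, ]
  if (n > 2) tg[2:(n - 1), ] <- points[3:n, ] - points[1:(n - 2), ]
  tg <- tg / sqrt(rowSums(tg^2))
  nor <- matrix(0, n, 3)
  ref <- c(1, 0, 0)
  if (abs(sum(ref * tg[1, ])) > 0.9) ref <- c(0, 1, 0)
  v <- ref - sum(ref * tg[1, ]) * tg[1, ]
  nor[1, ] <- v / sqrt(sum(v^2))
  for (i in 2:n) {
    # rotate previous normal by the minimal rotation taking t_{i-1} to t_i
    a <- tg[i - 1, ]; b <- tg[i, ]
    axis <- c(a[2] * b[3] - a[3] * b[2],
              a[3] * b[1] - a[1] * b[3],
              a[1] * b[2] - a[2] * b[1])
    s <- sqrt(sum(axis^2)); cth <- sum(a * b)
    if (s < 1e-12) {
      nor[i, ] <- nor[i - 1, ]
    } else {
      axis <- axis / s
      v <- nor[i - 1, ]
      uxv <- c(axis[2] * v[3] - axis[3] * v[2],
               axis[3] * v[1] - axis[1] * v[3],
               axis[1] * v[2] - axis[2] * v[1])
      nor[i, ] <- v * cth + uxv * s + axis * sum(axis * v) * (1 - cth)
    }
    # re-orthogonalize against accumulation of numerical drift
    v <- nor[i, ] - sum(nor[i, ] * tg[i, ]) * tg[i, ]
    nor[i, ] <- v / sqrt(sum(v^2))
  }
  bi <- cbind(tg[, 2] * nor[, 3] - tg[, 3] * nor[, 2],
              tg[, 3] * nor[, 1] - tg[, 1] * nor[, 3],
              tg[, 1] * nor[, 2] - tg[, 2] * nor[, 1])
  list(tangent = tg, normal = nor, binormal = bi)
}

ring_polygon_area <- function(r, n) 0.5 * n * r^2 * sin(2 * pi / n)

#' Build an idealized labeled dissected-aorta surface mesh
#'
#' Sweeps a circular tube along the ascending/arch/descending path, splits
#' the descending section with a planar zero-thickness flap into TL and FL
#' at the requested area fraction, opens an elliptical entry tear through
#' the flap with its rim labeled \code{tear_margin}, and attaches three
#' branch tubes on the arch. The construction is fully deterministic: it
#' uses no random numbers, so a fixed parameter set always yields an
#' identical mesh.
#'
#' @param params a \code{\link{dissection_params}}.
#' @return list with elements \code{mesh} (class \code{aorta_mesh}:
#'   \code{vertices} mm, \code{triangles}, \code{vertex_region},
#'   \code{triangle_component}, \code{outlet_caps}, \code{vertex_axial},
#'   \code{vertex_s}), \code{centerline} (descending-aorta
#'   \code{\link{centerline}}), and \code{tear}
#'   (a \code{\link{tear_metrics}} result, \code{NULL} if undissected).
#' @export
build_dissected_geometry <- function(params = dissection_params()) {
  stopifnot(inherits(params, "dissection_params"))
  p <- params
  r <- p$da_radius
  dissected <- p$flap_angle_fraction < 1

  # --- path ---------------------------------------------------------------
  n_asc <- max(2L, ceiling(p$asc_length / p$ds))
  asc <- cbind(0, 0, seq(0, p$asc_length, length.out = n_asc + 1))
  n_arch <- max(8L, ceiling(pi * p$arch_radius / p$ds))
  phi <- seq(0, pi, length.out = n_arch + 1)[-1]
  arch <- cbind(p$arch_radius * (1 - cos(phi)), 0,
                p$asc_length + p$arch_radius * sin(phi))
  n_desc <- max(4L, ceiling(p$desc_length / p$ds))
  sd_ <- seq(0, p$desc_length, length.out = n_desc + 1)[-1]
  desc <- cbind(2 * p$arch_radius,
                p$centerline_amplitude * sin(2 * pi * sd_ / p$wavelength),
                p$asc_length - sd_)
  path <- rbind(asc, arch, desc)
  seg_region <- c(rep("ascending", nrow(asc)), rep("arch", nrow(arch)),
                  rep("descending", nrow(desc)))
  # arclength along the descending segment only (mm from arch end)
  desc_start_row <- nrow(asc) + nrow(arch)
  desc_pts <- rbind(arch[nrow(arch), , drop = FALSE], desc)
  desc_s <- c(0, cumsum(sqrt(rowSums(diff(desc_pts)^2))))
  cl_desc <- centerline(desc_pts)

  fr <- transport_frames(path)
  n_ring <- nrow(path)
  n_theta <- p$n_theta
  theta <- 2 * pi * seq(0, n_theta - 1) / n_theta

  verts <- matrix(0, n_ring * n_theta, 3)
  axial <- matrix(0, n_ring * n_theta, 3)
  vnorm <- matrix(0, n_ring * n_theta, 3)
  region <- character(n_ring * n_theta)
  vs <- rep(NA_real_, n_ring * n_theta)

  d_off <- if (dissected) {
    chord_offset_for_fraction(1 - p$flap_angle_fraction, r)
  } else NA_real_

  for (i in seq_len(n_ring)) {
    idx <- (i - 1) * n_theta + seq_len(n_theta)
    offs <- outer(cos(theta), fr$normal[i, ]) + outer(sin(theta), fr$binormal[i, ])
    verts[idx, ] <- matrix(path[i, ], n_theta, 3, byrow = TRUE) + r * offs
    axial[idx, ] <- matrix(fr$tangent[i, ], n_theta, 3, byrow = TRUE)
    vnorm[idx, ] <- offs
    if (seg_region[i] == "descending") {
      si <- desc_s[i - desc_start_row + 1]
      vs[idx] <- si
      if (dissected) {
        region[idx] <- ifelse(r * cos(theta) > d_off, "FL", "TL")
      } else {
        region[idx] <- "TL"
      }
    } else {
      region[idx] <- seg_region[i]
    }
  }

  quad_strip <- function(row_a, row_b) {
    # triangles between two vertex index rings/rows of equal length
    n <- length(row_a)
    j <- seq_len(n)
    jn <- c(seq(2, n), 1)
    rbind(cbind(row_a[j], row_b[j], row_b[jn]),
          cbind(row_a[j], row_b[jn], row_a[jn]))
  }
  tris <- vector("list", n_ring - 1)
  for (i in seq_len(n_ring - 1)) {
    ra <- (i - 1) * n_theta + seq_len(n_theta)
    tris[[i]] <- quad_strip(ra, ra + n_theta)
  }
  triangles <- do.call(rbind, tris)
  tri_comp <- rep("wall", nrow(triangles))

  tear <- NULL
  if (dissected) {
    # --- flap strip ------------------------------------------------------
    half_chord <- sqrt(r^2 - d_off^2)
    if (p$tear_width / 2 >= half_chord) {
      stop("tear wider than the local flap extent (flap half-chord ",
           format(half_chord, digits = 4), " mm); reduce tear_width or move ",
           "flap_angle_fraction toward 0.5")
    }
    if (p$tear_arclength - p$tear_height / 2 <= 0 ||
        p$tear_arclength + p$tear_height / 2 >= p$desc_length) {
      stop("tear extends beyond the descending flap; adjust tear_arclength ",
           "or tear_height")
    }
    desc_rows <- which(seg_region == "descending")
    desc_rows <- c(desc_start_row, desc_rows)  # include arch/descending joint
    nf <- p$flap_n
    yk <- seq(-half_chord, half_chord, length.out = nf + 1)
    n_flap_rows <- length(desc_rows)
    fl_base <- nrow(verts)
    fverts <- matrix(0, n_flap_rows * (nf + 1), 3)
    faxial <- matrix(0, n_flap_rows * (nf + 1), 3)
    fnorm <- matrix(0, n_flap_rows * (nf + 1), 3)
    fs <- numeric(n_flap_rows * (nf + 1))
    for (ii in seq_along(desc_rows)) {
      i <- desc_rows[ii]
      idx <- (ii - 1) * (nf + 1) + seq_len(nf + 1)
      fverts[idx, ] <- matrix(path[i, ] + d_off * fr$normal[i, ],
                              nf + 1, 3, byrow = TRUE) +
        outer(yk, fr$binormal[i, ])
      faxial[idx, ] <- matrix(fr$tangent[i, ], nf + 1, 3, byrow = TRUE)
      fnorm[idx, ] <- matrix(fr$normal[i, ], nf + 1, 3, byrow = TRUE)
      fs[idx] <- desc_s[i - desc_start_row + 1]
    }
    # quad (row ii, col k) kept unless its center lies inside the tear ellipse
    inside <- function(s, y) {
      ((s - p$tear_arclength) / (p$tear_height / 2))^2 +
        (y / (p$tear_width / 2))^2 <= 1
    }
    ftris <- list(); fcomp_n <- 0L
    removed_touch <- rep(FALSE, n_flap_rows * (nf + 1))
    kept_touch <- rep(FALSE, n_flap_rows * (nf + 1))
    for (ii in seq_len(n_flap_rows - 1)) {
      s_mid <- (fs[(ii - 1) * (nf + 1) + 1] + fs[ii * (nf + 1) + 1]) / 2
      for (k in seq_len(nf)) {
        y_mid <- (yk[k] + yk[k + 1]) / 2
        a <- fl_base + (ii - 1) * (nf + 1) + k
        b <- a + 1
        cc <- fl_base + ii * (nf + 1) + k
        d2 <- cc + 1
        corners <- c(a, b, cc, d2) - fl_base
        if (inside(s_mid, y_mid)) {
          removed_touch[corners] <- TRUE
        } else {
          kept_touch[corners] <- TRUE
          ftris[[length(ftris) + 1]] <- rbind(c(a, cc, d2), c(a, d2, b))
        }
      }
    }
    if (length(ftris) == 0) stop("flap entirely removed by tear; invalid tear")
    ftris <- do.call(rbind, ftris)
    rim <- kept_touch & removed_touch
    if (!any(rim)) {
      stop("tear smaller than one flap cell at this resolution; refine the ",
           "mesh (larger flap_n / smaller ds) or enlarge the tear")
    }
    fregion <- ifelse(rim, "tear_margin", "TL")

    verts <- rbind(verts, fverts)
    axial <- rbind(axial, faxial)
    vnorm <- rbind(vnorm, fnorm)
    region <- c(region, fregion)
    vs <- c(vs, fs)
    triangles <- rbind(triangles, ftris)
    tri_comp <- c(tri_comp, rep("flap", nrow(ftris)))
    tear <- tear_metrics(p$tear_height, p$tear_width,
                         location = p$tear_arclength)
  }

  # --- branch tubes on the arch -------------------------------------------
  outlet_caps <- list()
  branch_phi <- c(0.30, 0.50, 0.70) * pi
  arch_center <- c(p$arch_radius, 0, p$asc_length)
  for (b in seq_len(3)) {
    rb <- p$branch_radii[b]
    base <- c(p$arch_radius * (1 - cos(branch_phi[b])), 0,
              p$asc_length + p$arch_radius * sin(branch_phi[b]))
    len_b <- 35
    nzb <- max(3L, ceiling(len_b / (2 * p$ds)))
    zb <- seq(0, len_b, length.out = nzb + 1)
    ntb <- max(16L, as.integer(p$n_theta / 4))
    thb <- 2 * pi * seq(0, ntb - 1) / ntb
    nb <- (nzb + 1) * ntb
    vb <- matrix(0, nb, 3)
    for (iz in seq_len(nzb + 1)) {
      idx <- (iz - 1) * ntb + seq_len(ntb)
      vb[idx, ] <- cbind(base[1] + rb * cos(thb), base[2] + rb * sin(thb),
                         base[3] + zb[iz])
    }
    tb <- vector("list", nzb)
    b0 <- nrow(verts)
    for (iz in seq_len(nzb)) {
      ra <- b0 + (iz - 1) * ntb + seq_len(ntb)
      tb[[iz]] <- quad_strip(ra, ra + ntb)
    }
    tb <- do.call(rbind, tb)
    lab <- paste0("branch", b)
    verts <- rbind(verts, vb)
    axial <- rbind(axial, matrix(rep(c(0, 0, 1), each = nb), nb, 3))
    vnorm <- rbind(vnorm, cbind(rep(cos(thb), nzb + 1), rep(sin(thb), nzb + 1), 0))
    region <- c(region, rep(lab, nb))
    vs <- c(vs, rep(NA_real_, nb))
    triangles <- rbind(triangles, tb)
    tri_comp <- c(tri_comp, rep(lab, nrow(tb)))
    outlet_caps[[lab]] <- list(vertices = b0 + nzb * ntb + seq_len(ntb),
                               area = ring_polygon_area(rb, ntb))
  }
  outlet_caps[["descending"]] <- list(
    vertices = (n_ring - 1) * n_theta + seq_len(n_theta),
    area = ring_polygon_area(r, n_theta))
  outlet_caps[["inlet"]] <- list(vertices = seq_len(n_theta),
                                 area = ring_polygon_area(r, n_theta))

  mesh <- structure(list(vertices = verts,
                         triangles = triangles,
                         vertex_region = region,
                         triangle_component = tri_comp,
                         outlet_caps = outlet_caps,
                         vertex_axial = axial,
                         vertex_normal = vnorm,
                         vertex_s = vs,
                         params = p),
                    class = "aorta_mesh")
  list(mesh = mesh, centerline = cl_desc, tear = tear)
}

#' @export
print.aorta_mesh <- function(x, ...) {
  cat(sprintf("aorta_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  print(table(x$vertex_region))
  invisible(x)
}
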