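#' Time-resolved wall-shear-stress series
#'
#' Per-vertex 3-vector wall shear stress (Pa) sampled on a uniform periodic
#' grid spanning one cardiac cycle.
#'
#' @param times sample times (s), uniform, \code{times[1] = 0},
#'   \code{times[n] < period}.
#' @param values numeric array \code{n_vertices x n_times x 3} (Pa).
#' @param period cycle period (s).
#' @return object of class \code{wss_series}.
#' @export
wss_series <- function(times, values, period = 0.8) {
  if (period <= 0) stop("period must be > 0")
  stopifnot(length(dim(values)) == 3, dim(values)[3] == 3,
            dim(values)[2] == length(times))
  if (abs(times[1]) > 1e-12 || times[length(times)] >= period) {
    stop("times must start at 0 and end strictly before the period")
  }
  dt <- diff(times)
  if (any(abs(dt - dt[1]) > 1e-9 * period)) stop("time grid must be uniform")
  structure(list(times = times, values = values, period = period),
            class = "wss_series")
}

#' Per-plane lumen pressure and flux series
#'
#' Mean pressure (Pa) and volumetric flux (m^3/s) for the true and false
#' lumen on cross-section planes along the descending aorta, per time sample.
#' Planes without a false lumen carry \code{NA} in the FL fields.
#'
#' @param s_mm plane arclengths along the descending centerline (mm), >= 3.
#' @param times sample times (s).
#' @param p_tl,p_fl pressure matrices, planes x times (Pa).
#' @param q_tl,q_fl flux matrices, planes x times (m^3/s).
#' @param period cycle period (s).
#' @return object of class \code{plane_series}.
#' @export
plane_series <- function(s_mm, times, p_tl, p_fl, q_tl, q_fl, period = 0.8) {
  if (length(s_mm) < 3) stop("need at least 3 planes")
  for (m in list(p_tl, p_fl, q_tl, q_fl)) {
    stopifnot(nrow(m) == length(s_mm), ncol(m) == length(times))
  }
  structure(list(s_mm = s_mm, times = times, p_tl = p_tl, p_fl = p_fl,
                 q_tl = q_tl, q_fl = q_fl, period = period),
            class = "plane_series")
}

#' Descending-centerline amplitude reproducing a target tortuosity
#'
#' Inverts the arc-chord ratio of the sinusoidally perturbed descending
#' centerline: for perturbation \eqn{y = A\sin(2\pi s/\lambda)} over one full
#' wavelength the tortuosity is \eqn{\frac{1}{L}\int_0^L
#' \sqrt{1 + (A k \cos k s)^2}\,ds}. Solved numerically for A.
#'
#' @param tort target tortuosity (>= 1).
#' @param wavelength perturbation wavelength (mm).
#' @return amplitude A (mm); 0 when \code{tort <= 1}.
#' @export
amplitude_for_tortuosity <- function(tort, wavelength = 200) {
  if (tort <= 1) return(0)
  k <- 2 * pi / wavelength
  tort_of <- function(a) {
    f <- function(s) sqrt(1 + (a * k * cos(k * s))^2)
    stats::integrate(f, 0, wavelength, rel.tol = 1e-9)$value / wavelength
  }
  stats::uniroot(function(a) tort_of(a) - tort, c(1e-9, 60 * wavelength / 200),
                 extendInt = "upX", tol = 1e-9)$root
}

#' Synthesize pulsatile wall-shear and pressure fields on a labeled mesh
#'
#' Analytic surrogate for a transient CFD solve. Each region of the mesh
#' receives the rectified Womersley wall-shear magnitude of a straight tube
#' carrying that region's flow share at that region's effective radius,
#' oriented along the local axial direction:
#' \itemize{
#' \item ascending/arch: full inlet flow at the aortic radius;
#' \item true lumen: \code{tl_flow_share} of the descending flow (55\% of
#'   inlet flow by default) at the TL equivalent radius;
#' \item false lumen: the complementary share, phase-lagged and attenuated,
#'   with a sign-reversing component (\code{fl_osc} times the cycle mean is
#'   subtracted) so the FL exhibits directional reversal and hence a higher
#'   oscillatory shear index than the TL;
#' \item tear margin: the TL series amplified by \code{jet_factor}, a
#'   surrogate for entry-jet impingement;
#' \item branches: area-weighted shares of the remaining arch flow.
#' }
#' Zero-mean Gaussian noise of standard deviation \code{noise_sd} is added in
#' the local tangent plane (axial and circumferential components), so
#' noise-free fields are exactly tangent to the surface.
#'
#' Plane pressures integrate the per-harmonic Womersley pressure gradient of
#' the descending tube; the FL pressure is the TL pressure plus the
#' configurable offset \code{fl_dp}, by default a diastole-weighted positive
#' offset. Plane fluxes split the descending flow exactly by
#' \code{tl_flow_share}, so TL + FL flux conserves mass by construction.
#'
#' @param mesh an \code{aorta_mesh}.
#' @param waveform inflow \code{\link{flow_waveform}}.
#' @param props \code{\link{fluid_properties}}.
#' @param params the mesh's \code{\link{dissection_params}} (defaults to the
#'   one stored in the mesh); supplies \code{noise_sd}, \code{waveform_scale}
#'   and the seed.
#' @param tl_flow_share TL share of descending flow in (0,1); default the
#'   flap area fraction.
#' @param desc_fraction fraction of inlet flow leaving through the
#'   descending aorta (default 0.55).
#' @param fl_osc FL reversal factor (>= 0); 0 gives a non-reversing FL field.
#' @param fl_lag FL phase lag as a fraction of the period.
#' @param fl_atten FL amplitude attenuation factor.
#' @param jet_factor tear-margin amplification factor.
#' @param fl_dp FL minus TL pressure offset: a single number (Pa, constant
#'   over planes and times), a planes x times matrix, or a function(s_mm, t)
#'   returning the offset. Default 40 Pa weighted toward diastole.
#' @param n_harmonics harmonics retained from the waveform.
#' @param n_planes number of pressure/flux planes along the descending aorta.
#' @return list with \code{wss} (a \code{\link{wss_series}}) and
#'   \code{planes} (a \code{\link{plane_series}}).
#' @export
synthesize_fields <- function(mesh, waveform = aortic_waveform(),
                              props = fluid_properties(),
                              params = mesh$params,
                              tl_flow_share = NULL,
                              desc_fraction = 0.55,
                              fl_osc = 1.2, fl_lag = 0.08, fl_atten = 0.8,
                              jet_factor = 4,
                              fl_dp = NULL,
                              n_harmonics = 8, n_planes = 7) {
  stopifnot(inherits(mesh, "aorta_mesh"), inherits(waveform, "flow_waveform"),
            inherits(props, "fluid_properties"),
            inherits(params, "dissection_params"))
  if (fl_osc < 0) stop("fl_osc must be >= 0")
  f_tl <- if (is.null(tl_flow_share)) {
    if (params$flap_angle_fraction < 1) params$flap_angle_fraction else 1
  } else tl_flow_share
  if (f_tl <= 0 || f_tl > 1) stop("tl_flow_share must be in (0, 1]")

  wf <- flow_waveform(waveform$times, waveform$q * params$waveform_scale,
                      waveform$period)
  h <- decompose_waveform(wf, n_harmonics)
  times <- wf$times
  n_t <- length(times)
  period <- wf$period
  r_m <- params$da_radius * 1e-3

  tube_tau <- function(share, radius_m) {
    sol <- womersley_solution(h * share, radius_m, props, times, period,
                              r = radius_m)
    sol$tau_w
  }
  tau_asc <- abs(tube_tau(1, r_m))
  tau_tl <- abs(tube_tau(desc_fraction * f_tl, r_m * sqrt(f_tl)))
  dissected <- params$flap_angle_fraction < 1
  if (dissected && f_tl < 1) {
    base_fl <- abs(tube_tau(desc_fraction * (1 - f_tl), r_m * sqrt(1 - f_tl)))
    shift <- round(fl_lag * n_t) %% n_t
    if (shift > 0) base_fl <- c(base_fl[(n_t - shift + 1):n_t],
                                base_fl[1:(n_t - shift)])
    tau_fl <- fl_atten * (base_fl - fl_osc * mean(base_fl))
  } else {
    tau_fl <- tau_tl
  }
  caps <- mesh$outlet_caps
  br_areas <- c(caps$branch1$area, caps$branch2$area, caps$branch3$area)
  br_share <- (1 - desc_fraction) * br_areas / sum(br_areas)
  tau_br <- lapply(seq_len(3), function(b) {
    abs(tube_tau(br_share[b], params$branch_radii[b] * 1e-3))
  })

  scalars <- list(ascending = tau_asc, arch = tau_asc,
                  TL = tau_tl, FL = tau_fl,
                  tear_margin = jet_factor * tau_tl,
                  branch1 = tau_br[[1]], branch2 = tau_br[[2]],
                  branch3 = tau_br[[3]])

  n_v <- nrow(mesh$vertices)
  values <- array(0, c(n_v, n_t, 3))
  reg <- mesh$vertex_region
  for (rg in names(scalars)) {
    idx <- which(reg == rg)
    if (length(idx) == 0) next
    sc <- scalars[[rg]]
    for (c3 in 1:3) {
      values[idx, , c3] <- outer(mesh$vertex_axial[idx, c3], sc)
    }
  }
  if (params$noise_sd > 0) {
    with_seed(params$seed, {
      circ <- cbind(
        mesh$vertex_normal[, 2] * mesh$vertex_axial[, 3] -
          mesh$vertex_normal[, 3] * mesh$vertex_axial[, 2],
        mesh$vertex_normal[, 3] * mesh$vertex_axial[, 1] -
          mesh$vertex_normal[, 1] * mesh$vertex_axial[, 3],
        mesh$vertex_normal[, 1] * mesh$vertex_axial[, 2] -
          mesh$vertex_normal[, 2] * mesh$vertex_axial[, 1])
      e_ax <- matrix(stats::rnorm(n_v * n_t, sd = params$noise_sd), n_v, n_t)
      e_ci <- matrix(stats::rnorm(n_v * n_t, sd = params$noise_sd), n_v, n_t)
      for (c3 in 1:3) {
        values[, , c3] <- values[, , c3] + e_ax * mesh$vertex_axial[, c3] +
          e_ci * circ[, c3]
      }
    })
  }
  wss <- wss_series(times, values, period)

  # --- plane pressures and fluxes -----------------------------------------
  s_planes <- seq(0.1, 0.9, length.out = n_planes) * params$desc_length
  q_desc <- desc_fraction * reconstruct_waveform(h, times, period)
  g <- pressure_gradient_harmonics(h * desc_fraction, r_m, props, period)
  grad_t <- Re(outer(rep(1, n_planes),
                     vapply(times, function(tt) {
                       sum(Re(g * exp(1i * (seq_along(g) - 1) *
                                        2 * pi / period * tt)))
                     }, numeric(1))))
  p_tl <- -grad_t * (s_planes * 1e-3)  # pressure relative to the arch end
  if (is.null(fl_dp)) {
    w_dia <- pmax(0, 1 - wf$q / max(wf$q))
    dp <- 40 * outer(rep(1, n_planes), w_dia)
  } else if (is.function(fl_dp)) {
    dp <- outer(s_planes, times, fl_dp)
  } else if (is.matrix(fl_dp)) {
    stopifnot(nrow(fl_dp) == n_planes, ncol(fl_dp) == n_t)
    dp <- fl_dp
  } else {
    dp <- matrix(fl_dp, n_planes, n_t)
  }
  if (dissected) {
    p_fl <- p_tl + dp
    q_tl <- outer(rep(f_tl, n_planes), q_desc)
    q_fl <- outer(rep(1 - f_tl, n_planes), q_desc)
  } else {
    p_fl <- matrix(NA_real_, n_planes, n_t)
    q_tl <- outer(rep(1, n_planes), q_desc)
    q_fl <- matrix(NA_real_, n_planes, n_t)
  }
  planes <- plane_series(s_planes, times, p_tl, p_fl, q_tl, q_fl, period)
  list(wss = wss, planes = planes)
}

# evaluate expr with a temporary RNG state seeded by `seed`, restoring any
# pre-existing global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}
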