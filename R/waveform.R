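#' Periodic volumetric flow-rate waveform
#'
#' Container for one cardiac cycle of volumetric flow rate \eqn{Q(t)}. Times
#' are in seconds on a uniform grid with \code{t[1] = 0} and \code{t[n] < T}
#' (the sample at \code{t = T} is the periodic image of \code{t = 0});
#' flow is in m\eqn{^3}/s.
#'
#' @param times numeric vector of sample times (s), uniform, starting at 0.
#' @param q numeric vector of volumetric flow rates (m^3/s), same length.
#' @param period cycle period T in seconds (default 0.8 s, i.e. 75 bpm).
#' @return An object of class \code{flow_waveform} with elements
#'   \code{times}, \code{q}, \code{period}.
#' @export
flow_waveform <- function(times, q, period = 0.8) {
  if (!is.numeric(period) || length(period) != 1 || period <= 0) {
    stop("waveform period must be a single positive number")
  }
  times <- as.numeric(times)
  q <- as.numeric(q)
  if (length(times) != length(q)) stop("times and q must have equal length")
  if (length(times) < 4) stop("need at least 4 samples per period")
  if (abs(times[1]) > 1e-12) stop("times must start at 0")
  if (times[length(times)] >= period) {
    stop("last sample must be strictly before the period (periodic grid)")
  }
  dt <- diff(times)
  if (any(abs(dt - dt[1]) > 1e-9 * period)) {
    stop("time grid must be uniform; resample before constructing")
  }
  structure(list(times = times, q = q, period = period),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "flow_waveform: %d samples, period %.3f s, mean %.1f mL/s, peak %.1f mL/s\n",
    length(x$times), x$period, mean(x$q) * 1e6, max(x$q) * 1e6))
  invisible(x)
}

#' Packaged aortic-like inflow waveform
#'
#' Parametric ascending-aorta flow curve over a 0.8 s cycle: a half-sine
#' systolic ejection occupying the first 36% of the cycle, a brief dicrotic
#' reversal at valve closure, and a small positive diastolic baseline. With
#' the default amplitude the peak velocity through a 30 mm aorta is about
#' 0.4 m/s and the cycle-averaged cardiac output about 4.5 L/min, both
#' typical resting values.
#'
#' @param n number of samples per period.
#' @param period cycle period (s).
#' @param q_peak peak flow rate (m^3/s); default corresponds to
#'   0.4 m/s peak velocity in a 30 mm vessel.
#' @param scale extra multiplicative factor applied to the whole curve.
#' @return A \code{\link{flow_waveform}}.
#' @export
aortic_waveform <- function(n = 64, period = 0.8,
                            q_peak = 0.4 * pi * 0.015^2, scale = 1) {
  stopifnot(n >= 8, period > 0, q_peak > 0)
  times <- seq(0, period, length.out = n + 1)[seq_len(n)]
  x <- times / period
  q <- numeric(n)
  sys <- x < 0.36
  q[sys] <- sin(pi * x[sys] / 0.36)
  dip <- x >= 0.36 & x < 0.46
  q[dip] <- -0.08 * sin(pi * (x[dip] - 0.36) / 0.10)
  q[x >= 0.46] <- 0.02
  flow_waveform(times, scale * q_peak * q, period)
}

#' Rescale a waveform to a different vessel diameter
#'
#' Scales the flow so the velocity waveform is preserved when the vessel
#' diameter changes from \code{d_ref} to \code{diameter}
#' (flow scales with the lumen cross-section, \eqn{Q \propto D^2}).
#'
#' @param waveform a \code{flow_waveform}.
#' @param diameter target diameter (m).
#' @param d_ref reference diameter the waveform was defined for (m).
#' @return A \code{flow_waveform}.
#' @export
scale_waveform <- function(waveform, diameter, d_ref = 0.03) {
  stopifnot(inherits(waveform, "flow_waveform"), diameter > 0, d_ref > 0)
  flow_waveform(waveform$times, waveform$q * (diameter / d_ref)^2,
                waveform$period)
}

#' Harmonic decomposition of a flow waveform
#'
#' Discrete Fourier analysis of the periodic flow curve into one-sided
#' complex harmonics \eqn{Q(t) = \Re\{\sum_{k=0}^{K} c_k e^{i k \omega t}\}}
#' with \eqn{\omega = 2\pi/T}. \code{c_0} is real and equals the
#' time-averaged flow.
#'
#' @param waveform a \code{\link{flow_waveform}} on a uniform periodic grid.
#' @param n_harmonics number of oscillatory harmonics K to retain; needs at
#'   least \code{2K + 1} samples per period.
#' @return complex vector of length \code{n_harmonics + 1} (indices 0..K).
#' @export
decompose_waveform <- function(waveform, n_harmonics = 8) {
  stopifnot(inherits(waveform, "flow_waveform"))
  n <- length(waveform$q)
  if (n < 2 * n_harmonics + 1) {
    stop("need at least 2*n_harmonics + 1 samples per period (have ", n, ")")
  }
  co <- stats::fft(waveform$q) / n
  harm <- complex(n_harmonics + 1)
  harm[1] <- Re(co[1])
  if (n_harmonics >= 1) harm[seq(2, n_harmonics + 1)] <-
      2 * co[seq(2, n_harmonics + 1)]
  harm
}

#' Reconstruct a flow curve from harmonics
#'
#' @param harmonics complex one-sided harmonics from
#'   \code{\link{decompose_waveform}}.
#' @param times evaluation times (s).
#' @param period cycle period (s).
#' @return numeric vector of flow (m^3/s) at \code{times}.
#' @export
reconstruct_waveform <- function(harmonics, times, period) {
  stopifnot(period > 0)
  omega <- 2 * pi / period
  q <- rep(Re(harmonics[1]), length(times))
  for (k in seq_len(length(harmonics) - 1)) {
    q <- q + Re(harmonics[k + 1] * exp(1i * k * omega * times))
  }
  q
}

#' Read / write waveform CSV (columns t_s, q_m3s)
#'
#' @param path CSV path.
#' @param period cycle period (s) for \code{read_waveform_csv}.
#' @return \code{read_waveform_csv} returns a \code{flow_waveform};
#'   \code{write_waveform_csv} invisibly returns \code{path}.
#' @export
read_waveform_csv <- function(path, period = 0.8) {
  d <- utils::read.csv(path)
  if (!all(c("t_s", "q_m3s") %in% names(d))) {
    stop("waveform CSV must have columns t_s, q_m3s")
  }
  flow_waveform(d$t_s, d$q_m3s, period)
}

#' @rdname read_waveform_csv
#' @param waveform a \code{flow_waveform} to write.
#' @export
write_waveform_csv <- function(waveform, path) {
  utils::write.csv(
    data.frame(t_s = waveform$times, q_m3s = waveform$q),
    path, row.names = FALSE)
  invisible(path)
}
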