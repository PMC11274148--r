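#' False-lumen flow fraction at the systolic peak
#'
#' Percentage of the flow entering the descending thoracic aorta that passes
#' through the false lumen, evaluated at the time of maximum total
#' descending flux: \eqn{100\, Q_{FL} / (Q_{FL} + Q_{TL})}. Measured by
#' default at the most proximal plane (just distal to the entry tear).
#'
#' @param planes a \code{\link{plane_series}}.
#' @param peak_time systolic peak time (s); default the sample of maximum
#'   total descending flux at the measurement plane.
#' @param plane index of the measurement plane (default 1, most proximal).
#' @return FL flow percentage in [0, 100].
#' @export
fl_flow_fraction <- function(planes, peak_time = NULL, plane = 1) {
  stopifnot(inherits(planes, "plane_series"))
  q_tl <- planes$q_tl[plane, ]
  q_fl <- planes$q_fl[plane, ]
  if (all(is.na(q_fl))) stop("no false lumen at the measurement plane")
  tot <- q_tl + q_fl
  i <- if (is.null(peak_time)) which.max(tot) else {
    which.min(abs(planes$times - peak_time))
  }
  if (!is.finite(tot[i]) || tot[i] == 0) {
    stop("zero total descending flux at the systolic peak")
  }
  100 * q_fl[i] / tot[i]
}

#' Outflow boundary split over descending aorta and arch branches
#'
#' A fixed fraction of the time-averaged inlet flow (55\% by default) leaves
#' through the descending aorta; the remainder is divided among the three
#' arch branches proportionally to their outlet cross-sectional areas.
#'
#' @param branch_areas cross-sectional areas of the three branch outlets
#'   (mm^2), all > 0.
#' @param desc_fraction descending-aorta fraction of total flow, in (0,1).
#' @return list of class \code{outflow_split}: \code{descending},
#'   \code{branches} (length 3), summing exactly to 1.
#' @export
outflow_split <- function(branch_areas, desc_fraction = 0.55) {
  if (length(branch_areas) != 3 || any(branch_areas <= 0)) {
    stop("branch_areas must be 3 positive areas")
  }
  if (desc_fraction <= 0 || desc_fraction >= 1) {
    stop("desc_fraction must be in (0, 1)")
  }
  br <- (1 - desc_fraction) * branch_areas / sum(branch_areas)
  structure(list(descending = desc_fraction, branches = br),
            class = "outflow_split")
}

#' Characteristic cardiac phase times of a flow waveform
#'
#' Resolves three phase times from the flow curve: the systolic peak
#' (maximum flow), the systolic deceleration (midpoint of the descending
#' systolic limb, between the peak and the end of systole where the flow
#' first drops below 5\% of peak or reaches its first local minimum), and
#' the diastolic peak (minimum flow after the end of systole).
#'
#' @param waveform a \code{\link{flow_waveform}}.
#' @return list: \code{peak}, \code{deceleration}, \code{diastole} (s).
#' @export
cardiac_phases <- function(waveform) {
  stopifnot(inherits(waveform, "flow_waveform"))
  q <- waveform$q; tt <- waveform$times
  i_peak <- which.max(q)
  n <- length(q)
  i_end <- n
  for (i in seq(i_peak + 1, n - 1)) {
    if (q[i] <= 0.05 * q[i_peak] || (q[i] < q[i - 1] && q[i] <= q[i + 1])) {
      i_end <- i
      break
    }
  }
  t_dec <- (tt[i_peak] + tt[i_end]) / 2
  dia_window <- seq(i_end, n)
  i_dia <- dia_window[which.min(q[dia_window])]
  list(peak = tt[i_peak], deceleration = t_dec, diastole = tt[i_dia])
}

#' Inter-lumen pressure-difference profile along the descending aorta
#'
#' Per-plane difference of mean false-lumen minus mean true-lumen pressure
#' (positive means higher FL pressure) at the sample nearest each of the
#' three cardiac phase times. Planes without a false lumen are NA.
#'
#' @param planes a \code{\link{plane_series}}.
#' @param phases list with \code{peak}, \code{deceleration}, \code{diastole}
#'   times (s), e.g. from \code{\link{cardiac_phases}}.
#' @return data.frame of class \code{pressure_profile}: \code{s_mm},
#'   \code{dp_peak_pa}, \code{dp_decel_pa}, \code{dp_diast_pa}.
#' @export
pressure_difference_profile <- function(planes, phases) {
  stopifnot(inherits(planes, "plane_series"))
  need <- c("peak", "deceleration", "diastole")
  if (!all(need %in% names(phases))) {
    stop("phases must name ", paste(need, collapse = ", "))
  }
  pick <- vapply(need, function(ph) {
    which.min(abs(planes$times - phases[[ph]]))
  }, integer(1))
  dp <- planes$p_fl - planes$p_tl
  out <- data.frame(s_mm = planes$s_mm,
                    dp_peak_pa = dp[, pick["peak"]],
                    dp_decel_pa = dp[, pick["deceleration"]],
                    dp_diast_pa = dp[, pick["diastole"]])
  class(out) <- c("pressure_profile", "data.frame")
  out
}

#' Write a pressure-difference profile as CSV
#' @param profile a \code{pressure_profile}.
#' @param path CSV path.
#' @export
write_pressure_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
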