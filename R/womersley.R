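#' Blood fluid properties
#'
#' Incompressible Newtonian blood model. Defaults are the conventional
#' large-vessel values: density 1060 kg/m^3 and dynamic viscosity
#' 0.00319 Pa s.
#'
#' @param density fluid density rho (kg/m^3).
#' @param viscosity dynamic viscosity mu (Pa s).
#' @return list with \code{density}, \code{viscosity} and the derived
#'   kinematic viscosity \code{nu} (m^2/s), class \code{fluid_properties}.
#' @export
fluid_properties <- function(density = 1060, viscosity = 0.00319) {
  if (density <= 0 || viscosity <= 0) stop("density and viscosity must be > 0")
  structure(list(density = density, viscosity = viscosity,
                 nu = viscosity / density),
            class = "fluid_properties")
}

#' Womersley pulsatile flow in a rigid straight tube
#'
#' Analytic axisymmetric solution for fully developed pulsatile flow driven
#' by the harmonic content of a prescribed volumetric flow waveform. For each
#' oscillatory harmonic k the axial velocity is
#' \deqn{u_k(r,t) = \Re\left\{ \frac{c_k}{\pi R^2}\,
#'   \frac{1 - J_0(\Lambda_k r/R)/J_0(\Lambda_k)}
#'        {1 - 2 J_1(\Lambda_k)/(\Lambda_k J_0(\Lambda_k))}
#'   \, e^{i k \omega t} \right\}}
#' with \eqn{\Lambda_k = i^{3/2} \alpha \sqrt{k}} and Womersley number
#' \eqn{\alpha = R\sqrt{\omega/\nu}}; the steady component is the Poiseuille
#' profile. Wall shear stress is evaluated from the analytic radial
#' derivative (a \eqn{J_1} expression), not by finite differences, and for a
#' purely steady flow reduces exactly to \eqn{\tau_w = 4\mu Q/(\pi R^3)}.
#'
#' The sign convention is the shear exerted by the fluid on the wall,
#' positive in the direction of positive flow.
#'
#' @param harmonics complex one-sided flow harmonics (index 0..K), m^3/s,
#'   as returned by \code{\link{decompose_waveform}}.
#' @param radius tube radius R (m).
#' @param props \code{\link{fluid_properties}}.
#' @param times evaluation times (s).
#' @param period cycle period T (s).
#' @param r radial positions (m, 0 <= r <= R) at which to evaluate velocity.
#' @return list of class \code{womersley_solution}:
#'   \code{u} (matrix, length(r) x length(times), m/s),
#'   \code{tau_w} (numeric, Pa, per time),
#'   \code{alpha} (fundamental Womersley number), plus the inputs.
#' @export
womersley_solution <- function(harmonics, radius, props, times,
                               period = 0.8, r = NULL) {
  stopifnot(inherits(props, "fluid_properties"))
  if (radius <= 0) stop("radius must be > 0")
  if (period <= 0) stop("period must be > 0")
  if (is.null(r)) r <- seq(0, radius, length.out = 25)
  if (any(r < 0 | r > radius + 1e-15)) stop("radial positions must lie in [0, R]")
  omega <- 2 * pi / period
  alpha <- radius * sqrt(omega / props$nu)
  mu <- props$viscosity
  area <- pi * radius^2
  f <- pmin(r / radius, 1)

  q0 <- Re(harmonics[1])
  u <- outer(2 * q0 / area * (1 - f^2), rep(1, length(times)))
  tau <- rep(4 * mu * q0 / (pi * radius^3), length(times))

  n_h <- length(harmonics) - 1
  for (k in seq_len(n_h)) {
    ck <- harmonics[k + 1]
    if (Mod(ck) == 0) next
    lam <- 1i^1.5 * alpha * sqrt(k)
    j1j0 <- bessel_j1_over_j0(lam)
    dk <- 1 - 2 * j1j0 / lam
    prof <- (1 - bessel_j0_ratio(lam, f)) / dk
    eit <- exp(1i * k * omega * times)
    u <- u + Re(outer(ck / area * prof, eit))
    tau_k <- -mu * (ck / area) * (lam / radius) * j1j0 / dk
    tau <- tau + Re(tau_k * eit)
  }
  structure(list(u = u, tau_w = tau, alpha = alpha, radius = radius,
                 r = r, times = times, period = period, props = props,
                 harmonics = harmonics),
            class = "womersley_solution")
}

#' Pressure-gradient harmonics corresponding to flow harmonics
#'
#' Converts one-sided flow harmonics to the matching axial pressure-gradient
#' harmonics \eqn{-\partial p/\partial z = \Re\{\sum G_k e^{ik\omega t}\}}
#' via the Womersley admittance; the steady term is the Poiseuille gradient
#' \eqn{8\mu Q_0/(\pi R^4)}.
#'
#' @inheritParams womersley_solution
#' @return complex vector of gradient harmonics (Pa/m), same length as
#'   \code{harmonics}.
#' @export
pressure_gradient_harmonics <- function(harmonics, radius, props,
                                        period = 0.8) {
  stopifnot(inherits(props, "fluid_properties"), radius > 0, period > 0)
  omega <- 2 * pi / period
  alpha <- radius * sqrt(omega / props$nu)
  g <- complex(length(harmonics))
  g[1] <- 8 * props$viscosity * Re(harmonics[1]) / (pi * radius^4)
  for (k in seq_len(length(harmonics) - 1)) {
    lam <- 1i^1.5 * alpha * sqrt(k)
    dk <- 1 - 2 * bessel_j1_over_j0(lam) / lam
    g[k + 1] <- 1i * props$density * k * omega * harmonics[k + 1] /
      (pi * radius^2 * dk)
  }
  g
}

#' Dimensionless numbers of a pulsatile tube flow
#'
#' Computes the Womersley number \eqn{\alpha = (D/2)\sqrt{\omega/\nu}}, the
#' inlet peak Reynolds number \eqn{Re_{peak} = \rho U_{peak} D / \mu} with
#' \eqn{U_{peak} = Q_{peak}/(\pi D^2/4)}, the Strouhal number
#' \eqn{St = f D / U} and the critical Reynolds number of the pulsatile
#' transition correlation \eqn{Re_{crit} = 169\,\alpha^{0.83}\,St^{-0.27}}
#' (replaceable via \code{re_crit}). The flow is flagged subcritical when
#' \eqn{Re_{peak} < Re_{crit}}.
#'
#' The characteristic velocity in the Strouhal number is selectable; the
#' default uses the peak inlet velocity, which places both Reynolds numbers
#' in the physiologically reported bands and yields subcritical flows for
#' aortic diameters at resting cardiac output.
#'
#' @param waveform a \code{\link{flow_waveform}}.
#' @param diameter tube diameter D (m).
#' @param props \code{\link{fluid_properties}}.
#' @param char_velocity characteristic velocity for St: "peak" or "mean".
#' @param re_crit function(alpha, strouhal) giving the critical Reynolds
#'   number; default the alpha/St power-law correlation above.
#' @return list of class \code{dimensionless_numbers}: \code{alpha},
#'   \code{strouhal}, \code{re_peak}, \code{re_crit}, \code{subcritical}.
#' @export
dimensionless_numbers <- function(waveform, diameter, props = fluid_properties(),
                                  char_velocity = c("peak", "mean"),
                                  re_crit = NULL) {
  stopifnot(inherits(waveform, "flow_waveform"), inherits(props, "fluid_properties"))
  if (diameter <= 0) stop("diameter must be > 0")
  char_velocity <- match.arg(char_velocity)
  if (is.null(re_crit)) {
    re_crit <- function(alpha, st) 169 * alpha^0.83 * st^(-0.27)
  }
  area <- pi * diameter^2 / 4
  omega <- 2 * pi / waveform$period
  alpha <- (diameter / 2) * sqrt(omega / props$nu)
  u_peak <- max(abs(waveform$q)) / area
  u_mean <- mean(waveform$q) / area
  u_char <- switch(char_velocity, peak = u_peak, mean = u_mean)
  if (u_char <= 0) {
    stop("characteristic velocity (", char_velocity,
         ") is not positive; Strouhal number undefined")
  }
  st <- (1 / waveform$period) * diameter / u_char
  rc <- re_crit(alpha, st)
  rp <- props$density * u_peak * diameter / props$viscosity
  structure(list(alpha = alpha, strouhal = st, re_peak = rp, re_crit = rc,
                 subcritical = rp < rc, char_velocity = char_velocity),
            class = "dimensionless_numbers")
}

#' @export
print.dimensionless_numbers <- function(x, ...) {
  cat(sprintf(
    "alpha %.2f | St %.3f (%s velocity) | Re_peak %.0f | Re_crit %.0f | %s\n",
    x$alpha, x$strouhal, x$char_velocity, x$re_peak, x$re_crit,
    if (x$subcritical) "subcritical" else "supercritical"))
  invisible(x)
}
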