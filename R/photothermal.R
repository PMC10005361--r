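#' Well-watered photothermal parameter set
#'
#' Container for the coefficients of the quantum-yield response model under
#' well-watered conditions. The three PAR-response amplitudes and decay
#' rates describe exponential declines of the yield envelope at the cardinal
#' temperatures:
#' \deqn{\Phi_{bL} = a_L e^{-b_L PAR}, \quad
#'       \Phi_{bH} = a_H e^{-b_H PAR}, \quad
#'       \Phi_{To} = (F_v/F_m) e^{-\epsilon PAR}}
#' `eps` is stored as the effective per-PAR exponent coefficient (e.g.
#' `5.91e-4`); its x1e4 scaled representation (5.91) is the baseline of the
#' drought-stress index (see [epsilon_d()]).
#'
#' @param a_l,b_l amplitude (dimensionless, in (0, 1]) and decay rate (per
#'   umol photons m-2 s-1, >= 0) of the low-temperature base yield.
#' @param a_h,b_h amplitude and decay rate of the high-temperature base yield.
#' @param fvfm dark-adapted maximum PSII quantum efficiency, in (0, 1).
#' @param eps effective amplitude-decrease coefficient of the optimum yield
#'   with PAR (>= 0).
#' @param t_min,t_o,t_max cardinal temperatures (degC), fixed constants for
#'   sugarcane photosynthesis: minimum 15, optimum 30, maximum 40.
#' @return an object of class `photothermal_params`.
#' @examples
#' p <- photothermal_params(
#'   a_l = 0.688, b_l = 6.77e-4, a_h = 0.676, b_h = 5.16e-4,
#'   fvfm = 0.769, eps = 5.91e-4
#' )
#' phi_photothermal(30, 0, p) # = fvfm
#' @export
photothermal_params <- function(a_l, b_l, a_h, b_h, fvfm, eps,
                                t_min = 15, t_o = 30, t_max = 40) {
  for (nm in c("a_l", "b_l", "a_h", "b_h", "fvfm", "eps", "t_min", "t_o", "t_max")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      .err_domain(sprintf("'%s' must be a single finite number", nm))
    }
  }
  if (!(t_min < t_o && t_o < t_max)) .err_domain("requires t_min < t_o < t_max")
  if (a_l <= 0 || a_l > 1 || a_h <= 0 || a_h > 1) {
    .err_domain("amplitudes a_l, a_h must lie in (0, 1]")
  }
  if (b_l < 0 || b_h < 0 || eps < 0) .err_domain("decay rates must be >= 0")
  if (fvfm <= 0 || fvfm >= 1) .err_domain("fvfm must lie in (0, 1)")
  structure(
    list(
      a_l = a_l, b_l = b_l, a_h = a_h, b_h = b_h,
      fvfm = fvfm, eps = eps, t_min = t_min, t_o = t_o, t_max = t_max
    ),
    class = "photothermal_params"
  )
}

.eps_scaled <- function(params) params$eps * 1e4

#' @export
print.photothermal_params <- function(x, digits = 4, ...) {
  cat("Photothermal quantum-yield parameters\n")
  cat(sprintf("  Phi_bL(PAR) = %s * exp(-%s * PAR)\n",
              format(x$a_l, digits = digits), format(x$b_l, digits = digits)))
  cat(sprintf("  Phi_bH(PAR) = %s * exp(-%s * PAR)\n",
              format(x$a_h, digits = digits), format(x$b_h, digits = digits)))
  cat(sprintf("  Phi_To(PAR) = %s * exp(-%s * PAR)   (eps scaled: %s)\n",
              format(x$fvfm, digits = digits), format(x$eps, digits = digits),
              format(.eps_scaled(x), digits = digits)))
  cat(sprintf("  cardinal temperatures: %g / %g / %g degC\n",
              x$t_min, x$t_o, x$t_max))
  invisible(x)
}

#' PAR-response base curves of quantum yield
#'
#' Evaluates the three exponential envelopes of the photothermal model at
#' given irradiance: the base yields at `t_min` and `t_max` and the optimum
#' yield at `t_o`.
#'
#' @param par photosynthetically active radiation, umol photons m-2 s-1 (>= 0).
#' @param params a [photothermal_params()] object.
#' @return data frame with columns `phi_bl`, `phi_bh`, `phi_to`.
#' @export
base_curves <- function(par, params) {
  stopifnot(inherits(params, "photothermal_params"))
  .check_numeric(par, "par")
  if (any(par < 0)) .err_domain("par must be >= 0")
  data.frame(
    phi_bl = params$a_l * exp(-params$b_l * par),
    phi_bh = params$a_h * exp(-params$b_h * par),
    phi_to = params$fvfm * exp(-params$eps * par)
  )
}

# piecewise-sinusoidal temperature interpolation between the base curves;
# `extend` permits evaluation outside [t_min, t_max] (the sine argument goes
# negative), used only when emitting deliberately out-of-range synthetic
# records.
.phi_photothermal <- function(temp, par, params, extend = FALSE) {
  bc <- base_curves(par, params)
  n <- max(length(temp), nrow(bc))
  temp <- rep_len(temp, n)
  lower <- temp <= params$t_o
  s <- sin(pi / 2 * (temp - params$t_min) / (params$t_o - params$t_min))
  u <- sin(pi / 2 * (params$t_max - temp) / (params$t_max - params$t_o))
  phi_bl <- rep_len(bc$phi_bl, n)
  phi_bh <- rep_len(bc$phi_bh, n)
  phi_to <- rep_len(bc$phi_to, n)
  ifelse(lower,
    phi_bl + (phi_to - phi_bl) * s,
    phi_bh + (phi_to - phi_bh) * u
  )
}

#' Quantum yield under well-watered photothermal conditions
#'
#' Piecewise sinusoidal response of the effective PSII quantum yield to
#' temperature, interpolating between the PAR-dependent base curves:
#' \deqn{\Phi(T) = \Phi_{bL} + (\Phi_{To}-\Phi_{bL})
#'   \sin\!\left(\frac{\pi}{2}\frac{T-T_{min}}{T_o-T_{min}}\right),
#'   \quad T_{min} \le T \le T_o}
#' \deqn{\Phi(T) = \Phi_{bH} + (\Phi_{To}-\Phi_{bH})
#'   \sin\!\left(\frac{\pi}{2}\frac{T_{max}-T}{T_{max}-T_o}\right),
#'   \quad T_o \le T \le T_{max}}
#' Both branches agree at `T_o`, where the yield equals `Phi_To(PAR)`.
#'
#' @param temp air temperature, degC, within `[t_min, t_max]`.
#' @param par irradiance, umol photons m-2 s-1 (>= 0).
#' @param params a [photothermal_params()] object.
#' @return quantum yield, mol e- (mol photon)-1. Vectorized over `temp` and
#'   `par` with recycling.
#' @export
phi_photothermal <- function(temp, par, params) {
  stopifnot(inherits(params, "photothermal_params"))
  .check_numeric(temp, "temp")
  if (any(temp < params$t_min | temp > params$t_max)) {
    .err_domain(sprintf(
      "temp outside the model range [%g, %g] degC; filter such records first",
      params$t_min, params$t_max
    ))
  }
  .phi_photothermal(temp, par, params)
}
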