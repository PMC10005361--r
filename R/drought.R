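#' Drought extension parameter set
#'
#' Couples a well-watered photothermal parameter set with the coefficients of
#' the drought-stress index: below the critical relative substrate water
#' content `rswc_c` the index rises exponentially as the substrate dries,
#' \deqn{\epsilon_D(rSWC) = \epsilon_s + c\, e^{-d\, rSWC},
#'   \quad rSWC \le rSWC_c}
#' and equals the well-watered baseline `eps_s = eps * 1e4` above it. `rswc`
#' enters as a fraction (0-1); with the magnitudes of `d` typical for
#' sugarcane (around 10-22 per unit fractional rSWC) a percent scale would be
#' numerically degenerate.
#'
#' @param c amplitude of the index rise (scaled-eps units, >= 0).
#' @param d decay rate per unit fractional rSWC (>= 0).
#' @param rswc_c critical relative substrate water content, fraction in (0,1).
#' @param base a [photothermal_params()] object.
#' @return an object of class `drought_params`.
#' @export
drought_params <- function(c, d, rswc_c, base) {
  stopifnot(inherits(base, "photothermal_params"))
  # NB: the argument named `c` shadows base::c inside this function
  for (nm in base::c("c", "d", "rswc_c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      .err_domain(sprintf("'%s' must be a single finite number", nm))
    }
  }
  if (c < 0 || d < 0) .err_domain("c and d must be >= 0")
  if (rswc_c <= 0 || rswc_c >= 1) .err_domain("rswc_c must lie in (0, 1)")
  structure(list(c = c, d = d, rswc_c = rswc_c, base = base),
            class = "drought_params")
}

#' @export
print.drought_params <- function(x, digits = 4, ...) {
  cat("Drought-stress index parameters\n")
  cat(sprintf("  eps_D(rswc) = %s + %s * exp(-%s * rswc) for rswc <= %s\n",
              format(.eps_scaled(x$base), digits = digits),
              format(x$c, digits = digits), format(x$d, digits = digits),
              format(x$rswc_c, digits = digits)))
  cat(sprintf("  baseline eps (scaled) = %s above the changepoint\n",
              format(.eps_scaled(x$base), digits = digits)))
  invisible(x)
}

#' Drought-stress index
#'
#' Evaluates the scaled drought-stress index `eps_D` at given relative
#' substrate water content. Above the critical content the index equals the
#' well-watered baseline `eps * 1e4`; at or below it the index rises by
#' `c * exp(-d * rswc)`. The function is non-increasing in `rswc` on
#' `[0, rswc_c]` and jumps by `c * exp(-d * rswc_c)` at the changepoint (the
#' model is discontinuous by construction; the jump size is reported by
#' [fit_drought()] as a diagnostic).
#'
#' @param rswc relative substrate water content, fraction in `[0, 1]`.
#' @param dp a [drought_params()] object.
#' @return scaled index values (dimensionless, on the 7/9/13 stage bands).
#' @examples
#' p <- cultivar_archetype("roc22")
#' epsilon_d(0.8, p$drought)  # baseline 5.91
#' epsilon_d(0.29, p$drought) # elevated
#' @export
epsilon_d <- function(rswc, dp) {
  stopifnot(inherits(dp, "drought_params"))
  .check_numeric(rswc, "rswc")
  if (any(rswc < 0 | rswc > 1)) .err_domain("rswc must lie in [0, 1]")
  eps_s <- .eps_scaled(dp$base)
  ifelse(rswc > dp$rswc_c, eps_s, eps_s + dp$c * exp(-dp$d * rswc))
}

# forward yield at explicit scaled index values; the default "ratio"
# attenuation multiplies every base curve by exp(-(eps_d - eps_s)*1e-4*PAR),
# so the optimum envelope becomes fvfm * exp(-eps_d*1e-4*PAR) and the model
# reduces exactly to the well-watered one at eps_d = eps_s. The "literal"
# variant applies exp(-eps_d*1e-4*PAR) to the base curves directly (kept for
# comparison; it does not reduce to the well-watered model at drought onset).
.phi_at_eps <- function(temp, par, eps_d, base,
                        attenuation = c("ratio", "literal"),
                        extend = FALSE) {
  attenuation <- match.arg(attenuation)
  eps_s <- .eps_scaled(base)
  delta <- if (attenuation == "ratio") eps_d - eps_s else eps_d
  .phi_photothermal(temp, par, base, extend = extend) *
    exp(-delta * 1e-4 * par)
}

#' Quantum yield under drought
#'
#' Drought-modified quantum yield: the well-watered photothermal prediction
#' attenuated by the drought-stress index. With the default `"ratio"`
#' attenuation every base curve is multiplied by
#' `exp(-(eps_D - eps_s) * 1e-4 * PAR)`, equivalently the optimum envelope
#' becomes `fvfm * exp(-eps_D * 1e-4 * PAR)`; above the critical water
#' content the result equals [phi_photothermal()] exactly, and at `PAR = 0`
#' drought has no effect (the exponent vanishes).
#'
#' @param temp air temperature, degC, within the cardinal range.
#' @param par irradiance, >= 0.
#' @param rswc relative substrate water content, fraction in `[0, 1]`.
#' @param dp a [drought_params()] object.
#' @param attenuation `"ratio"` (default, continuous at drought onset) or
#'   `"literal"` (direct exponential applied to the base curves).
#' @return quantum yield. Vectorized with recycling.
#' @export
phi_drought <- function(temp, par, rswc, dp,
                        attenuation = c("ratio", "literal")) {
  stopifnot(inherits(dp, "drought_params"))
  attenuation <- match.arg(attenuation)
  .check_numeric(temp, "temp")
  base <- dp$base
  if (any(temp < base$t_min | temp > base$t_max)) {
    .err_domain(sprintf("temp outside the model range [%g, %g] degC",
                        base$t_min, base$t_max))
  }
  eps_d <- epsilon_d(rswc, dp)
  .phi_at_eps(temp, par, eps_d, base, attenuation)
}

#' Invert observed quantum yield to the drought-stress index
#'
#' Finds the scaled index `eps_D` at which the drought-attenuated model
#' reproduces an observed yield at known temperature and irradiance, by
#' bisection of the monotone forward model on `[eps_s, eps_max]` to absolute
#' tolerance `tol`. This is the per-record estimator used when fitting the
#' drought model to measured yields.
#'
#' Observations at or slightly above the well-watered prediction carry no
#' stress signal: if the excess is within `noise_tol` the result is clamped
#' to the baseline `eps_s` (with a warning), otherwise an inversion error is
#' raised. Records below the yield attainable at `eps_max` raise a bracket
#' error. Irradiance below `par_min` makes the index unidentifiable (the
#' attenuation factor tends to 1) and is refused.
#'
#' @param phi_obs observed quantum yield(s), in (0, 1).
#' @param temp,par measurement temperature (degC) and irradiance.
#' @param params a [drought_params()] or [photothermal_params()] object (only
#'   the well-watered coefficients are needed).
#' @param par_min minimum informative irradiance (default 50).
#' @param eps_max upper bracket of the scaled index (default 200).
#' @param tol absolute bisection tolerance (default 1e-8).
#' @param noise_tol absolute yield tolerance for clamping observations above
#'   the well-watered prediction (default 0.02); `Inf` clamps always.
#' @param attenuation forward-model variant, see [phi_drought()].
#' @return scaled index values, `>= eps_s`. Vectorized.
#' @export
invert_epsilon_d <- function(phi_obs, temp, par, params,
                             par_min = 50, eps_max = 200, tol = 1e-8,
                             noise_tol = 0.02,
                             attenuation = c("ratio", "literal")) {
  attenuation <- match.arg(attenuation)
  base <- if (inherits(params, "drought_params")) params$base else params
  stopifnot(inherits(base, "photothermal_params"))
  .check_numeric(phi_obs, "phi_obs")
  if (any(par < par_min)) {
    .err_domain(sprintf(
      "par below par_min = %g; eps_D is uninformative at low irradiance",
      par_min
    ))
  }
  if (any(phi_obs <= 0 | phi_obs >= 1)) {
    .err_domain("phi_obs must lie in (0, 1)")
  }
  n <- max(length(phi_obs), length(temp), length(par))
  phi_obs <- rep_len(phi_obs, n)
  temp <- rep_len(temp, n)
  par <- rep_len(par, n)

  eps_s <- .eps_scaled(base)
  phi_ww <- phi_photothermal(temp, par, base)
  over <- phi_obs >= phi_ww
  excess <- phi_obs - phi_ww
  if (any(excess > noise_tol)) {
    .err(sprintf(
      "%s exceed the well-watered prediction by more than noise_tol = %g",
      .rows_msg(which(excess > noise_tol)), noise_tol
    ), "phistress_inversion_error")
  }
  if (any(over)) {
    warning(sprintf(
      "%d observation(s) at/above the well-watered prediction clamped to eps_s",
      sum(over)
    ))
  }
  phi_floor <- .phi_at_eps(temp, par, eps_max, base, attenuation)
  if (any(phi_obs < phi_floor & !over)) {
    .err(sprintf(
      "%s below the yield attainable at eps_max = %g; cannot bracket",
      .rows_msg(which(phi_obs < phi_floor & !over)), eps_max
    ), "phistress_bracket_error")
  }

  lo <- rep(eps_s, n)
  hi <- rep(eps_max, n)
  iters <- ceiling(log2((eps_max - eps_s) / tol)) + 2L
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    phi_mid <- .phi_at_eps(temp, par, mid, base, attenuation)
    take_hi <- phi_mid > phi_obs # yield decreasing in eps_d
    lo <- ifelse(take_hi, mid, lo)
    hi <- ifelse(take_hi, hi, mid)
  }
  out <- (lo + hi) / 2
  out[over] <- eps_s
  out
}

#' Classify drought stage from the stress index
#'
#' Maps scaled index values onto the drought-severity bands: below 7
#' well-watered, 7-9 slight, 9-13 moderate, above 13 severe. Band boundaries
#' are assigned to the more severe stage (conservative for stress
#' diagnosis).
#'
#' @param eps_d scaled drought-stress index values (>= 0).
#' @param bands the three ascending boundaries (default `c(7, 9, 13)`).
#' @return ordered factor with levels
#'   `well_watered < slight < moderate < severe`.
#' @examples
#' drought_stage(c(5.91, 8, 10, 14))
#' @export
drought_stage <- function(eps_d, bands = c(7, 9, 13)) {
  .check_numeric(eps_d, "eps_d")
  if (any(eps_d < 0)) .err_domain("eps_d must be >= 0")
  if (length(bands) != 3L || is.unsorted(bands, strictly = TRUE)) {
    .err_domain("bands must be three strictly increasing boundaries")
  }
  cut(eps_d,
      breaks = c(-Inf, bands, Inf),
      labels = c("well_watered", "slight", "moderate", "severe"),
      right = FALSE, ordered_result = TRUE)
}
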