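#' Fluorescence quartet from quenching targets
#'
#' Algebraic inversion of the quenching formulas: builds a raw fluorescence
#' quartet whose derived parameters reproduce given targets exactly,
#' \deqn{F_m' = F_m/(NPQ+1), \quad F_s = F_m'(1-\Phi), \quad
#'       F_o = F_m (1 - F_v/F_m).}
#' Recomputing [chlf_params()] on the result returns `(phi, npq, fvfm)` to
#' machine precision. A quartet has three free signal ratios, so exactly
#' three ratio targets can be prescribed; all remaining quantities (`q_L`,
#' `Phi_NO`, `F_o'`) follow.
#'
#' @param phi effective PSII quantum yield target, in (0, 1).
#' @param npq nonphotochemical quenching target, >= 0.
#' @param fvfm dark-adapted maximum efficiency target, in (0, 1).
#' @param f_m maximal dark-adapted fluorescence scale (a.u., > 0).
#' @return data frame with columns `f_s`, `f_m_prime`, `f_o`, `f_m`.
#' @examples
#' fluorescence_from_targets(0.25, 1, 0.769, 1)
#' @export
fluorescence_from_targets <- function(phi, npq, fvfm, f_m = 1) {
  .check_numeric(phi, "phi")
  .check_numeric(npq, "npq")
  .check_numeric(fvfm, "fvfm")
  .check_numeric(f_m, "f_m")
  if (any(phi <= 0 | phi >= 1)) .err_domain("phi must lie in (0, 1)")
  if (any(npq < 0)) .err_domain("npq must be >= 0")
  if (any(fvfm <= 0 | fvfm >= 1)) .err_domain("fvfm must lie in (0, 1)")
  if (any(f_m <= 0)) .err_domain("f_m must be > 0")
  f_m_prime <- f_m / (npq + 1)
  f_s <- f_m_prime * (1 - phi)
  f_o <- f_m * (1 - fvfm)
  quartet <- data.frame(f_s = f_s, f_m_prime = f_m_prime,
                        f_o = f_o, f_m = rep_len(f_m, length(f_s)))
  reason <- .fluor_invalid_reason(quartet)
  if (any(!is.na(reason))) {
    i <- which(!is.na(reason))[1L]
    .err(sprintf("infeasible target combination at element %d: %s",
                 i, reason[i]), "phistress_feasibility_error")
  }
  quartet
}

# With the F_o' estimate used throughout, the yield of non-regulated losses
# collapses algebraically to Phi_NO = F_s/F_m = (1 - Phi)/(1 + NPQ): it is
# fully determined by (Phi, NPQ), independent of Fv/Fm. The generator
# therefore realizes a per-day Phi_NO floor by solving NPQ from the
# identity, capped below the day's saturating NPQ light curve and at 0.
# Returns the NPQ to emit plus a flag for records where the floor was met
# exactly.
.npq_for_phino_floor <- function(phi, npq_cap, phino_floor) {
  solved <- pmax(0, (1 - phi) / phino_floor - 1)
  npq <- pmin(npq_cap, solved)
  list(npq = npq, hit = solved > 0 & solved <= npq_cap)
}

.record_frame <- function(cultivar, experiment_id, bucket_id, day, time_of_day,
                          par, temp, quartet, vwc_pct, vwc_s_pct) {
  data.frame(
    cultivar = cultivar,
    experiment_id = experiment_id,
    bucket_id = bucket_id,
    day_after_drought = day,
    time_of_day = time_of_day,
    par = par,
    temp = temp,
    f_s = quartet$f_s,
    f_m_prime = quartet$f_m_prime,
    f_o = quartet$f_o,
    f_m = quartet$f_m,
    vwc_pct = vwc_pct,
    vwc_s_pct = vwc_s_pct,
    stringsAsFactors = FALSE
  )
}

#' Simulate a photothermal calibration experiment
#'
#' Emulates the well-watered calibration design: quantum yield measured at
#' three fixed irradiance levels (285/625/1150 umol photons m-2 s-1) across
#' a temperature sweep (default 10 temperatures from 11.8 to 42.7 degC,
#' giving the 30-point design). Yields come from the archetype's
#' photothermal model; Gaussian noise of SD `sigma_phi` is added on the
#' yield scale and propagated into the steady fluorescence `F_s`, then full
#' quartets are reconstructed with [fluorescence_from_targets()].
#' Temperatures outside the cardinal range are emitted with
#' `in_model_range = FALSE` (their noise-free yield extends the sine
#' formula), so downstream range filtering is exercised.
#'
#' @param arch a [cultivar_archetype()].
#' @param par_levels irradiance levels.
#' @param temps temperature sweep, degC.
#' @param sigma_phi additive Gaussian SD on the yield (default 0.02).
#' @param seed optional RNG seed for reproducible output.
#' @return list with `records` (a fluorescence-record table, day 0,
#'   well-watered) and `truth` (every generating parameter).
#' @export
simulate_photothermal <- function(arch,
                                  par_levels = c(285, 625, 1150),
                                  temps = seq(11.8, 42.7, length.out = 10),
                                  sigma_phi = 0.02,
                                  seed = NULL) {
  stopifnot(inherits(arch, "cultivar_archetype"))
  if (sigma_phi < 0) .err_domain("sigma_phi must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  pt <- arch$photothermal
  design <- expand.grid(temp = temps, par = par_levels,
                        KEEP.OUT.ATTRS = FALSE)
  phi_true <- .phi_photothermal(design$temp, design$par, pt, extend = TRUE)
  phi_true <- .clip(phi_true, 0.001, 0.999)
  npq <- .npq_at(arch, 1, design$par) # pre-drought quenching level
  quartet <- fluorescence_from_targets(phi_true, npq, pt$fvfm, f_m = 1)
  phi_obs <- .clip(phi_true + stats::rnorm(nrow(design), 0, sigma_phi),
                   0.001, 0.999)
  quartet$f_s <- quartet$f_m_prime * (1 - phi_obs)

  rec <- .record_frame(
    cultivar = arch$name,
    experiment_id = "photothermal",
    bucket_id = sprintf("b%02d", rep_len(1:5, nrow(design))),
    day = 0L,
    time_of_day = "09:00",
    par = design$par,
    temp = design$temp,
    quartet = quartet,
    vwc_pct = arch$vwc_s,
    vwc_s_pct = arch$vwc_s
  )
  rec$in_model_range <- design$temp >= pt$t_min & design$temp <= pt$t_max
  list(
    records = rec,
    truth = list(
      cultivar = arch$name,
      photothermal = unclass(pt),
      design = list(par_levels = par_levels, temps = temps),
      sigma_phi = sigma_phi,
      phi_true = phi_true,
      seed = seed
    )
  )
}

#' Simulate a progressive-drought diurnal experiment
#'
#' Emulates the drying-cycle protocol: on each measurement day a diurnal
#' irradiance ramp from 0 to 1200 umol photons m-2 s-1 (six steps of 240,
#' one per hour from 06:00) at near-optimal temperature (uniform in 29 +/-
#' 1.5 degC), with several replicate leaves per step. Substrate water
#' content follows the archetype's drying anchors (log-linear between
#' anchored days); yields come from the drought-attenuated model.
#'
#' Quenching dynamics exploit the identity `Phi_NO = F_s/F_m =
#' (1-Phi)/(1+NPQ)` (an algebraic consequence of the `F_o'` estimate): the
#' archetype's per-day `Phi_NO` trajectory (baseline + step + slope) acts
#' as a floor, realized by solving `NPQ = (1-Phi)/Phi_NO_floor - 1` and
#' capping it below the day's saturating NPQ light response and at 0.
#' Where a bound binds — e.g. at `PAR = 0`, where `Phi_NO` is forced to
#' `1-Phi` — the emitted `Phi_NO` deviates from the floor towards the
#' attainable range; such records are counted in the truth record. Yield
#' noise is added on the `Phi` scale and propagated into `F_s`;
#' water-content observations get Gaussian noise of SD `sigma_rswc`
#' (fraction scale).
#'
#' @param arch a [cultivar_archetype()].
#' @param days measurement days after withholding irrigation.
#' @param par_levels diurnal irradiance steps.
#' @param n_leaves replicate leaves per irradiance step.
#' @param temp_range uniform temperature range, degC.
#' @param sigma_phi additive Gaussian SD on yield (default 0.02).
#' @param sigma_rswc Gaussian SD of the water-content observation, fraction
#'   scale (default 0.01).
#' @param seed optional RNG seed.
#' @return list with `records` and `truth` (generating parameters, per-day
#'   true rswc, per-day Phi_NO targets, and the count of records whose
#'   Phi_NO target was clamped to the attainable range).
#' @export
simulate_drought <- function(arch,
                             days = c(1L, 3L, 5L, 7L, 9L),
                             par_levels = seq(0, 1200, by = 240),
                             n_leaves = 4L,
                             temp_range = c(27.5, 30.5),
                             sigma_phi = 0.02,
                             sigma_rswc = 0.01,
                             seed = NULL) {
  stopifnot(inherits(arch, "cultivar_archetype"))
  if (sigma_phi < 0 || sigma_rswc < 0) .err_domain("noise SDs must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  dp <- arch$drought
  pt <- arch$photothermal

  rswc_day <- .rswc_at_day(arch$rswc_day_anchors, days)
  design <- expand.grid(leaf = seq_len(n_leaves), par = par_levels,
                        day = days, KEEP.OUT.ATTRS = FALSE)
  design$rswc_true <- rswc_day[match(design$day, days)]
  design$temp <- stats::runif(nrow(design), temp_range[1], temp_range[2])

  phi_true <- phi_drought(design$temp, design$par, design$rswc_true, dp)
  phi_true <- .clip(phi_true, 0.001, 0.999)
  npq_cap <- .npq_at(arch, design$day, design$par)
  phino_floor <- .phino_target_at(arch, design$day)
  sol <- .npq_for_phino_floor(phi_true, npq_cap, phino_floor)

  f_m <- stats::runif(nrow(design), 0.9, 1.1) # per-leaf signal scale
  quartet <- fluorescence_from_targets(phi_true, sol$npq, pt$fvfm, f_m = f_m)
  phi_obs <- .clip(phi_true + stats::rnorm(nrow(design), 0, sigma_phi),
                   0.001, 0.999)
  quartet$f_s <- quartet$f_m_prime * (1 - phi_obs)

  rswc_obs <- .clip(design$rswc_true +
                      stats::rnorm(nrow(design), 0, sigma_rswc),
                    0.01, 1)
  hour <- 6L + match(design$par, sort(unique(par_levels))) - 1L
  rec <- .record_frame(
    cultivar = arch$name,
    experiment_id = "drought",
    bucket_id = sprintf("b%02d", design$leaf),
    day = design$day,
    time_of_day = sprintf("%02d:00", hour),
    par = design$par,
    temp = design$temp,
    quartet = quartet,
    vwc_pct = rswc_obs * arch$vwc_s,
    vwc_s_pct = arch$vwc_s
  )
  rec$in_model_range <- TRUE
  list(
    records = rec,
    truth = list(
      cultivar = arch$name,
      photothermal = unclass(pt),
      drought = list(c = dp$c, d = dp$d, rswc_c = dp$rswc_c),
      rswc_by_day = stats::setNames(rswc_day, days),
      phino_floor_by_day = stats::setNames(.phino_target_at(arch, days), days),
      npq_max_by_day = arch$npq_max_by_day,
      sigma_phi = sigma_phi,
      sigma_rswc = sigma_rswc,
      n_phino_off_floor = sum(!sol$hit),
      phi_true = phi_true,
      seed = seed
    )
  )
}
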