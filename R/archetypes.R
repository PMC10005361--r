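#' Built-in sugarcane cultivar archetypes
#'
#' Parameter bundles describing the two study cultivars for synthetic
#' experiment generation: the drought-resistant 'ROC22' and the
#' drought-susceptible 'ROC16'. Photothermal and drought coefficients are
#' the published estimates for these cultivars (`a_l = 0.688`,
#' `b_l = 6.77e-4`, `a_h = 0.676`, `b_h = 5.16e-4`, `Fv/Fm = 0.769`,
#' `eps = 5.91e-4` for both; `c/d/rswc_c` = 39.63/10.01/0.40 for ROC22 and
#' 286.78/21.53/0.29 for ROC16). Drying-curve anchors pin the relative
#' substrate water content at the observed day-5 values (40% ROC22, 29%
#' ROC16) and day-3 value (56% ROC16); days not anchored are filled by
#' log-linear (exponential-drying) interpolation. The NPQ ceiling contrast
#' (approaching 1.6 at PAR 1200 for ROC22 vs staying below 1.3 for ROC16)
#' and the non-regulated-loss (`Phi_NO`) step days (5 for ROC22, 3 for
#' ROC16) reproduce the qualitative drought-response contrast; their
#' saturating/step functional forms are generator conventions, not
#' measured curves.
#'
#' @param name `"roc22"` or `"roc16"`.
#' @param ... named overrides for any archetype field (e.g.
#'   `rswc_day_anchors`, `npq_max_by_day`, `phino_step_day`).
#' @return an object of class `cultivar_archetype`: a list with fields
#'   `name`, `photothermal` ([photothermal_params()]), `drought`
#'   ([drought_params()]), `rswc_day_anchors` (named vector, day ->
#'   fraction, strictly decreasing), `npq_max_by_day` (day -> saturating
#'   NPQ asymptote), `npq_half_saturation` (irradiance at half saturation),
#'   `phino_baseline`, `phino_step_day`, `phino_step_size`,
#'   `phino_slope_after` (per day), and `vwc_s` (percent).
#' @examples
#' cultivar_archetype("roc16")$drought
#' @export
cultivar_archetype <- function(name = c("roc22", "roc16"), ...) {
  name <- match.arg(name)
  pt <- photothermal_params(
    a_l = 0.688, b_l = 6.77e-4,
    a_h = 0.676, b_h = 5.16e-4,
    fvfm = 0.769, eps = 5.91e-4
  )
  arch <- if (name == "roc22") {
    list(
      name = "roc22",
      photothermal = pt,
      drought = drought_params(c = 39.63, d = 10.01, rswc_c = 0.40, base = pt),
      rswc_day_anchors = c(`0` = 1.00, `1` = 0.83, `3` = 0.58,
                           `5` = 0.40, `7` = 0.27, `9` = 0.18),
      npq_max_by_day = c(`1` = 0.90, `3` = 1.20, `5` = 1.85,
                         `7` = 1.85, `9` = 1.85),
      npq_half_saturation = 200,
      phino_baseline = 0.22,
      phino_step_day = 5L,
      phino_step_size = 0.03,
      phino_slope_after = 0.005,
      vwc_s = 38
    )
  } else {
    list(
      name = "roc16",
      photothermal = pt,
      drought = drought_params(c = 286.78, d = 21.53, rswc_c = 0.29, base = pt),
      rswc_day_anchors = c(`0` = 1.00, `1` = 0.82, `3` = 0.56,
                           `5` = 0.29, `7` = 0.20, `9` = 0.15),
      npq_max_by_day = c(`1` = 0.90, `3` = 1.00, `5` = 1.10,
                         `7` = 1.40, `9` = 1.40),
      npq_half_saturation = 200,
      phino_baseline = 0.30,
      phino_step_day = 3L,
      phino_step_size = 0.08,
      phino_slope_after = 0.01,
      vwc_s = 38
    )
  }
  over <- list(...)
  bad <- setdiff(names(over), names(arch))
  if (length(bad)) {
    .err_validation(paste("unknown archetype fields:", paste(bad, collapse = ", ")))
  }
  arch[names(over)] <- over
  anchors <- arch$rswc_day_anchors
  if (is.unsorted(rev(anchors), strictly = TRUE)) {
    .err_validation("rswc_day_anchors must be strictly decreasing in day")
  }
  structure(arch, class = "cultivar_archetype")
}

#' @export
print.cultivar_archetype <- function(x, ...) {
  cat(sprintf("Cultivar archetype '%s'\n", x$name))
  print(x$photothermal)
  print(x$drought)
  cat("  rswc anchors (day -> fraction):\n")
  print(x$rswc_day_anchors)
  cat(sprintf("  Phi_NO: baseline %g, +%g from day %d, +%g/day after\n",
              x$phino_baseline, x$phino_step_size, x$phino_step_day,
              x$phino_slope_after))
  invisible(x)
}

# log-linear (exponential drying) interpolation of rswc anchors; days past
# the last anchor extrapolate the final log-slope
.rswc_at_day <- function(anchors, day) {
  ad <- as.numeric(names(anchors))
  stopifnot(!is.unsorted(ad, strictly = TRUE))
  la <- log(anchors)
  vapply(day, function(dd) {
    if (dd < min(ad)) .err_domain("day precedes the first rswc anchor")
    if (dd >= max(ad)) {
      k <- length(ad)
      slope <- (la[k] - la[k - 1L]) / (ad[k] - ad[k - 1L])
      return(exp(la[k] + slope * (dd - ad[k])))
    }
    exp(stats::approx(ad, la, xout = dd)$y)
  }, numeric(1))
}

# per-day generator targets
.npq_at <- function(arch, day, par) {
  amps <- arch$npq_max_by_day
  ad <- as.numeric(names(amps))
  amp <- stats::approx(ad, amps, xout = .clip(day, min(ad), max(ad)),
                       rule = 2)$y
  amp * par / (par + arch$npq_half_saturation)
}

.phino_target_at <- function(arch, day) {
  arch$phino_baseline +
    arch$phino_step_size * (day >= arch$phino_step_day) +
    arch$phino_slope_after * pmax(0, day - arch$phino_step_day)
}
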