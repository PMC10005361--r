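#' Excitation-energy distribution curves under progressive drought
#'
#' Summarizes derived quenching parameters per cultivar, day after drought
#' and irradiance bin: bin-wise means and standard deviations of the PSII
#' quantum yield, nonphotochemical quenching, and the yield of non-regulated
#' losses. Single-record bins report the record's value with a missing SD.
#' A per-day mean `rswc` is carried along when available so turning points
#' can be reported on the water-status scale.
#'
#' @param records derived fluorescence table (see [chlf_params()]) with
#'   columns `cultivar`, `day_after_drought`, `par`, `phi`, `npq`, `phi_no`
#'   and optionally `rswc`.
#' @param bin_width irradiance bin width, umol photons m-2 s-1 (default 100).
#' @param par_range range covered by the bins (default `c(0, 1200)`).
#' @return a data frame of class `energy_curves` with one row per
#'   cultivar x day x non-empty bin: `bin_lo`, `bin_hi`, `bin_mid`, `n`,
#'   `*_mean`, `*_sd` columns and `rswc_mean`. Row order is deterministic
#'   and independent of the input record order.
#' @export
energy_curves <- function(records, bin_width = 100, par_range = c(0, 1200)) {
  need <- c("cultivar", "day_after_drought", "par", "phi", "npq", "phi_no")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    .err_validation(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  if (bin_width <= 0) .err_domain("bin_width must be > 0")
  breaks <- seq(par_range[1], par_range[2] + bin_width * 1e-9, by = bin_width)
  if (max(records$par) > max(breaks) || min(records$par) < min(breaks)) {
    warning("records outside par_range dropped from energy curves")
    keep <- records$par >= min(breaks) & records$par <= max(breaks)
    records <- records[keep, , drop = FALSE]
  }
  bin <- cut(records$par, breaks = breaks, include.lowest = TRUE, right = TRUE)
  has_rswc <- "rswc" %in% names(records)

  key <- list(cultivar = records$cultivar,
              day = records$day_after_drought,
              bin = bin)
  agg <- function(x, f) {
    a <- stats::aggregate(x, by = key, FUN = f)
    a$x
  }
  sd_or_na <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)
  base <- stats::aggregate(records$par, by = key, FUN = length)
  out <- data.frame(
    cultivar = base$cultivar,
    day_after_drought = base$day,
    bin_lo = breaks[as.integer(base$bin)],
    bin_hi = breaks[as.integer(base$bin) + 1L],
    n = base$x,
    phi_mean = agg(records$phi, mean),
    phi_sd = agg(records$phi, sd_or_na),
    npq_mean = agg(records$npq, mean),
    npq_sd = agg(records$npq, sd_or_na),
    phi_no_mean = agg(records$phi_no, mean),
    phi_no_sd = agg(records$phi_no, sd_or_na),
    rswc_mean = if (has_rswc) agg(records$rswc, mean) else NA_real_
  )
  out$bin_mid <- (out$bin_lo + out$bin_hi) / 2
  out <- out[order(out$cultivar, out$day_after_drought, out$bin_lo), ]
  rownames(out) <- NULL
  class(out) <- c("energy_curves", "data.frame")
  out
}

#' Detect the turning point of non-regulated energy losses
#'
#' Finds, per cultivar, the earliest day after drought whose all-PAR mean
#' yield of non-regulated losses exceeds the day-1 baseline by more than a
#' relative threshold. A sustained rise in this yield signals accumulating
#' photosystem damage; the threshold rule (default 10% over the baseline
#' day) is this package's operationalization and is exposed as a parameter.
#' Days are compared on record-weighted all-PAR means, not per-bin tests.
#'
#' @param curves an [energy_curves()] table.
#' @param rel_threshold relative rise over the baseline-day mean that counts
#'   as a turning point (default 0.10).
#' @param baseline_day day used as the baseline (default 1).
#' @return data frame with one row per cultivar: `day` (NA when the rise
#'   never exceeds the threshold), `phi_no_baseline`, `phi_no_at_day`, and
#'   `rswc_at_day` (mean rswc of the detected day, NA when unavailable).
#' @export
phino_turning_point <- function(curves, rel_threshold = 0.10,
                                baseline_day = 1) {
  stopifnot(inherits(curves, "data.frame"))
  if (rel_threshold < 0) .err_domain("rel_threshold must be >= 0")
  res <- lapply(split(curves, curves$cultivar), function(cu) {
    days <- sort(unique(cu$day_after_drought))
    if (!(baseline_day %in% days)) {
      .err_validation(sprintf(
        "cultivar '%s' has no baseline day %g curve",
        cu$cultivar[1], baseline_day
      ))
    }
    day_mean <- vapply(days, function(d) {
      g <- cu[cu$day_after_drought == d, ]
      stats::weighted.mean(g$phi_no_mean, g$n)
    }, numeric(1))
    day_rswc <- vapply(days, function(d) {
      g <- cu[cu$day_after_drought == d, ]
      stats::weighted.mean(g$rswc_mean, g$n)
    }, numeric(1))
    base <- day_mean[days == baseline_day]
    later <- days > baseline_day
    hit <- later & day_mean > base * (1 + rel_threshold)
    day <- if (any(hit)) min(days[hit]) else NA_integer_
    data.frame(
      cultivar = cu$cultivar[1],
      day = day,
      phi_no_baseline = base,
      phi_no_at_day = if (is.na(day)) NA_real_ else day_mean[days == day],
      rswc_at_day = if (is.na(day)) NA_real_ else day_rswc[days == day]
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
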