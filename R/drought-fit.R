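# weighted least-squares fit of (c, d) to elevated index values below a
# candidate changepoint. For fixed d the amplitude has the closed form
# c(d) = sum(w e_i y_i) / sum(w e_i^2), e_i = exp(-d r_i),
# y_i = eps_i - eps_s, so only d needs a 1-D search (coarse grid + local
# refinement).
.fit_cd <- function(rswc, eps_elev, w, d_interval = c(0, 100)) {
  sse_at <- function(d) {
    e <- exp(-d * rswc)
    ch <- sum(w * e * eps_elev) / sum(w * e * e)
    ch <- max(ch, 0)
    c(sse = sum(w * (eps_elev - ch * e)^2), c = ch)
  }
  dg <- seq(d_interval[1], d_interval[2], length.out = 101)
  vals <- vapply(dg, function(d) sse_at(d)[["sse"]], numeric(1))
  i <- which.min(vals)
  lo <- dg[max(1L, i - 1L)]
  hi <- dg[min(length(dg), i + 1L)]
  opt <- stats::optimize(function(d) sse_at(d)[["sse"]],
                         interval = c(lo, hi), tol = 1e-7)
  best <- sse_at(opt$minimum)
  list(c = best[["c"]], d = opt$minimum, sse = best[["sse"]])
}

#' Fit the drought-stress model by changepoint profiling
#'
#' Estimates the drought coefficients `(c, d)` and the critical relative
#' substrate water content `rswc_c` from drought-experiment records. The
#' procedure follows the structure of the index model:
#'
#' 1. each observed yield is inverted to a per-record scaled index against
#'    the supplied well-watered model (the closed form of the exponential
#'    attenuation; it agrees with the bisection of [invert_epsilon_d()] to
#'    tolerance). Records with `par < par_min` are excluded with a logged
#'    count. The reported per-record index is clamped at the baseline, as
#'    in [invert_epsilon_d()], but the regression below uses the *signed*
#'    elevation — truncating the above-prediction observations (negative
#'    apparent stress, i.e. pure noise) would censor the error
#'    distribution and bias the coefficients downward;
#' 2. for every candidate changepoint on a grid (all observed `rswc` values
#'    plus a regular 0.01-step grid over `[0.05, 0.95]` by default), the
#'    exponential rise is fitted by weighted least squares to the records
#'    at or below the candidate, while records above it are scored against
#'    the baseline index. Weights are the delta-method precisions of the
#'    inverted index, proportional to `(PAR * Phi)^2` with `Phi` a model
#'    prediction (well-watered on the first pass, then the fitted drought
#'    model on one IRLS refinement pass): yield noise of fixed SD blows up
#'    enormously on the index scale at low irradiance or collapsed yield,
#'    so equal weighting would let those records dominate, while weighting
#'    by the *observed* yield would correlate the weights with the noise
#'    and bias the coefficients;
#' 3. the winning changepoint is the *left edge* of the low-SSE region: the
#'    smallest candidate whose SSE is within `sse_tol` (relative) of the
#'    profile minimum. Above the true changepoint the profile is nearly
#'    flat — the fitted exponential passes close to zero there, so
#'    unstressed records are almost equally well described on either side
#'    of the candidate — while below it the profile rises sharply as
#'    genuinely stressed records are forced onto the baseline. The left
#'    edge therefore marks the changepoint; with noise-free data the rule
#'    reduces to exact recovery up to the grid resolution.
#'
#' @param data data frame with columns `temp`, `par`, `phi` (observed
#'   yield) and `rswc` (fraction).
#' @param base the fitted or known well-watered [photothermal_params()].
#' @param par_min irradiance threshold below which records are excluded
#'   (default 50 umol photons m-2 s-1; the attenuation factor tends to 1
#'   there and the index is unidentifiable).
#' @param grid optional numeric vector of candidate changepoints; default as
#'   described above.
#' @param sse_tol relative SSE tolerance defining the low-SSE region whose
#'   left edge is reported (default 0.05).
#' @param d_interval search interval for the decay rate `d`.
#' @param attenuation forward-model variant, see [phi_drought()].
#' @param group optional grouping factor (length `nrow(data)`) marking
#'   records that share a single substrate water status — typically the
#'   measurement day, since water content is read once per pot each morning
#'   while many leaves are measured. The regression then uses the
#'   group-mean `rswc`, averting the regression-dilution bias that
#'   per-record observation noise in the regressor would otherwise cause.
#' @return an object of class `drought_fit` with components `params` (a
#'   [drought_params()] object), `coefficients` (`c`, `d`, `rswc_c`),
#'   `eps_data` (per-record `rswc`, `eps_d` and clamp flags), `profile`
#'   (candidate grid with SSE and conditional `(c, d)`), `sse`, `jump` (the
#'   index discontinuity at the fitted changepoint, a diagnostic),
#'   `n`, `n_excluded_par`, `n_clamped`. Methods: `print`, `summary`,
#'   `coef`, `predict`, `plot`.
#' @examples
#' arch <- cultivar_archetype("roc22")
#' sim <- simulate_drought(arch, sigma_phi = 0, sigma_rswc = 0, seed = 1)
#' d <- chlf_params(sim$records)
#' fit <- suppressWarnings(
#'   fit_drought(d, base = arch$photothermal)
#' )
#' coef(fit)
#' @export
fit_drought <- function(data, base, par_min = 50, grid = NULL,
                        sse_tol = 0.05, d_interval = c(0, 100),
                        attenuation = c("ratio", "literal"),
                        group = NULL) {
  attenuation <- match.arg(attenuation)
  stopifnot(inherits(base, "photothermal_params"))
  need <- c("temp", "par", "phi", "rswc")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    .err_validation(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  if (!is.null(group)) {
    if (length(group) != nrow(data)) {
      .err_validation("group must have one entry per data row")
    }
    data$.group <- as.character(group)
  }
  keep_cols <- c(need, if (!is.null(group)) ".group")
  data <- data[stats::complete.cases(data[need]), keep_cols, drop = FALSE]
  low_par <- data$par < par_min
  if (any(low_par)) {
    message(sprintf(
      "fit_drought: excluded %d record(s) with par < %g", sum(low_par), par_min
    ))
    data <- data[!low_par, , drop = FALSE]
  }
  data <- .filter_temp_range(data, base$t_min, base$t_max)
  if (nrow(data) < 3L) .err_validation("too few usable records")
  if (!is.null(group)) {
    data$rswc <- stats::ave(data$rswc, data$.group)
  }

  eps_s <- .eps_scaled(base)
  # closed-form inversion of the exponential attenuation. The regression
  # uses the *signed* elevation: truncating observations that fall above
  # the well-watered prediction (negative apparent stress, pure noise)
  # would censor the error distribution and bias (c, d) downward. The
  # reported per-record index is still clamped at the baseline, matching
  # invert_epsilon_d().
  phi_ww <- phi_photothermal(data$temp, data$par, base)
  elev <- -1e4 * log(data$phi / phi_ww) / data$par -
    if (attenuation == "literal") eps_s else 0
  eps_d <- pmax(eps_s, eps_s + elev)
  clamped <- elev <= 1e-12

  if (is.null(grid)) {
    grid <- sort(unique(c(seq(0.05, 0.95, by = 0.01), round(data$rswc, 6))))
  }
  grid <- grid[grid > 0 & grid < 1]

  # delta-method precision of each inverted index: var(eps_D) is
  # proportional to (1e4 / (PAR * Phi))^2 on the yield-noise scale, so the
  # profile uses inverse-variance weights. The Phi entering the weights is
  # a *model prediction*, never the observation — observed-yield weights
  # correlate with the noise and bias the weighted elevations downward.
  # Pass 1 weights by the well-watered prediction; pass 2 reweights by the
  # pass-1 fitted drought model (one IRLS refinement).
  profile_fit <- function(w) {
    w <- w / mean(w)
    prof <- lapply(grid, function(cc) {
      below <- data$rswc <= cc
      if (sum(below) < 2L || length(unique(data$rswc[below])) < 2L) {
        return(NULL)
      }
      cd <- .fit_cd(data$rswc[below], elev[below], w[below], d_interval)
      data.frame(rswc_c = cc, c = cd$c, d = cd$d,
                 sse = cd$sse + sum(w[!below] * elev[!below]^2))
    })
    prof <- do.call(rbind, prof)
    if (is.null(prof) || nrow(prof) == 0L) {
      .err(paste(
        "changepoint not identifiable:",
        "no candidate has two distinct rswc values at or below it"
      ), "phistress_changepoint_error")
    }
    # a changepoint needs an actual index elevation somewhere: when the
    # best candidate barely improves on the all-baseline null model the
    # data lie entirely above the changepoint (or carry no stress signal)
    null_sse <- sum(w * elev^2)
    if (null_sse <= 1e-12 * nrow(data) || min(prof$sse) > 0.5 * null_sse) {
      .err(paste(
        "changepoint not identifiable:",
        "no detectable index elevation below any candidate"
      ), "phistress_changepoint_error")
    }
    in_band <- prof$sse <= min(prof$sse) * (1 + sse_tol) + 1e-12
    list(best = prof[which(in_band)[1L], ], prof = prof) # low-SSE left edge
  }

  pass1 <- profile_fit((data$par * phi_ww)^2)
  params1 <- drought_params(pass1$best$c, pass1$best$d, pass1$best$rswc_c,
                            base)
  phi_hat <- phi_drought(data$temp, data$par, data$rswc, params1,
                         attenuation = attenuation)
  pass2 <- profile_fit((data$par * phi_hat)^2)
  best <- pass2$best
  prof <- pass2$prof

  params <- drought_params(best$c, best$d, best$rswc_c, base)
  out <- list(
    params = params,
    coefficients = c(c = best$c, d = best$d, rswc_c = best$rswc_c),
    eps_data = data.frame(rswc = data$rswc, par = data$par,
                          temp = data$temp, phi = data$phi,
                          eps_d = eps_d, clamped = clamped),
    profile = prof,
    sse = best$sse,
    jump = best$c * exp(-best$d * best$rswc_c),
    n = nrow(data),
    n_excluded_par = sum(low_par),
    n_clamped = sum(clamped),
    attenuation = attenuation,
    call = match.call()
  )
  class(out) <- "drought_fit"
  out
}

#' @export
print.drought_fit <- function(x, digits = 4, ...) {
  cat("Drought-stress model fit (changepoint profile)\n")
  cat(sprintf("  rswc_c = %s, c = %s, d = %s\n",
              format(x$coefficients[["rswc_c"]], digits = digits),
              format(x$coefficients[["c"]], digits = digits),
              format(x$coefficients[["d"]], digits = digits)))
  cat(sprintf("  n = %d (excluded low-PAR: %d, clamped at baseline: %d)\n",
              x$n, x$n_excluded_par, x$n_clamped))
  cat(sprintf("  SSE = %s, index jump at changepoint = %s\n",
              format(x$sse, digits = digits), format(x$jump, digits = digits)))
  invisible(x)
}

#' @export
coef.drought_fit <- function(object, ...) object$coefficients

#' @export
summary.drought_fit <- function(object, ...) {
  stages <- drought_stage(object$eps_data$eps_d)
  structure(
    list(coefficients = object$coefficients, sse = object$sse,
         jump = object$jump, n = object$n,
         n_excluded_par = object$n_excluded_par,
         n_clamped = object$n_clamped,
         stage_counts = table(stages),
         eps_range = range(object$eps_data$eps_d)),
    class = "summary.drought_fit"
  )
}

#' @export
print.summary.drought_fit <- function(x, digits = 4, ...) {
  cat("Drought-stress model (changepoint profile fit)\n\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nSSE = %s; index jump at changepoint = %s\n",
              format(x$sse, digits = digits), format(x$jump, digits = digits)))
  cat(sprintf("eps_D range: %s - %s\n",
              format(x$eps_range[1], digits = digits),
              format(x$eps_range[2], digits = digits)))
  cat("\nDrought-stage counts over fitted records:\n")
  print(x$stage_counts)
  invisible(x)
}

#' Predict quantum yield (or the index) from a drought fit
#'
#' @param object a `drought_fit`.
#' @param newdata data frame with `temp`, `par`, `rswc`; defaults to the
#'   fitting records.
#' @param type `"phi"` for the drought-attenuated yield, `"eps_d"` for the
#'   stress index at `newdata$rswc`.
#' @param ... unused.
#' @export
predict.drought_fit <- function(object, newdata = NULL,
                                type = c("phi", "eps_d"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$eps_data
  if (type == "eps_d") return(epsilon_d(newdata$rswc, object$params))
  phi_drought(newdata$temp, newdata$par, newdata$rswc, object$params,
              attenuation = object$attenuation)
}

#' @export
fitted.drought_fit <- function(object, ...) {
  predict.drought_fit(object)
}

#' @export
residuals.drought_fit <- function(object, ...) {
  object$eps_data$phi - fitted.drought_fit(object)
}

#' Plot a drought fit
#'
#' Left panel: per-record inverted index values against relative substrate
#' water content with the fitted changepoint curve. Right panel: the SSE
#' profile over candidate changepoints.
#'
#' @param x a `drought_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.drought_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  d <- x$eps_data
  graphics::plot(d$rswc, d$eps_d, xlab = "rSWC (fraction)",
                 ylab = "eps_D (scaled)", main = "Stress index", ...)
  rr <- seq(min(d$rswc), max(d$rswc), length.out = 300)
  graphics::lines(rr, epsilon_d(rr, x$params), col = 2)
  graphics::abline(v = x$coefficients[["rswc_c"]], lty = 2, col = 2)
  graphics::plot(x$profile$rswc_c, x$profile$sse, type = "l",
                 xlab = "candidate rswc_c", ylab = "SSE",
                 main = "Changepoint profile")
  graphics::abline(v = x$coefficients[["rswc_c"]], lty = 2, col = 2)
  invisible(x)
}
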