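# raw model evaluation without constructor validation (safe on the bound
# constraints the optimizer may touch)
.pt_eval <- function(temp, par, a_l, b_l, a_h, b_h, eps,
                     fvfm, t_min, t_o, t_max) {
  phi_bl <- a_l * exp(-b_l * par)
  phi_bh <- a_h * exp(-b_h * par)
  phi_to <- fvfm * exp(-eps * par)
  s <- sin(pi / 2 * (temp - t_min) / (t_o - t_min))
  u <- sin(pi / 2 * (t_max - temp) / (t_max - t_o))
  ifelse(temp <= t_o,
    phi_bl + (phi_to - phi_bl) * s,
    phi_bh + (phi_to - phi_bh) * u
  )
}

# drop observations outside the cardinal-temperature range, with a logged
# warning; returns the kept data
.filter_temp_range <- function(data, t_min, t_max) {
  out <- data$temp < t_min | data$temp > t_max
  if (any(out)) {
    warning(sprintf(
      "excluded %d observation(s) with temperature outside [%g, %g] degC",
      sum(out), t_min, t_max
    ))
    data <- data[!out, , drop = FALSE]
  }
  data
}

# stage 1: for one PAR level the temperature response is linear in
# (phi_bl, phi_bh, phi_to) once the sine weights are fixed, so OLS suffices
.stage1_level <- function(temp, phi, t_min, t_o, t_max) {
  s <- sin(pi / 2 * (temp - t_min) / (t_o - t_min))
  u <- sin(pi / 2 * (t_max - temp) / (t_max - t_o))
  lower <- temp <= t_o
  L <- ifelse(lower, 1 - s, 0)
  H <- ifelse(lower, 0, 1 - u)
  S <- ifelse(lower, s, u)
  fit <- stats::lm.fit(cbind(L = L, H = H, S = S), phi)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  .clip(co, 1e-6, 1)
}

# stage 2: log-linear fits of the three envelopes across PAR levels; the
# intercept of the Phi_To line is pinned at log(fvfm)
.two_stage_fit <- function(data, fvfm, t_min, t_o, t_max) {
  levels <- sort(unique(data$par))
  st1 <- t(vapply(levels, function(p) {
    d <- data[data$par == p, , drop = FALSE]
    .stage1_level(d$temp, d$phi, t_min, t_o, t_max)
  }, numeric(3)))
  bl <- st1[, "L"]; bh <- st1[, "H"]; to <- st1[, "S"]
  fit_exp <- function(y) {
    co <- stats::coef(stats::lm(log(y) ~ levels))
    c(a = .clip(exp(co[[1]]), 1e-6, 1), b = max(0, -co[[2]]))
  }
  lo <- fit_exp(bl)
  hi <- fit_exp(bh)
  eps <- max(0, -sum(levels * log(to / fvfm)) / sum(levels^2))
  list(
    start = c(a_l = lo[["a"]], b_l = lo[["b"]],
              a_h = hi[["a"]], b_h = hi[["b"]], eps = eps),
    levels = data.frame(par = levels, phi_bl = bl, phi_bh = bh, phi_to = to)
  )
}

#' Fit the photothermal quantum-yield model
#'
#' Estimates the five PAR-response coefficients `(a_l, b_l, a_h, b_h, eps)`
#' of the well-watered model (see [phi_photothermal()]) from observations of
#' quantum yield across temperature and irradiance. The dark-adapted
#' `F_v/F_m` is supplied, not fitted: experimentally it is measured directly
#' and fixed to the campaign mean. Cardinal temperatures are fixed constants.
#'
#' Two strategies are available. `"joint"` (default) minimizes the total sum
#' of squared yield residuals over all five coefficients with
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]; bounds `[0,1]` on amplitudes
#' and `[0, 0.1]` on decay rates, relative tolerance `1e-10`), initialized
#' from the two-stage estimates. `"two_stage"` reproduces the classical
#' procedure: a per-PAR-level linear fit of the temperature response (which
#' is linear in the three level yields once the sine weights are formed),
#' followed by log-linear fits of the three envelopes across PAR. On
#' noise-free data the two agree; the joint fit is more stable on small
#' designs.
#'
#' @param data data frame with columns `temp` (degC), `par`
#'   (umol photons m-2 s-1) and `phi` (observed quantum yield). Observations
#'   with temperatures outside the cardinal range are excluded with a
#'   warning.
#' @param fvfm dark-adapted maximum quantum efficiency used for the optimum
#'   envelope (e.g. the mean of the measured `F_v/F_m`).
#' @param t_min,t_o,t_max cardinal temperatures (degC).
#' @param method `"joint"` or `"two_stage"`.
#' @param control optional [minpack.lm::nls.lm.control()] overrides.
#' @return an object of class `photothermal_fit` with components `params`
#'   (a [photothermal_params()] object), `coefficients`, `se`, `sse`,
#'   `sigma`, `fitted.values`, `residuals`, `data`, `method`, `two_stage`
#'   (the stage estimates) and `n`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' arch <- cultivar_archetype("roc22")
#' sim <- simulate_photothermal(arch, sigma_phi = 0, seed = 1)
#' d <- chlf_params(sim$records)
#' fit <- suppressWarnings(
#'   fit_photothermal(d, fvfm = 0.769)
#' )
#' coef(fit)
#' @export
fit_photothermal <- function(data, fvfm, t_min = 15, t_o = 30, t_max = 40,
                             method = c("joint", "two_stage"),
                             control = NULL) {
  method <- match.arg(method)
  need <- c("temp", "par", "phi")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    .err_validation(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  if (!is.numeric(fvfm) || length(fvfm) != 1L || fvfm <= 0 || fvfm >= 1) {
    .err_domain("fvfm must be a single number in (0, 1)")
  }
  data <- .filter_temp_range(data[need], t_min, t_max)
  if (any(data$par < 0)) .err_domain("par must be >= 0")

  n_design <- nrow(unique(data[c("temp", "par")]))
  if (n_design < 5L) {
    .err(sprintf(
      "underdetermined design: %d distinct (temp, par) points for 5 coefficients",
      n_design
    ), "phistress_underdetermined_error")
  }
  if (length(unique(data$par)) < 2L) {
    .err(paste(
      "all observations share one PAR level;",
      "b_l, b_h and eps are jointly unidentifiable"
    ), "phistress_underdetermined_error")
  }
  if (!any(data$temp < t_o) || !any(data$temp > t_o)) {
    .err(paste(
      "observations must span both temperature branches",
      "(below and above t_o)"
    ), "phistress_underdetermined_error")
  }

  ts <- tryCatch(
    .two_stage_fit(data, fvfm, t_min, t_o, t_max),
    error = function(e) NULL
  )
  start <- if (!is.null(ts)) ts$start else
    c(a_l = fvfm * 0.9, b_l = 1e-4, a_h = fvfm * 0.9, b_h = 1e-4, eps = 1e-4)
  lower <- c(0, 0, 0, 0, 0)
  upper <- c(1, 0.1, 1, 0.1, 0.1)
  start <- .clip(start, lower + 1e-8, upper - 1e-8)

  if (method == "two_stage") {
    if (is.null(ts)) .err_convergence("two-stage estimation failed")
    est <- ts$start
    se <- rep(NA_real_, 5)
  } else {
    ctl <- minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 10000,
                                      ftol = 1e-10, ptol = 1e-10)
    if (!is.null(control)) ctl[names(control)] <- control
    df <- data.frame(temp = data$temp, par = data$par, phi = data$phi)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        phi ~ .pt_eval(temp, par, a_l, b_l, a_h, b_h, eps,
                       fvfm, t_min, t_o, t_max),
        data = df,
        start = as.list(start),
        lower = lower, upper = upper,
        control = ctl
      ),
      error = function(e) .err_convergence(
        sprintf("joint fit did not converge: %s", conditionMessage(e))
      )
    )
    est <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 5))
  }

  params <- photothermal_params(est[["a_l"]], est[["b_l"]], est[["a_h"]],
                                est[["b_h"]], fvfm, est[["eps"]],
                                t_min, t_o, t_max)
  fitted_phi <- .phi_photothermal(data$temp, data$par, params)
  res <- data$phi - fitted_phi
  out <- list(
    params = params,
    coefficients = est,
    se = stats::setNames(as.numeric(se), names(est)),
    sse = sum(res^2),
    sigma = sqrt(sum(res^2) / max(1, nrow(data) - length(est))),
    fitted.values = fitted_phi,
    residuals = res,
    data = data,
    method = method,
    two_stage = if (!is.null(ts)) ts$levels else NULL,
    n = nrow(data),
    call = match.call()
  )
  class(out) <- "photothermal_fit"
  out
}

#' @export
print.photothermal_fit <- function(x, digits = 4, ...) {
  cat("Photothermal quantum-yield model fit (", x$method, ")\n", sep = "")
  cat(sprintf("  n = %d, SSE = %s, residual sigma = %s\n",
              x$n, format(x$sse, digits = digits),
              format(x$sigma, digits = digits)))
  print(x$params, digits = digits)
  invisible(x)
}

#' @export
coef.photothermal_fit <- function(object, ...) object$coefficients

#' @export
fitted.photothermal_fit <- function(object, ...) object$fitted.values

#' @export
residuals.photothermal_fit <- function(object, ...) object$residuals

#' @export
summary.photothermal_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(
    list(coefficients = tab, sse = object$sse, sigma = object$sigma,
         n = object$n, method = object$method, params = object$params),
    class = "summary.photothermal_fit"
  )
}

#' @export
print.summary.photothermal_fit <- function(x, digits = 4, ...) {
  cat("Photothermal quantum-yield model (", x$method, " fit)\n\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits, na.print = "-")
  cat(sprintf("\nn = %d, SSE = %s, residual sigma = %s, fixed Fv/Fm = %s\n",
              x$n, format(x$sse, digits = digits),
              format(x$sigma, digits = digits),
              format(x$params$fvfm, digits = digits)))
  invisible(x)
}

#' Predict quantum yield from a photothermal fit
#'
#' @param object a `photothermal_fit`.
#' @param newdata data frame with `temp` and `par`; defaults to the fitting
#'   data.
#' @param ... unused.
#' @return predicted quantum yields.
#' @export
predict.photothermal_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  phi_photothermal(newdata$temp, newdata$par, object$params)
}

#' @export
simulate.photothermal_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, .clip(
    mu + stats::rnorm(length(mu), sd = object$sigma), 0.001, 0.999
  )))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a photothermal fit
#'
#' Observed yields and fitted temperature-response curves, one curve per PAR
#' level in the data.
#'
#' @param x a `photothermal_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.photothermal_fit <- function(x, ...) {
  d <- x$data
  levels <- sort(unique(d$par))
  cols <- seq_along(levels)
  graphics::plot(d$temp, d$phi, col = cols[match(d$par, levels)],
                 xlab = "Temperature (degC)",
                 ylab = "Quantum yield",
                 main = "Photothermal response", ...)
  tt <- seq(x$params$t_min, x$params$t_max, length.out = 200)
  for (i in seq_along(levels)) {
    graphics::lines(tt, phi_photothermal(tt, levels[i], x$params),
                    col = cols[i])
  }
  graphics::legend("topright", legend = paste("PAR", levels),
                   col = cols, lty = 1, pch = 1, bty = "n")
  invisible(x)
}
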