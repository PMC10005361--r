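#' Goodness-of-fit metrics for observed vs simulated yield
#'
#' Computes the coefficient of determination as the squared Pearson
#' correlation between observed and simulated values,
#' \deqn{r^2 = \frac{\left(\sum (x-\bar x)(y-\bar y)\right)^2}
#'   {\sum (x-\bar x)^2 \sum (y-\bar y)^2}}
#' and the relative root mean-squared error
#' \deqn{rRMSE = \frac{\sqrt{\sum_i (OBS_i - SIM_i)^2 / n}}{M}}
#' where `M` is the mean of the *observed* values. Note that `r^2` defined
#' this way is invariant under affine transforms of either argument (it
#' measures association, not agreement), while `rRMSE` is not; the two are
#' deliberately reported together.
#'
#' @param obs observed values (length >= 2, not constant, non-zero mean).
#' @param sim simulated/predicted values, same length.
#' @return an object of class `validation_report`: a list with `r2`,
#'   `rrmse`, `n` and `mean_obs`.
#' @examples
#' validation_metrics(c(1, 3), c(2, 2))$rrmse # 0.5
#' @export
validation_metrics <- function(obs, sim) {
  .check_numeric(obs, "obs")
  .check_numeric(sim, "sim")
  if (length(obs) != length(sim)) {
    .err_validation("obs and sim must have equal length")
  }
  if (length(obs) < 2L) .err_validation("need at least 2 paired values")
  if (stats::sd(obs) == 0) {
    .err_domain("obs is constant; r2 is undefined")
  }
  m <- mean(obs)
  if (m == 0) .err_domain("mean(obs) is zero; rRMSE is undefined")
  r2 <- if (stats::sd(sim) == 0) {
    warning("sim is constant; r2 reported as NA")
    NA_real_
  } else {
    stats::cor(obs, sim)^2
  }
  structure(
    list(
      r2 = r2,
      rrmse = sqrt(mean((obs - sim)^2)) / m,
      n = length(obs),
      mean_obs = m
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, digits = 4, ...) {
  cat("Validation report\n")
  cat(sprintf("  n = %d, mean observed = %s\n",
              x$n, format(x$mean_obs, digits = digits)))
  cat(sprintf("  r2 = %s, rRMSE = %s\n",
              format(x$r2, digits = digits),
              format(x$rrmse, digits = digits)))
  invisible(x)
}
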