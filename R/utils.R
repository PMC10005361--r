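# internal error helpers: every user-facing failure carries a condition class
# so callers can distinguish domain errors (bad values), validation errors
# (inconsistent records), and optimizer problems.
.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "phistress_error")))
}
.err_domain      <- function(msg) .err(msg, "phistress_domain_error")
.err_validation  <- function(msg) .err(msg, "phistress_validation_error")
.err_convergence <- function(msg) .err(msg, "phistress_convergence_error")

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.check_numeric <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    .err_domain(sprintf("'%s' must be finite numeric", name))
  }
  invisible(x)
}

# compact row-index summary for error messages
.rows_msg <- function(idx, max_show = 8L) {
  idx <- sort(unique(idx))
  shown <- paste(utils::head(idx, max_show), collapse = ", ")
  if (length(idx) > max_show) shown <- paste0(shown, ", ...")
  sprintf("%d record(s) (rows %s)", length(idx), shown)
}
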