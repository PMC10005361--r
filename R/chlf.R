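#' Minimal fluorescence of light-adapted leaves
#'
#' Estimates `F_o'`, the minimal fluorescence a light-adapted leaf would show
#' with all PSII centers open, from the dark-adapted minimal fluorescence
#' `F_o`, the dark-adapted maximum quantum yield `F_v/F_m`, and the
#' light-adapted maximal fluorescence `F_m'`:
#' \deqn{F_o' = F_o / (F_v/F_m + F_o/F_m')}
#'
#' @param f_o minimal dark-adapted fluorescence (arbitrary units, > 0).
#' @param fvfm dark-adapted maximum PSII quantum efficiency, in (0, 1).
#' @param f_m_prime maximal light-adapted fluorescence (a.u., > 0).
#' @return `F_o'` in the same arbitrary units as the inputs; always in
#'   `(0, f_m_prime)`.
#' @examples
#' fo_prime(0.2, 0.769, 0.5)
#' @export
fo_prime <- function(f_o, fvfm, f_m_prime) {
  .check_numeric(f_o, "f_o")
  .check_numeric(fvfm, "fvfm")
  .check_numeric(f_m_prime, "f_m_prime")
  if (any(f_o <= 0) || any(f_m_prime <= 0)) {
    .err_domain("fluorescence signals must be > 0")
  }
  if (any(fvfm <= 0) || any(fvfm >= 1)) {
    .err_domain("fvfm must lie in (0, 1)")
  }
  f_o / (fvfm + f_o / f_m_prime)
}

#' Relative substrate water content
#'
#' `rSWC = VWC / VWC_s`: volumetric water content relative to its value at
#' saturation. Both arguments may be in percent or in any common unit; the
#' result is a dimensionless fraction in `[0, 1]`.
#'
#' @param vwc volumetric water content (>= 0).
#' @param vwc_s saturated volumetric water content (> 0), same units as `vwc`.
#' @return fraction in `[0, 1]`.
#' @examples
#' rel_swc(15.2, 38) # 0.4
#' @export
rel_swc <- function(vwc, vwc_s) {
  .check_numeric(vwc, "vwc")
  .check_numeric(vwc_s, "vwc_s")
  if (any(vwc_s <= 0)) .err_domain("vwc_s must be > 0")
  if (any(vwc < 0)) .err_domain("vwc must be >= 0")
  if (any(vwc > vwc_s)) .err_validation("vwc exceeds saturated vwc_s")
  vwc / vwc_s
}

# reasons (or NA) per record for fluorescence-quartet invariant violations
.fluor_invalid_reason <- function(records) {
  with(records, {
    reason <- rep(NA_character_, nrow(records))
    bad <- !is.finite(f_s) | !is.finite(f_m_prime) | !is.finite(f_o) | !is.finite(f_m)
    reason[bad] <- "non-finite fluorescence value"
    chk <- function(cond, msg) {
      hit <- is.na(reason) & cond
      reason[hit] <<- msg
      invisible(NULL)
    }
    chk(f_o <= 0 | f_s <= 0, "fluorescence must be > 0")
    chk(f_m <= f_o, "requires f_m > f_o")
    chk(f_m_prime < f_s, "requires f_m_prime >= f_s")
    chk(f_m < f_m_prime, "requires f_m >= f_m_prime")
    reason
  })
}

#' Derive chlorophyll-fluorescence quenching parameters
#'
#' Computes, for each raw PAM record, the effective PSII quantum efficiency
#' `Phi = (F_m' - F_s)/F_m'`, the dark-adapted maximum efficiency
#' `F_v/F_m = (F_m - F_o)/F_m`, nonphotochemical quenching
#' `NPQ = F_m/F_m' - 1`, the fraction of open PSII centers
#' `q_L = (F_o'/F_s) (F_m' - F_s)/(F_m' - F_o')` (lake model), and the yield
#' of non-regulated energy losses
#' `Phi_NO = 1 / (NPQ + 1 + q_L (F_m/F_o - 1))`, with `F_o'` from
#' [fo_prime()]. When volumetric water content columns are present, the
#' relative substrate water content `rswc` is appended as a fraction.
#'
#' All derived quantities are ratios of fluorescence signals and are
#' therefore invariant under uniform rescaling of the quartet.
#'
#' @param records data frame with columns `f_s`, `f_m_prime`, `f_o`, `f_m`
#'   (one dark-adapted quartet paired per record by the data producer), and
#'   optionally `vwc_pct`/`vwc_s_pct` (percent) or `vwc`/`vwc_s`.
#' @param phi_fvfm_tol absolute tolerance for the physical ordering
#'   `phi <= fvfm`; violations beyond it raise a warning (measurement noise
#'   can invert the ordering), never an error.
#' @return `records` with columns `f_o_prime`, `phi`, `fvfm`, `npq`, `q_l`,
#'   `phi_no` (and `rswc` when water content is available) appended.
#' @seealso [fluorescence_from_targets()] for the inverse construction.
#' @export
chlf_params <- function(records, phi_fvfm_tol = 0.02) {
  need <- c("f_s", "f_m_prime", "f_o", "f_m")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    .err_validation(paste("missing fluorescence columns:", paste(miss, collapse = ", ")))
  }
  reason <- .fluor_invalid_reason(records)
  if (any(!is.na(reason))) {
    i <- which(!is.na(reason))
    .err_validation(sprintf(
      "invalid fluorescence records: %s; first problem: %s",
      .rows_msg(i), reason[i[1]]
    ))
  }

  fvfm <- (records$f_m - records$f_o) / records$f_m
  phi <- (records$f_m_prime - records$f_s) / records$f_m_prime
  npq <- records$f_m / records$f_m_prime - 1
  fop <- fo_prime(records$f_o, fvfm, records$f_m_prime)
  if (any(abs(records$f_m_prime - fop) < .Machine$double.eps * 8)) {
    .err_validation("degenerate record: f_m_prime equals F_o', q_L undefined")
  }
  q_l <- (fop / records$f_s) * (records$f_m_prime - records$f_s) /
    (records$f_m_prime - fop)
  phi_no <- 1 / (npq + 1 + q_l * (records$f_m / records$f_o - 1))

  n_over <- sum(phi > fvfm + phi_fvfm_tol)
  if (n_over > 0) {
    warning(sprintf(
      "%d record(s) have phi > fvfm + %g; kept (likely measurement noise)",
      n_over, phi_fvfm_tol
    ))
  }

  out <- records
  out$f_o_prime <- fop
  out$phi <- phi
  out$fvfm <- fvfm
  out$npq <- npq
  out$q_l <- q_l
  out$phi_no <- phi_no

  # water content: percent columns (CSV convention) take precedence
  vwc <- if ("vwc_pct" %in% names(out)) out$vwc_pct else out$vwc
  vwc_s <- if ("vwc_s_pct" %in% names(out)) out$vwc_s_pct else out$vwc_s
  if (!is.null(vwc) && !is.null(vwc_s)) {
    ok <- !is.na(vwc) & !is.na(vwc_s)
    out$rswc <- NA_real_
    if (any(ok)) out$rswc[ok] <- rel_swc(vwc[ok], vwc_s[ok])
  }
  out
}
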