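#' Read a fluorescence-record CSV
#'
#' Reads a comma-separated, UTF-8, header-required table of raw PAM records
#' (columns as emitted by [simulate_photothermal()] /
#' [simulate_drought()]: `cultivar`, `experiment_id`, `bucket_id`,
#' `day_after_drought`, `time_of_day`, `par`, `temp`, `f_s`, `f_m_prime`,
#' `f_o`, `f_m`, optional `vwc_pct`, `vwc_s_pct`). Percent columns carry the
#' `_pct` suffix; unsuffixed water columns are fractions. Rows violating the
#' fluorescence invariants are rejected with their row number and reason;
#' the read continues if fewer than `max_reject_frac` of rows are rejected
#' and aborts otherwise.
#'
#' @param path CSV file path.
#' @param max_reject_frac abort threshold for the rejected-row fraction
#'   (default 0.05).
#' @return data frame of valid records; rejected rows (if any) are attached
#'   as attribute `"rejected"` (row numbers and reasons) and reported in a
#'   warning.
#' @export
read_fluorescence_csv <- function(path, max_reject_frac = 0.05) {
  if (!file.exists(path)) .err_validation(sprintf("no such file: %s", path))
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("f_s", "f_m_prime", "f_o", "f_m")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    .err_validation(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  for (col in need) rec[[col]] <- suppressWarnings(as.numeric(rec[[col]]))
  reason <- .fluor_invalid_reason(rec)
  bad <- !is.na(reason)
  if (any(bad)) {
    if (mean(bad) >= max_reject_frac) {
      .err_validation(sprintf(
        "%.0f%% of rows are malformed (first: row %d, %s); aborting",
        100 * mean(bad), which(bad)[1L], reason[which(bad)[1L]]
      ))
    }
    warning(sprintf("rejected %s: %s", .rows_msg(which(bad)),
                    reason[which(bad)[1L]]))
    rej <- data.frame(row = which(bad), reason = reason[bad])
    rec <- rec[!bad, , drop = FALSE]
    attr(rec, "rejected") <- rej
  }
  rec
}

#' Write fluorescence/derived records to CSV
#'
#' Plain UTF-8 comma-separated output with header, '.' decimal separator,
#' no row names; the inverse of [read_fluorescence_csv()].
#'
#' @param records data frame.
#' @param path output path.
#' @export
write_fluorescence_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# serializable view of a parameter document
.params_doc <- function(photothermal = NULL, drought = NULL) {
  doc <- list(package = "phistress",
              version = as.character(utils::packageVersion("phistress")))
  if (!is.null(photothermal)) {
    p <- if (inherits(photothermal, "photothermal_fit")) {
      list(params = photothermal$params, n = photothermal$n,
           sse = photothermal$sse, method = photothermal$method)
    } else {
      list(params = photothermal, n = NA, sse = NA, method = "given")
    }
    doc$photothermal <- c(
      unclass(p$params),
      list(eps_effective = p$params$eps,
           eps_scaled = .eps_scaled(p$params),
           n = p$n, sse = p$sse, method = p$method)
    )
  }
  if (!is.null(drought)) {
    doc$drought <- lapply(drought, function(fit) {
      if (inherits(fit, "drought_fit")) {
        list(c = fit$coefficients[["c"]], d = fit$coefficients[["d"]],
             rswc_c = fit$coefficients[["rswc_c"]], sse = fit$sse,
             jump = fit$jump, n = fit$n,
             n_excluded_par = fit$n_excluded_par,
             n_clamped = fit$n_clamped)
      } else {
        list(c = fit$c, d = fit$d, rswc_c = fit$rswc_c)
      }
    })
  }
  doc
}

#' Write a model-parameter JSON document
#'
#' Serializes fitted (or constructed) photothermal and drought parameters to
#' a JSON document with explicit `eps_effective` and `eps_scaled` keys and
#' fit provenance (n, SSE, method).
#'
#' @param path output path.
#' @param photothermal a `photothermal_fit` or [photothermal_params()].
#' @param drought a named list of `drought_fit` or [drought_params()]
#'   objects (one per cultivar), or NULL.
#' @export
write_params_json <- function(path, photothermal = NULL, drought = NULL) {
  doc <- .params_doc(photothermal, drought)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a model-parameter JSON document
#'
#' Reconstructs [photothermal_params()] (and, when present,
#' [drought_params()] per cultivar) from a document written by
#' [write_params_json()].
#'
#' @param path JSON file path.
#' @return list with `photothermal` and (possibly empty) `drought` entries.
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  pt <- NULL
  if (!is.null(doc$photothermal)) {
    q <- doc$photothermal
    pt <- photothermal_params(q$a_l, q$b_l, q$a_h, q$b_h, q$fvfm, q$eps,
                              q$t_min, q$t_o, q$t_max)
  }
  dr <- list()
  if (!is.null(doc$drought)) {
    dr <- lapply(doc$drought, function(q) {
      drought_params(q$c, q$d, q$rswc_c, base = pt)
    })
  }
  list(photothermal = pt, drought = dr)
}
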