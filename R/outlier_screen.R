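#' Tukey fences for one subject's monthly log HF values
#'
#' Computes quartiles Q1 and Q3 of the supplied values, the fences
#' \eqn{Q1 - k \cdot IQR} and \eqn{Q3 + k \cdot IQR} with \eqn{k = 1.5}, and
#' flags each value strictly outside the fences. Quartiles use linear
#' interpolation of order statistics (R's type 7) by default; the convention
#' is configurable since Tukey's original hinges differ slightly.
#'
#' @param values Numeric vector (a subject's monthly log HF estimates;
#'   baseline never enters). Missing values are ignored for the quartiles
#'   and never flagged.
#' @param k Fence multiplier; default 1.5.
#' @param type Quantile type passed to [stats::quantile()]; default 7.
#' @return List of class \code{fence_result}: \code{q1}, \code{q3},
#'   \code{iqr}, \code{lower}, \code{upper}, \code{flags} (logical, same
#'   length as \code{values}), \code{screened} (FALSE when fewer than 4
#'   non-missing values were available, in which case nothing is flagged).
#' @export
tukey_fences <- function(values, k = 1.5, type = 7) {
  values <- as.numeric(values)
  ok <- !is.na(values)
  if (sum(ok) < 4L) {
    warning("fewer than 4 non-missing values: outlier screening skipped")
    return(structure(list(q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          flags = rep(FALSE, length(values)),
                          screened = FALSE),
                     class = "fence_result"))
  }
  q <- unname(stats::quantile(values[ok], c(0.25, 0.75), type = type))
  iqr <- q[2L] - q[1L]
  lower <- q[1L] - k * iqr
  upper <- q[2L] + k * iqr
  flags <- rep(FALSE, length(values))
  flags[ok] <- values[ok] < lower | values[ok] > upper
  structure(list(q1 = q[1L], q3 = q[2L], iqr = iqr, lower = lower,
                 upper = upper, flags = flags, screened = TRUE),
            class = "fence_result")
}

#' @export
print.fence_result <- function(x, ...) {
  cat(sprintf("Tukey fences: Q1 %.3f, Q3 %.3f, [%.3f, %.3f], %d flagged\n",
              x$q1, x$q3, x$lower, x$upper, sum(x$flags)))
  invisible(x)
}

#' Screen a cohort's expedition sessions for outliers
#'
#' Per subject, Tukey fences are computed on the monthly (expedition, never
#' baseline) values of \code{value_col} — by default log HF, the index of
#' vagal modulation most sensitive to breathing irregularities or lack of a
#' steady state. Every flagged session is removed as a whole: the recording
#' is considered unreliable, so all its indices leave the analysis set.
#' Screening is single-pass: fences are computed once on each subject's
#' surviving monthly values and not recomputed after removal.
#'
#' @param cohort A data.frame of per-session indices with at least
#'   \code{subject_id}, \code{month} and \code{value_col} columns.
#' @param value_col Column screened; default \code{"log_hf"}.
#' @param k,type Fence parameters, see [tukey_fences()].
#' @return List with \code{data} (the filtered cohort, baseline rows always
#'   retained) and \code{exclusions}: a data.frame with columns
#'   \code{subject_id, month, value, q1, q3, lower, upper}.
#' @export
screen_outliers <- function(cohort, value_col = "log_hf", k = 1.5, type = 7) {
  stopifnot(is.data.frame(cohort),
            all(c("subject_id", "month", value_col) %in% names(cohort)))
  is_exp <- cohort$month %in% .MONTHS
  drop <- rep(FALSE, nrow(cohort))
  excl <- list()
  for (sid in unique(cohort$subject_id[is_exp])) {
    rows <- which(is_exp & cohort$subject_id == sid)
    vals <- cohort[[value_col]][rows]
    fr <- withCallingHandlers(
      tukey_fences(vals, k = k, type = type),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!fr$screened || !any(fr$flags)) next
    hit <- rows[fr$flags]
    drop[hit] <- TRUE
    excl[[length(excl) + 1L]] <- data.frame(
      subject_id = sid, month = as.character(cohort$month[hit]),
      value = cohort[[value_col]][hit],
      q1 = fr$q1, q3 = fr$q3, lower = fr$lower, upper = fr$upper,
      stringsAsFactors = FALSE)
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(), month = character(),
               value = numeric(), q1 = numeric(), q3 = numeric(),
               lower = numeric(), upper = numeric())
  filtered <- if (any(drop)) cohort[!drop, , drop = FALSE] else cohort
  list(data = filtered, exclusions = exclusions)
}
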