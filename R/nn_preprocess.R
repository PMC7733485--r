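#' Detect abnormal beats in an RR series
#'
#' Reproducible stand-in for manual beat editing: beat \eqn{i} is flagged
#' when its relative deviation from the local median exceeds
#' \code{rel_threshold}, i.e. \eqn{|RR_i - m_i| / m_i >} threshold, where
#' \eqn{m_i} is the median of the window of \code{window} beats centred on
#' \eqn{i} (shrunk near the edges). Premature beats (short intervals) and
#' missed-beat artifacts (long intervals) both deviate strongly from the
#' local median and are caught by the same rule.
#'
#' @param x An [rr_series] or numeric vector of intervals (ms).
#' @param rel_threshold Relative deviation threshold in (0, 1); default 0.20.
#' @param window Window width in beats (odd); default 11.
#' @return Logical vector, one flag per beat.
#' @export
detect_abnormal_beats <- function(x, rel_threshold = 0.20, window = 11L) {
  iv <- if (inherits(x, "rr_series")) x$intervals else as.numeric(x)
  n <- length(iv)
  if (n < 2L) .stop2("series shorter than 2 beats", "icehrv_short_series")
  stopifnot(rel_threshold > 0, rel_threshold < 1,
            window >= 3, window %% 2 == 1)
  h <- (as.integer(window) - 1L) %/% 2L
  med <- vapply(seq_len(n), function(i) {
    stats::median(iv[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
  abs(iv - med) / med > rel_threshold
}

#' Edit flagged beats to obtain an NN series
#'
#' Flagged beats are replaced by cubic interpolation over beat index through
#' the unflagged neighbours (natural spline, linear extrapolation at the
#' edges); replacement rather than deletion keeps the beat count, and hence
#' the tachogram time base, continuous for spectral resampling. The fraction
#' of edited beats is recorded for the series-level discard rule.
#'
#' @param x An [rr_series].
#' @param mask Logical vector, one entry per beat (e.g. from
#'   [detect_abnormal_beats()]).
#' @return An object of class \code{nn_series}: list with
#'   \code{nn_intervals}, \code{edited_mask}, \code{edited_fraction},
#'   \code{discarded} (NA until [apply_discard_rule()]), and the parent
#'   metadata (\code{subject_id}, \code{sex}, \code{mission}, \code{month},
#'   \code{source}).
#' @export
edit_to_nn <- function(x, mask) {
  stopifnot(inherits(x, "rr_series"))
  iv <- x$intervals
  mask <- as.logical(mask)
  if (length(mask) != length(iv))
    stop("mask length must equal series length", call. = FALSE)
  if (all(mask)) .stop2("uneditable series: all beats flagged",
                        "icehrv_uneditable")
  nn <- iv
  if (any(mask)) {
    idx <- seq_along(iv)
    keep <- which(!mask)
    if (length(keep) >= 4L) {
      f <- stats::splinefun(idx[keep], iv[keep], method = "natural")
      nn[mask] <- f(idx[mask])
    } else {
      nn[mask] <- stats::approx(idx[keep], iv[keep], xout = idx[mask],
                                rule = 2)$y
    }
    if (any(nn <= 0))
      .stop2("interpolated NN interval non-positive", "icehrv_invalid_interval")
  }
  structure(list(nn_intervals = nn,
                 edited_mask = mask,
                 edited_fraction = mean(mask),
                 discarded = NA,
                 subject_id = x$subject_id, sex = x$sex,
                 mission = x$mission, month = x$month, source = x$source),
            class = "nn_series")
}

#' Apply the series-level discard rule
#'
#' A series is discarded when the fraction of edited (abnormal) beats
#' strictly exceeds the threshold; a fraction of exactly 5\% is retained.
#'
#' @param nn An \code{nn_series}.
#' @param threshold Fraction threshold; default 0.05.
#' @return The \code{nn_series} with \code{discarded} set.
#' @export
apply_discard_rule <- function(nn, threshold = 0.05) {
  stopifnot(inherits(nn, "nn_series"), .is_prob(threshold))
  nn$discarded <- nn$edited_fraction > threshold
  nn
}

#' Preprocess one RR series to an NN series
#'
#' Convenience wrapper: [detect_abnormal_beats()], [edit_to_nn()],
#' [apply_discard_rule()].
#'
#' @param x An [rr_series].
#' @param rel_threshold,window Detection parameters.
#' @param discard_threshold Discard-rule threshold.
#' @return An \code{nn_series} with the \code{discarded} flag set.
#' @export
preprocess_rr <- function(x, rel_threshold = 0.20, window = 11L,
                          discard_threshold = 0.05) {
  mask <- detect_abnormal_beats(x, rel_threshold, window)
  apply_discard_rule(edit_to_nn(x, mask), discard_threshold)
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf(
    "NN series: %s [%s]  %d beats, %d edited (%.2f%%), discarded: %s\n",
    x$subject_id, x$month %||% NA, length(x$nn_intervals),
    sum(x$edited_mask), 100 * x$edited_fraction, x$discarded))
  invisible(x)
}

#' @export
length.nn_series <- function(x) length(x$nn_intervals)
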