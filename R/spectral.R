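#' Resample an NN tachogram onto a uniform grid
#'
#' NN intervals are an unevenly sampled series: the value NN_k (ms) is
#' attached to the cumulative beat time t_k (s). For Fourier analysis the
#' tachogram is cubic-spline interpolated and sampled on a uniform grid of
#' spacing 1/fs between the first and last beat. No mean removal is done
#' here; detrending belongs to the Welch step.
#'
#' @param nn An \code{nn_series} (not discarded) or numeric vector of NN
#'   intervals (ms).
#' @param fs Resampling rate in Hz; default 4 (the common convention for
#'   short-term HRV, comfortably above twice the 0.4 Hz band edge).
#' @return A list of class \code{tachogram}: \code{t} (s), \code{y} (ms),
#'   \code{fs}.
#' @export
resample_tachogram <- function(nn, fs = 4) {
  iv <- if (inherits(nn, "nn_series")) nn$nn_intervals else as.numeric(nn)
  if (inherits(nn, "nn_series") && isTRUE(nn$discarded))
    stop("refusing to resample a discarded series", call. = FALSE)
  if (length(iv) < 4L)
    .stop2("need at least 4 beats to resample", "icehrv_short_series")
  stopifnot(fs > 0)
  tk <- (cumsum(iv) - iv) / 1000  # interval attached to its onset beat
  grid <- seq(tk[1L], tk[length(tk)], by = 1 / fs)
  f <- stats::splinefun(tk, iv, method = "fmm")
  structure(list(t = grid, y = f(grid), fs = fs), class = "tachogram")
}

.window_fun <- function(name, n) {
  switch(name,
         hann = 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)),
         hamming = 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1)),
         rectangular = rep(1, n),
         stop("unknown window: ", name, call. = FALSE))
}

.detrend <- function(x, mode) {
  n <- length(x)
  switch(mode,
         none = x,
         constant = x - mean(x),
         linear = {
           t0 <- seq_len(n) - (n + 1) / 2
           x - mean(x) - t0 * sum(t0 * x) / sum(t0^2)
         },
         stop("unknown detrend mode: ", mode, call. = FALSE))
}

#' Welch power spectral density of a tachogram
#'
#' Averaged modified periodogram over overlapping windowed segments.
#' One-sided density in ms^2/Hz, normalized so that the rectangle-rule
#' integral of the PSD over [0, Nyquist] equals the mean (over segments) of
#' the windowed, detrended segment power — the Parseval convention under
#' which band powers are in ms^2.
#'
#' @param x A \code{tachogram} from [resample_tachogram()], or a numeric
#'   signal (then \code{fs} is required).
#' @param fs Sampling rate in Hz (taken from the tachogram if given).
#' @param segment_s Segment length in seconds; default 150 (frequency
#'   resolution fs/N ~ 0.0067 Hz, enough to separate the 0.04 Hz band edge).
#' @param overlap Overlap fraction between segments; default 0.5.
#' @param window Taper name: \code{"hann"} (default), \code{"hamming"},
#'   \code{"rectangular"}.
#' @param detrend Per-segment detrending: \code{"linear"} (default),
#'   \code{"constant"}, \code{"none"}.
#' @return Object of class \code{spectral_estimate}: \code{freq} (Hz, 0 to
#'   Nyquist), \code{psd} (ms^2/Hz), \code{params}, \code{n_segments},
#'   \code{segment_power} (mean windowed segment variance, the Parseval
#'   reference).
#' @export
welch_psd <- function(x, fs = NULL, segment_s = 150, overlap = 0.5,
                      window = "hann", detrend = "linear") {
  if (inherits(x, "tachogram")) { fs <- x$fs; sig <- x$y } else sig <- as.numeric(x)
  if (is.null(fs)) stop("fs is required for a plain numeric signal", call. = FALSE)
  stopifnot(overlap >= 0, overlap < 1, segment_s > 0)
  nper <- round(segment_s * fs)
  n <- length(sig)
  if (n < nper)
    .stop2(sprintf("signal (%d samples) shorter than one segment (%d)", n, nper),
           "icehrv_short_signal")
  step <- max(1L, floor(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- .window_fun(window, nper)
  wnorm <- sum(w^2)
  nfreq <- nper %/% 2L + 1L
  acc <- numeric(nfreq)
  segpow <- 0
  for (s in starts) {
    seg <- .detrend(sig[s:(s + nper - 1L)], detrend) * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    p <- (Mod(X)^2) / (fs * wnorm)
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
    if (nper %% 2L == 1L) p[nfreq] <- 2 * p[nfreq]
    acc <- acc + p
    segpow <- segpow + sum(seg^2) / wnorm
  }
  structure(list(freq = seq(0, length.out = nfreq, by = fs / nper),
                 psd = acc / length(starts),
                 params = list(fs = fs, segment_s = segment_s,
                               overlap = overlap, window = window,
                               detrend = detrend),
                 n_segments = length(starts),
                 segment_power = segpow / length(starts)),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf(
    "Welch PSD: %d bins to %.3f Hz (df %.4f Hz), %d segment(s) of %g s, %s window\n",
    length(x$freq), max(x$freq), x$freq[2L], x$n_segments,
    x$params$segment_s, x$params$window))
  invisible(x)
}

#' Band power from a spectral estimate
#'
#' Integrates the piecewise-linear (trapezoidal) PSD over \code{[lo, hi]},
#' interpolating the PSD at band edges that fall between grid points, so
#' that adjacent bands tile the axis without double counting.
#'
#' @param spec A \code{spectral_estimate}.
#' @param lo,hi Band edges in Hz, \code{0 <= lo < hi <= Nyquist}.
#' @return Power in ms^2.
#' @export
band_power <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "spectral_estimate"))
  nyq <- max(spec$freq)
  if (!(lo >= 0 && hi > lo)) stop("need 0 <= lo < hi", call. = FALSE)
  hi <- min(hi, nyq)
  if (lo >= nyq) return(0)
  f <- spec$freq; p <- spec$psd
  inside <- f > lo & f < hi
  fv <- c(lo, f[inside], hi)
  pv <- c(stats::approx(f, p, xout = lo)$y, p[inside],
          stats::approx(f, p, xout = hi)$y)
  sum(diff(fv) * (pv[-length(pv)] + pv[-1L]) / 2)
}

.DEFAULT_BANDS <- list(vlf = c(0, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.40))

#' Frequency-domain HRV indices for one NN series
#'
#' Computes mean heart rate, Welch band powers in the very-low (0–0.04 Hz),
#' low (0.04–0.15 Hz) and high (0.15–0.40 Hz) frequency bands plus total
#' power over the analysed range 0–0.40 Hz (the band-limited convention, so
#' that the normalized units sum to 100 exactly by construction),
#' normalized units \eqn{LF_{nu} = LF/(total - VLF) \times 100} and
#' \eqn{HF_{nu} = HF/(total - VLF) \times 100}, the LF/HF ratio, base-10
#' logarithms of LF, HF and LF/HF, and the frequency of the highest spectral
#' peak within the HF band (an indirect index of respiratory frequency).
#'
#' @param nn An \code{nn_series} (retained) or numeric NN vector (ms).
#' @param fs Resampling rate (Hz), default 4.
#' @param segment_s,overlap,window,detrend Welch parameters, see
#'   [welch_psd()].
#' @param bands Named list of band edges; default VLF/LF/HF as above.
#' @return A one-row data.frame of class \code{hrv_indices} with columns
#'   \code{hr_bpm, vlf, lf, hf, total_power, lf_nu, hf_nu, lf_hf, log_lf,
#'   log_hf, log_lf_hf, hf_peak_hz}, plus any metadata carried by \code{nn}.
#' @export
compute_indices <- function(nn, fs = 4, segment_s = 150, overlap = 0.5,
                            window = "hann", detrend = "linear",
                            bands = .DEFAULT_BANDS) {
  iv <- if (inherits(nn, "nn_series")) nn$nn_intervals else as.numeric(nn)
  if (inherits(nn, "nn_series") && isTRUE(nn$discarded))
    stop("refusing to compute indices for a discarded series", call. = FALSE)
  hr <- 60000 / mean(iv)
  tach <- resample_tachogram(iv, fs = fs)
  spec <- welch_psd(tach, segment_s = segment_s, overlap = overlap,
                    window = window, detrend = detrend)
  vlf <- band_power(spec, bands$vlf[1], bands$vlf[2])
  lf <- band_power(spec, bands$lf[1], bands$lf[2])
  hf <- band_power(spec, bands$hf[1], bands$hf[2])
  total <- vlf + lf + hf
  if (lf <= 0 || hf <= 0 || (total - vlf) <= 0)
    .stop2("degenerate spectrum: zero LF or HF power, log indices undefined",
           "icehrv_degenerate_spectrum")
  hfsel <- spec$freq >= bands$hf[1] & spec$freq <= bands$hf[2]
  hf_peak <- spec$freq[hfsel][which.max(spec$psd[hfsel])]
  out <- data.frame(hr_bpm = hr, vlf = vlf, lf = lf, hf = hf,
                    total_power = total,
                    lf_nu = lf / (total - vlf) * 100,
                    hf_nu = hf / (total - vlf) * 100,
                    lf_hf = lf / hf,
                    log_lf = log10(lf), log_hf = log10(hf),
                    log_lf_hf = log10(lf / hf),
                    hf_peak_hz = hf_peak)
  if (inherits(nn, "nn_series"))
    out <- cbind(data.frame(subject_id = nn$subject_id, sex = nn$sex,
                            mission = nn$mission, month = nn$month,
                            stringsAsFactors = FALSE), out)
  class(out) <- c("hrv_indices", "data.frame")
  out
}

#' HRV indices for a whole cohort of NN series
#'
#' Applies [compute_indices()] to each retained series; discarded series and
#' series with a degenerate spectrum are reported, not silently dropped.
#'
#' @param nn_list List of \code{nn_series}.
#' @param ... Passed to [compute_indices()].
#' @return A data.frame of indices (one row per analysable session) with
#'   attributes \code{discarded} and \code{degenerate}: data.frames listing
#'   the skipped sessions.
#' @export
cohort_indices <- function(nn_list, ...) {
  rows <- list(); disc <- list(); degen <- list()
  for (nn in nn_list) {
    meta <- data.frame(subject_id = nn$subject_id, sex = nn$sex,
                       mission = nn$mission, month = nn$month,
                       edited_fraction = nn$edited_fraction,
                       stringsAsFactors = FALSE)
    if (isTRUE(nn$discarded)) { disc[[length(disc) + 1L]] <- meta; next }
    res <- tryCatch(compute_indices(nn, ...),
                    icehrv_degenerate_spectrum = function(e) NULL)
    if (is.null(res)) degen[[length(degen) + 1L]] <- meta
    else rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = 16)),
                    c("subject_id", "sex", "mission", "month", "hr_bpm",
                      "vlf", "lf", "hf", "total_power", "lf_nu", "hf_nu",
                      "lf_hf", "log_lf", "log_hf", "log_lf_hf", "hf_peak_hz"))
  class(out) <- "data.frame"
  rownames(out) <- NULL
  attr(out, "discarded") <- if (length(disc)) do.call(rbind, disc) else NULL
  attr(out, "degenerate") <- if (length(degen)) do.call(rbind, degen) else NULL
  out
}
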