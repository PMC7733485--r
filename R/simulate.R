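#' Specification of a synthetic tachogram
#'
#' Describes a modulated NN-interval process: a mean heart period with one
#' sinusoidal modulation in the LF band (vasomotor/baroreflex surrogate) and
#' one in the HF band (respiratory sinus arrhythmia surrogate) plus white
#' beat-to-beat noise. A sinusoidal modulation of amplitude A contributes an
#' expected band power of A^2/2 ms^2, which is the ground truth used by the
#' spectral tests.
#'
#' @param mean_nn Mean NN interval in ms (> 0).
#' @param lf_amp,hf_amp Modulation amplitudes in ms (>= 0).
#' @param lf_freq LF modulation frequency in Hz, in [0.04, 0.15).
#' @param hf_freq HF modulation frequency in Hz, in [0.15, 0.40).
#' @param noise_sd White noise SD in ms (>= 0).
#' @param duration Recording duration in seconds; default 600 (10 min
#'   supine recordings).
#' @return List of class \code{tachogram_spec}.
#' @export
tachogram_spec <- function(mean_nn = 1000, lf_amp = 20, hf_amp = 30,
                           lf_freq = 0.1, hf_freq = 0.25, noise_sd = 0,
                           duration = 600) {
  stopifnot(mean_nn > 0, lf_amp >= 0, hf_amp >= 0, noise_sd >= 0,
            duration > 0,
            lf_freq >= 0.04, lf_freq < 0.15,
            hf_freq >= 0.15, hf_freq < 0.40)
  structure(list(mean_nn = mean_nn, lf_amp = lf_amp, hf_amp = hf_amp,
                 lf_freq = lf_freq, hf_freq = hf_freq, noise_sd = noise_sd,
                 duration = duration),
            class = "tachogram_spec")
}

#' Generate a synthetic RR series from a tachogram spec
#'
#' Beat times are generated iteratively, \eqn{t_{k+1} = t_k + NN(t_k)/1000},
#' with \eqn{NN(t) = \bar{NN} + A_{LF}\sin(2\pi f_{LF} t) +
#' A_{HF}\sin(2\pi f_{HF} t) + \epsilon}, \eqn{\epsilon \sim N(0,
#' noise\_sd^2)}; the recorded intervals are the successive NN values in ms.
#' This is a deliberately simple modulated-interval process, not a full
#' integral-pulse-frequency-modulation model: adequate for band-power
#' ground truth.
#'
#' @param spec A [tachogram_spec()].
#' @param seed Optional integer; when given the series is reproducible and
#'   the caller's RNG stream is left untouched.
#' @param subject_id,sex,mission,month Metadata for the resulting series.
#' @return An [rr_series] with \code{source = "synthetic"}.
#' @export
generate_rr_series <- function(spec, seed = NULL, subject_id = "synthetic",
                               sex = NA_character_, mission = NA,
                               month = NA_character_) {
  stopifnot(inherits(spec, "tachogram_spec"))
  .with_seed(seed, {
    n_max <- ceiling(1000 * spec$duration / spec$mean_nn * 2) + 16L
    nn <- numeric(n_max)
    t <- 0; k <- 0L
    while (t < spec$duration) {
      val <- spec$mean_nn +
        spec$lf_amp * sin(2 * pi * spec$lf_freq * t) +
        spec$hf_amp * sin(2 * pi * spec$hf_freq * t) +
        (if (spec$noise_sd > 0) stats::rnorm(1, 0, spec$noise_sd) else 0)
      # val <= 0 is outright non-physiologic; k > n_max catches interval
      # collapse (NN(t) -> 0+ makes beat times converge without crossing 0)
      if (val <= 0 || k >= n_max)
        .stop2("spec produces non-physiologic intervals",
               "icehrv_nonphysiologic")
      k <- k + 1L
      nn[k] <- val
      t <- t + val / 1000
    }
    rr_series(nn[seq_len(k)], subject_id = subject_id, sex = sex,
              mission = mission, month = month, source = "synthetic")
  })
}

#' Inject beat artifacts into an RR series
#'
#' Randomly chosen beats are halved (premature-beat surrogate) or doubled
#' (missed-beat surrogate) with equal probability. The affected positions
#' are recorded as ground truth in the \code{artifact_idx} attribute.
#'
#' @param x An [rr_series].
#' @param rate Per-beat artifact probability in [0, 1].
#' @param seed Optional integer for reproducibility.
#' @param n Optional exact number of artifacts (overrides binomial draws;
#'   positions still random).
#' @return The modified [rr_series] with attribute \code{artifact_idx}.
#' @export
inject_artifacts <- function(x, rate = 0, seed = NULL, n = NULL) {
  stopifnot(inherits(x, "rr_series"), .is_prob(rate) || !is.null(n))
  .with_seed(seed, {
    nb <- length(x$intervals)
    idx <- if (!is.null(n)) sample.int(nb, n)
    else which(stats::runif(nb) < rate)
    if (length(idx)) {
      fac <- sample(c(0.5, 2), length(idx), replace = TRUE)
      x$intervals[idx] <- x$intervals[idx] * fac
    }
    attr(x, "artifact_idx") <- sort(idx)
    x
  })
}

#' Specification of a synthetic longitudinal cohort
#'
#' Encodes the study conditions emulated by [generate_cohort()]: 25 subjects
#' (15 men, 10 women) measured at one pre-expedition baseline and 9 monthly
#' expedition sessions, with per-sex intercepts, per-sex month trends,
#' subject random intercepts, residual noise, occasional outlier sessions
#' (a negative shift of log HF, emulating recordings taken out of steady
#' state), optional per-beat artifacts (signal mode), and optional missing
#' sessions.
#'
#' Trends are parameterized per response and sex as coefficients on the
#' orthonormal polynomial contrasts over the 9 months, so an injected
#' coefficient equals the expected estimate of the corresponding
#' pre-planned contrast. The month profile is anchored at the first
#' expedition month (February sits at the sex intercept, as a cohort
#' starting near its baseline does); the anchor is a per-sex constant and
#' leaves every polynomial contrast estimate unchanged. Defaults: log HF declines linearly in both sexes
#' (coefficient -0.775, i.e. -0.10 per month step); log LF/HF rises
#' linearly (+0.19) and has a cubic component (-0.18) in women only; heart
#' rate is flat. Intercepts follow the baseline sex means; intercept SD 0.3
#' and residual SD 0.2 are typical of log-power indices at this scale.
#'
#' @param n_men,n_women Subjects per sex (defaults 15 and 10).
#' @param intercept_sd Between-subject (random intercept) SD; default 0.3.
#' @param residual_sd Within-subject residual SD; default 0.2.
#' @param effects Named list per response: each a list with \code{intercept
#'   = c(F=, M=)} and optional \code{linear}, \code{quadratic},
#'   \code{cubic} (each \code{c(F=, M=)}) orthonormal-contrast
#'   coefficients. See defaults in the function body.
#' @param outlier_rate Per-session probability of an outlier session;
#'   default 0.03.
#' @param outlier_shift Added to log HF of outlier sessions; default -1.5.
#' @param artifact_rate Per-beat artifact probability in signal mode;
#'   default 0.
#' @param missing_rate Per-session probability of a missing expedition
#'   session; default 0.
#' @param hr_sd_scale Multiplier applied to intercept/residual SDs for the
#'   heart-rate response (bpm scale); default 25.
#' @param baseline_from_intercept When TRUE (default), the baseline session
#'   shares the subject's random intercept, as a repeated measurement of
#'   the same physiology would; conditioning on such a baseline shrinks the
#'   conditional between-subject variance. Set FALSE to draw baselines
#'   independently of the subject effects, so that the fitted conditional
#'   model coincides with the generating model (used for
#'   variance-component recovery experiments).
#' @param noise_sd Beat-to-beat white noise (ms) in signal mode; default 3.
#' @param duration Recording length (s) in signal mode; default 600.
#' @return List of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_men = 15, n_women = 10,
                        intercept_sd = 0.3, residual_sd = 0.2,
                        effects = NULL,
                        outlier_rate = 0.03, outlier_shift = -1.5,
                        artifact_rate = 0, missing_rate = 0,
                        hr_sd_scale = 25, noise_sd = 3, duration = 600,
                        baseline_from_intercept = TRUE) {
  stopifnot(.is_count(n_men), .is_count(n_women), n_men + n_women >= 4,
            intercept_sd >= 0, residual_sd >= 0,
            .is_prob(outlier_rate), .is_prob(artifact_rate),
            .is_prob(missing_rate))
  if (is.null(effects)) effects <- list(
    log_hf = list(intercept = c(F = 2.824, M = 2.534),
                  linear = c(F = -0.775, M = -0.775)),
    log_lf_hf = list(intercept = c(F = 0.004, M = 0.334),
                     linear = c(F = 0.19, M = 0),
                     cubic = c(F = -0.18, M = 0)),
    hr_bpm = list(intercept = c(F = 70.3, M = 64.2)))
  for (ef in effects) {
    stopifnot(is.list(ef), all(c("F", "M") %in% names(ef$intercept)))
    for (tr in intersect(names(ef), c("linear", "quadratic", "cubic")))
      stopifnot(all(c("F", "M") %in% names(ef[[tr]])))
  }
  structure(list(n_men = n_men, n_women = n_women, months = .MONTHS,
                 intercept_sd = intercept_sd, residual_sd = residual_sd,
                 effects = effects, outlier_rate = outlier_rate,
                 outlier_shift = outlier_shift,
                 artifact_rate = artifact_rate, missing_rate = missing_rate,
                 hr_sd_scale = hr_sd_scale, noise_sd = noise_sd,
                 duration = duration,
                 baseline_from_intercept = isTRUE(baseline_from_intercept)),
            class = "cohort_spec")
}

# per-sex month profile (length 9) from orthonormal polynomial coefficients,
# anchored so the first expedition month sits at the sex intercept (the
# anchor is a constant per sex, so orthonormal contrast estimates are
# unaffected; it keeps early-mission index targets physiologic)
.trend_profile <- function(ef, sex, k = 9L) {
  pol <- stats::contr.poly(k)
  prof <- rep(0, k)
  for (j in 1:3) {
    nm <- c("linear", "quadratic", "cubic")[j]
    if (!is.null(ef[[nm]])) prof <- prof + ef[[nm]][[sex]] * pol[, j]
  }
  prof - prof[1L]
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' In \code{"indices"} mode, per-session HRV index values are drawn directly
#' from the linear mixed model stated in [cohort_spec()] (fixed sex
#' intercepts and month trends + subject random intercept + residual); this
#' is the fast route for testing the screening and modelling stages. In
#' \code{"signal"} mode, each session's target log HF and log LF/HF are
#' mapped to sinusoid amplitudes (\code{hf_amp = sqrt(2 * 10^log_hf)},
#' likewise for LF via \code{log_lf = log_lf_hf + log_hf}) and a full RR
#' series is generated with [generate_rr_series()], closing the loop
#' through preprocessing and the spectral module.
#'
#' @param spec A [cohort_spec()].
#' @param mode \code{"indices"} (default) or \code{"signal"}.
#' @param seed Optional integer seed (recommended).
#' @param dir In signal mode, an optional directory: RR files (plain
#'   dialect), a \code{manifest.csv} readable by [load_cohort()], and a
#'   \code{ground_truth.json} sidecar are written there.
#' @return In indices mode: a data.frame cohort (columns
#'   \code{subject_id, sex, mission, month} + one per response) with
#'   attribute \code{truth} (subject effects, outlier sessions, spec). In
#'   signal mode: a list with \code{series} (list of [rr_series]),
#'   \code{manifest}, \code{targets} (per-session index targets) and
#'   \code{truth}.
#' @export
generate_cohort <- function(spec, mode = c("indices", "signal"), seed = NULL,
                            dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  .with_seed(seed, {
    n <- spec$n_men + spec$n_women
    subjects <- sprintf("S%02d", seq_len(n))
    sexes <- c(rep("M", spec$n_men), rep("F", spec$n_women))
    missions <- rep_len(rep(1:3, times = c(9, 7, 9))[seq_len(min(n, 25))], n)
    responses <- names(spec$effects)
    k <- length(spec$months)

    b <- matrix(stats::rnorm(n * length(responses), 0, spec$intercept_sd),
                n, length(responses), dimnames = list(subjects, responses))
    sd_scale <- ifelse(responses == "hr_bpm", spec$hr_sd_scale, 1)
    b <- sweep(b, 2, sd_scale, "*")

    month_all <- c("BASELINE", spec$months)
    rows <- expand.grid(subject_id = subjects, month = month_all,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows$sex <- sexes[match(rows$subject_id, subjects)]
    rows$mission <- missions[match(rows$subject_id, subjects)]
    is_exp <- rows$month != "BASELINE"
    rows$is_outlier <- is_exp & stats::runif(nrow(rows)) < spec$outlier_rate
    rows$missing <- is_exp & stats::runif(nrow(rows)) < spec$missing_rate

    for (j in seq_along(responses)) {
      rsp <- responses[j]
      ef <- spec$effects[[rsp]]
      mu <- ef$intercept[rows$sex]
      prof <- sapply(c("F", "M"), function(s) .trend_profile(ef, s, k))
      mi <- match(rows$month, spec$months)
      tr <- ifelse(is_exp, prof[cbind(mi, match(rows$sex, c("F", "M")))], 0)
      eps <- stats::rnorm(nrow(rows), 0, spec$residual_sd * sd_scale[j])
      bterm <- b[rows$subject_id, j]
      if (!spec$baseline_from_intercept) bterm[!is_exp] <- 0
      rows[[rsp]] <- mu + tr + bterm + eps
    }
    if ("log_hf" %in% responses)
      rows$log_hf[rows$is_outlier] <- rows$log_hf[rows$is_outlier] +
        spec$outlier_shift

    rows <- rows[order(rows$subject_id, match(rows$month, month_all)), ]
    rownames(rows) <- NULL
    kept <- rows[!rows$missing, setdiff(names(rows), "missing"), drop = FALSE]
    truth <- list(spec = spec, subject_effects = b,
                  outliers = rows[rows$is_outlier & !rows$missing,
                                  c("subject_id", "month")],
                  missing = rows[rows$missing, c("subject_id", "month")])
    cohort <- kept[, setdiff(names(kept), "is_outlier"), drop = FALSE]
    attr(cohort, "truth") <- truth
    if (mode == "indices") return(cohort)

    if (!all(c("log_hf", "log_lf_hf") %in% responses))
      stop("signal mode needs log_hf and log_lf_hf effects", call. = FALSE)
    series <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      hr <- if ("hr_bpm" %in% responses) cohort$hr_bpm[i] else 65
      log_hf <- cohort$log_hf[i]
      log_lf <- cohort$log_lf_hf[i] + log_hf
      ts <- tachogram_spec(mean_nn = 60000 / hr,
                           lf_amp = sqrt(2 * 10^log_lf),
                           hf_amp = sqrt(2 * 10^log_hf),
                           noise_sd = spec$noise_sd,
                           duration = spec$duration)
      s <- generate_rr_series(ts, subject_id = cohort$subject_id[i],
                              sex = cohort$sex[i],
                              mission = cohort$mission[i],
                              month = cohort$month[i])
      if (spec$artifact_rate > 0)
        s <- inject_artifacts(s, spec$artifact_rate)
      series[[i]] <- s
    }
    manifest <- data.frame(subject_id = cohort$subject_id, sex = cohort$sex,
                           mission = cohort$mission, month = cohort$month,
                           rr_file = sprintf("%s_%s.txt", cohort$subject_id,
                                             cohort$month),
                           stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(series))
        writeLines(format(series[[i]]$intervals, trim = TRUE,
                          scientific = FALSE),
                   file.path(dir, manifest$rr_file[i]))
      utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(outliers = truth$outliers, missing = truth$missing,
             subject_effects = as.data.frame(truth$subject_effects)),
        file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    }
    out <- list(series = series, manifest = manifest, targets = cohort,
                truth = truth)
    if (is.null(dir)) out else invisible(out)
  })
}
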