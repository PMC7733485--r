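#' Pipeline configuration
#'
#' Validated bundle of every tunable parameter of the end-to-end analysis.
#' Defaults encode the study conventions: 20\% local-median editing with an
#' 11-beat window and a strict 5\% series discard rule; 4 Hz cubic-spline
#' resampling with 150 s / 50\% overlap Hann Welch segments and linear
#' detrending; VLF 0–0.04, LF 0.04–0.15, HF 0.15–0.40 Hz bands; type 7
#' quartiles for the Tukey screen; Welch-type baseline t tests; two-sided
#' alpha 0.05 with no multiplicity correction.
#'
#' @param manifest Path to the cohort manifest CSV.
#' @param out_dir Output directory for the result tables.
#' @param rel_threshold,window,discard_threshold Preprocessing parameters.
#' @param fs,segment_s,overlap,spectral_window,detrend Spectral parameters.
#' @param quartile_type Tukey-screen quantile type (default 7).
#' @param responses HRV indices modelled, in output order.
#' @param welch_ttest Use Welch baseline t tests (default TRUE).
#' @param alpha Significance level (two-sided); default 0.05.
#' @param dialect RR file dialect.
#' @param seed Integer seed recorded in the run manifest.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(manifest, out_dir,
                            rel_threshold = 0.20, window = 11L,
                            discard_threshold = 0.05,
                            fs = 4, segment_s = 150, overlap = 0.5,
                            spectral_window = "hann", detrend = "linear",
                            quartile_type = 7,
                            responses = c("hr_bpm", "log_hf", "log_lf",
                                          "log_lf_hf", "lf_nu", "hf_nu"),
                            welch_ttest = TRUE, alpha = 0.05,
                            dialect = "plain", seed = 1L) {
  stopifnot(rel_threshold > 0, rel_threshold < 1,
            window >= 3, window %% 2 == 1,
            discard_threshold > 0, discard_threshold < 1,
            fs > 0, segment_s > 0, overlap >= 0, overlap < 1,
            quartile_type %in% 1:9,
            alpha > 0, alpha < 1)
  structure(list(manifest = manifest, out_dir = out_dir,
                 rel_threshold = rel_threshold, window = as.integer(window),
                 discard_threshold = discard_threshold,
                 fs = fs, segment_s = segment_s, overlap = overlap,
                 spectral_window = spectral_window, detrend = detrend,
                 quartile_type = quartile_type, responses = responses,
                 welch_ttest = welch_ttest, alpha = alpha,
                 dialect = dialect, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A validated \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full HRV analysis pipeline
#'
#' Orchestrates, in order: cohort loading, NN preprocessing with the
#' discard rule (QC log), per-session spectral indices, the per-subject
#' Tukey outlier screen on log HF (exclusion log), baseline sex
#' comparisons, and — per response — the mixed-model fixed-effect tests,
#' adjusted means, polynomial trend contrasts and trimester contrasts. All
#' tables are written as CSV under \code{config$out_dir} together with a
#' JSON run manifest (configuration, software versions, session
#' accounting). Outputs are deterministic given identical inputs and
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-loaded list of [rr_series] (bypasses the
#'   manifest on disk).
#' @return Invisibly, a result bundle: \code{qc_log}, \code{indices},
#'   \code{exclusions}, \code{baseline_tests}, \code{model_tests},
#'   \code{adjusted_means}, \code{polynomial_contrasts},
#'   \code{trimester_contrasts}, \code{accounting}, \code{fits}.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  series <- stage("load", cohort %||%
                    load_cohort(config$manifest, dialect = config$dialect))
  n_missing <- if (is.null(attr(series, "missing"))) 0L
               else nrow(attr(series, "missing"))

  nn_list <- stage("preprocess", lapply(series, preprocess_rr,
                                        rel_threshold = config$rel_threshold,
                                        window = config$window,
                                        discard_threshold = config$discard_threshold))
  qc_log <- do.call(rbind, lapply(nn_list, function(nn)
    data.frame(subject_id = nn$subject_id, month = nn$month,
               n_beats = length(nn$nn_intervals),
               n_edited = sum(nn$edited_mask),
               edited_fraction = nn$edited_fraction,
               discarded = nn$discarded, stringsAsFactors = FALSE)))

  indices <- stage("indices", cohort_indices(
    nn_list, fs = config$fs, segment_s = config$segment_s,
    overlap = config$overlap, window = config$spectral_window,
    detrend = config$detrend))
  n_discarded <- sum(qc_log$discarded)
  n_degenerate <- if (is.null(attr(indices, "degenerate"))) 0L
                  else nrow(attr(indices, "degenerate"))

  scr <- stage("screen", screen_outliers(indices, value_col = "log_hf",
                                         type = config$quartile_type))
  analysed <- scr$data
  n_outliers <- nrow(scr$exclusions)

  n_loaded <- length(series) + n_missing
  n_analysed <- nrow(analysed)
  stopifnot(n_loaded == n_analysed + n_discarded + n_degenerate +
              n_outliers + n_missing)

  baseline_tests <- stage("baseline", baseline_ttests(
    analysed, variables = intersect(config$responses, names(analysed)),
    welch = config$welch_ttest))

  fits <- list(); tests <- list(); emms <- list(); polys <- list(); tris <- list()
  for (rsp in config$responses) {
    fit <- stage(paste0("model:", rsp),
                 suppressWarnings(hrv_lmm(rsp, analysed)))
    fits[[rsp]] <- fit
    tests[[rsp]] <- cbind(variable = rsp, fixed_effect_tests(fit))
    emms[[rsp]] <- cbind(variable = rsp, adjusted_means(fit))
    polys[[rsp]] <- cbind(variable = rsp, polynomial_contrasts(fit))
    tris[[rsp]] <- cbind(variable = rsp, trimester_contrasts(fit))
  }
  model_tests <- do.call(rbind, c(tests, list(make.row.names = FALSE)))
  emm_tab <- do.call(rbind, c(emms, list(make.row.names = FALSE)))
  poly_tab <- do.call(rbind, c(polys, list(make.row.names = FALSE)))
  tri_tab <- do.call(rbind, c(tris, list(make.row.names = FALSE)))

  out <- function(x, f) write_hrv_table(x, file.path(config$out_dir, f))
  out(qc_log, "qc_log.csv")
  out(indices, "session_indices.csv")
  out(scr$exclusions, "exclusion_log.csv")
  out(baseline_tests, "baseline_comparison.csv")
  out(model_tests, "fixed_effect_tests.csv")
  out(poly_tab, "polynomial_contrasts.csv")
  out(tri_tab, "trimester_contrasts.csv")
  out(emm_tab, "adjusted_means.csv")

  accounting <- c(n_loaded = n_loaded, n_missing = n_missing,
                  n_discarded = n_discarded, n_degenerate = n_degenerate,
                  n_outliers = n_outliers, n_analysed = n_analysed)
  cfg <- unclass(config)
  jsonlite::write_json(
    list(config = cfg,
         config_hash = sum(utf8ToInt(paste(
           names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                              ""), collapse = ";"))),
         versions = list(icehrv = as.character(utils::packageVersion("icehrv")),
                         R = paste(R.version$major, R.version$minor, sep = "."),
                         lme4 = as.character(utils::packageVersion("lme4"))),
         accounting = as.list(accounting),
         contrast_coefficients = list(
           polynomial = as.data.frame(stats::contr.poly(9)[, 1:3]),
           trimester = list(T1 = .MONTHS[1:3], T2 = .MONTHS[4:6],
                            T3 = .MONTHS[7:9])),
         conventions = list(
           polynomial = "orthonormal over equally spaced months",
           trimester_sign = "earlier minus later",
           difference = "men minus women",
           baseline_covariate = "same index, per subject, mean-centred",
           ttest = if (config$welch_ttest) "Welch" else "pooled")),
    file.path(config$out_dir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA)

  invisible(list(qc_log = qc_log, indices = indices,
                 exclusions = scr$exclusions,
                 baseline_tests = baseline_tests, model_tests = model_tests,
                 adjusted_means = emm_tab, polynomial_contrasts = poly_tab,
                 trimester_contrasts = tri_tab, accounting = accounting,
                 fits = fits))
}
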