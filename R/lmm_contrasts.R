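#' Satterthwaite denominator degrees of freedom for a contrast
#'
#' For a contrast \eqn{c} on the fixed effects, the Satterthwaite df are
#' \deqn{df = 2\,[c'V_\beta c]^2 / \widehat{Var}[c'V_\beta(\hat\theta)c],}
#' where the variance of the variance is obtained by the delta method: the
#' gradient of \eqn{c'V_\beta(\theta)c} in the variance components
#' \eqn{\theta = (\sigma_b^2, \sigma_e^2)} combined with the inverse REML
#' information of \eqn{\hat\theta}. The gradient components are
#' \eqn{u' (\partial V/\partial\theta_k) u} with
#' \eqn{u = V^{-1} X V_\beta c}.
#'
#' @param fit An [hrv_lmm()] fit.
#' @param contrast Numeric contrast vector conformable with
#'   \code{coef(fit)}.
#' @return Degrees of freedom (positive scalar).
#' @export
satterthwaite_df <- function(fit, contrast) {
  stopifnot(inherits(fit, "hrv_lmm"))
  cvec <- as.numeric(contrast)
  if (length(cvec) != length(fit$beta))
    stop("contrast not conformable with fixed effects", call. = FALSE)
  a <- drop(fit$Vbeta %*% cvec)
  varc <- sum(cvec * a)
  u <- drop(fit$VinvX %*% a)
  g <- c(sum(rowsum(u, fit$subj)^2),  # u' ZZ' u
         sum(u^2))                    # u' I u
  if (!all(is.finite(g)))
    stop("non-finite gradient in Satterthwaite computation", call. = FALSE)
  if (fit$singular) {
    # at the boundary the model degenerates to OLS: the intercept-variance
    # direction is inactive and only sigma_e^2 uncertainty remains
    varvar <- g[2L]^2 * 2 * fit$sigma_e2^2 / (fit$n_obs - length(fit$beta))
  } else {
    varvar <- drop(t(g) %*% fit$theta_vcov %*% g)
  }
  if (varvar <= 0) return(fit$n_obs - length(fit$beta))
  max(2 * varc^2 / varvar, 1e-8)
}

.contrast_row <- function(fit, cvec, contrast, group) {
  est <- sum(cvec * fit$beta)
  se <- sqrt(drop(t(cvec) %*% fit$Vbeta %*% cvec))
  df <- satterthwaite_df(fit, cvec)
  t <- est / se
  data.frame(contrast = contrast, group = group, estimate = est, se = se,
             df = df, t = t, p = 2 * stats::pt(-abs(t), df),
             stringsAsFactors = FALSE)
}

#' Test an arbitrary contrast on the fixed effects
#'
#' @param fit An [hrv_lmm()] fit.
#' @param contrast Numeric contrast vector on the fixed-effect coefficients.
#' @param label Row label.
#' @return One-row data.frame with \code{estimate, se, df
#'   (Satterthwaite), t, p} (two-sided).
#' @export
contrast_test <- function(fit, contrast, label = "contrast") {
  .contrast_row(fit, as.numeric(contrast), label, "custom")
}

#' Type III F tests of the fixed effects
#'
#' Marginal F tests for Time (month), Sex, their interaction, and the
#' baseline covariate, with Satterthwaite denominator df. Factors are
#' sum-coded in [hrv_lmm()], so each term's coefficient block gives the
#' marginal (Type III) hypothesis. Multi-df denominator df follow the usual
#' eigendecomposition construction: the covariance of the term's estimates
#' is diagonalized, each 1-df component receives its own Satterthwaite df
#' \eqn{\nu_m}, and \eqn{df_2 = 2E/(E - q)} with
#' \eqn{E = \sum \nu_m/(\nu_m - 2)}.
#'
#' @param fit An [hrv_lmm()] fit.
#' @return Data.frame with columns \code{effect, df1, df2, F, p}.
#' @export
fixed_effect_tests <- function(fit) {
  stopifnot(inherits(fit, "hrv_lmm"))
  labels <- fit$term_labels
  pretty <- c(month = "Time", sex = "Sex", baseline_c = "Baseline",
              `month:sex` = "Time × Sex")
  ord <- c("month", "sex", "month:sex", "baseline_c")
  out <- lapply(ord[ord %in% labels], function(lb) {
    idx <- which(fit$assign == match(lb, labels))
    q <- length(idx)
    Lb <- fit$beta[idx]
    VL <- fit$Vbeta[idx, idx, drop = FALSE]
    qr_ <- qr(VL)
    if (qr_$rank < q)
      stop("rank-deficient design for term '", lb, "' (aliased columns)",
           call. = FALSE)
    Fstat <- drop(t(Lb) %*% solve(VL, Lb)) / q
    eig <- eigen(VL, symmetric = TRUE)
    nus <- vapply(seq_len(q), function(m) {
      cvec <- numeric(length(fit$beta))
      cvec[idx] <- eig$vectors[, m]
      satterthwaite_df(fit, cvec)
    }, numeric(1))
    if (q == 1L) {
      df2 <- nus
    } else {
      E <- sum(ifelse(nus > 2, nus / (nus - 2), 0))
      df2 <- if (E > q) 2 * E / (E - q) else 2 * max(nus)
    }
    data.frame(effect = unname(pretty[lb]), df1 = q, df2 = df2, F = Fstat,
               p = stats::pf(Fstat, q, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# model-matrix rows for the (month, sex) grid at baseline_c = 0,
# using the same factor coding as the fit
.emm_grid <- function(fit) {
  grid <- expand.grid(month = fit$month_levels, sex = fit$sex_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gm <- factor(grid$month, levels = fit$month_levels)
  gs <- factor(grid$sex, levels = fit$sex_levels)
  stats::contrasts(gm) <- fit$month_contrasts
  stats::contrasts(gs) <- fit$sex_contrasts
  R <- stats::model.matrix(~ month * sex + baseline_c,
                           data = data.frame(month = gm, sex = gs,
                                             baseline_c = 0))
  list(grid = grid, R = R)
}

#' Adjusted (estimated marginal) means by month and sex
#'
#' Model predictions for each (month, sex) cell with the baseline covariate
#' fixed at its grand mean; standard errors from the fixed-effect
#' covariance.
#'
#' @param fit An [hrv_lmm()] fit.
#' @return Data.frame with \code{month, sex, emmean, se}.
#' @export
adjusted_means <- function(fit) {
  stopifnot(inherits(fit, "hrv_lmm"))
  g <- .emm_grid(fit)
  emm <- drop(g$R %*% fit$beta)
  se <- sqrt(rowSums((g$R %*% fit$Vbeta) * g$R))
  data.frame(month = g$grid$month, sex = g$grid$sex, emmean = emm, se = se,
             stringsAsFactors = FALSE)
}

.sex_rows <- function(fit, g, sex) {
  which(g$grid$sex == sex)[order(match(g$grid$month[g$grid$sex == sex],
                                       fit$month_levels))]
}

#' Pre-planned polynomial trend contrasts
#'
#' Orthonormal linear, quadratic and cubic contrasts (unit Euclidean norm
#' over equally spaced month levels, via \code{contr.poly}) applied to each
#' sex's month-by-month adjusted means, plus the sex difference of each
#' trend computed as men minus women. Two-sided p values with Satterthwaite
#' df; no multiplicity correction is applied, matching a small pre-planned
#' contrast set at \eqn{\alpha = 0.05}.
#'
#' @param fit An [hrv_lmm()] fit.
#' @return Data.frame with \code{contrast} (Linear/Quadratic/Cubic),
#'   \code{group} (Women/Men/Difference), \code{estimate, se, df, t, p}.
#'   The contrast coefficients and sign conventions are attached as the
#'   \code{"coefficients"} and \code{"conventions"} attributes.
#' @export
polynomial_contrasts <- function(fit) {
  stopifnot(inherits(fit, "hrv_lmm"))
  k <- length(fit$month_levels)
  if (k < length(.MONTHS))
    warning("only ", k, " month levels present; polynomial contrasts ",
            "computed on the available levels")
  if (k < 4L) stop("need at least 4 month levels for cubic trends",
                   call. = FALSE)
  pol <- stats::contr.poly(k)[, 1:3, drop = FALSE]
  g <- .emm_grid(fit)
  rw <- .sex_rows(fit, g, "F"); rm_ <- .sex_rows(fit, g, "M")
  trends <- c("Linear", "Quadratic", "Cubic")
  out <- do.call(rbind, lapply(1:3, function(j) {
    cw <- drop(crossprod(g$R[rw, , drop = FALSE], pol[, j]))
    cm <- drop(crossprod(g$R[rm_, , drop = FALSE], pol[, j]))
    rbind(.contrast_row(fit, cw, trends[j], "Women"),
          .contrast_row(fit, cm, trends[j], "Men"),
          .contrast_row(fit, cm - cw, trends[j], "Difference"))
  }))
  rownames(out) <- NULL
  attr(out, "coefficients") <- pol
  attr(out, "conventions") <- list(
    polynomial = "orthonormal (unit Euclidean norm) over equally spaced months",
    difference = "men minus women")
  out
}

#' Trimester contrasts
#'
#' The expedition months are grouped into trimesters T1 (Feb–Apr), T2
#' (May–Jul), T3 (Aug–Oct); each trimester mean is the unweighted average of
#' its month adjusted means. Contrasts are earlier minus later (T1–T2,
#' T2–T3, T1–T3) per sex, with the sex difference as men minus women.
#'
#' @param fit An [hrv_lmm()] fit.
#' @return Data.frame with \code{contrast, group, estimate, se, df, t, p}
#'   and a \code{"conventions"} attribute.
#' @export
trimester_contrasts <- function(fit) {
  stopifnot(inherits(fit, "hrv_lmm"))
  tri <- list(T1 = .MONTHS[1:3], T2 = .MONTHS[4:6], T3 = .MONTHS[7:9])
  g <- .emm_grid(fit)
  tri_vec <- function(sex, months) {
    have <- intersect(months, fit$month_levels)
    if (length(have) < length(months))
      warning("trimester average over ", length(have), " of ",
              length(months), " months (missing levels)")
    rows <- which(g$grid$sex == sex & g$grid$month %in% have)
    colMeans(g$R[rows, , drop = FALSE])
  }
  pairs <- list(`T1–T2` = c("T1", "T2"), `T2–T3` = c("T2", "T3"),
                `T1–T3` = c("T1", "T3"))
  out <- do.call(rbind, lapply(names(pairs), function(lab) {
    a <- pairs[[lab]][1L]; b <- pairs[[lab]][2L]
    cw <- tri_vec("F", tri[[a]]) - tri_vec("F", tri[[b]])
    cm <- tri_vec("M", tri[[a]]) - tri_vec("M", tri[[b]])
    rbind(.contrast_row(fit, cw, lab, "Women"),
          .contrast_row(fit, cm, lab, "Men"),
          .contrast_row(fit, cm - cw, lab, "Difference"))
  }))
  rownames(out) <- NULL
  attr(out, "conventions") <- list(trimesters = tri,
                                   sign = "earlier minus later",
                                   difference = "men minus women")
  out
}

#' Baseline sex comparisons (unpaired t tests)
#'
#' Two-sided unpaired t tests comparing men and women on the baseline
#' (pre-expedition) sessions, reporting mean (SD) per sex. Welch's
#' unequal-variance form is the default; the pooled-variance form is
#' available via \code{welch = FALSE}.
#'
#' @param data Cohort data.frame containing \code{BASELINE} rows (or any
#'   data.frame of one row per subject with a \code{sex} column).
#' @param variables Character vector of columns to compare.
#' @param welch Use Welch's t test (default TRUE).
#' @return Data.frame with per-sex n/mean/SD, the mean difference (men
#'   minus women), \code{t, df, p}.
#' @export
baseline_ttests <- function(data, variables = c("hr_bpm", "log_lf_hf", "log_hf"),
                            welch = TRUE) {
  stopifnot(is.data.frame(data), "sex" %in% names(data))
  d <- if ("month" %in% names(data))
    data[data$month == "BASELINE", , drop = FALSE] else data
  if (!nrow(d)) stop("no baseline rows", call. = FALSE)
  out <- lapply(variables, function(v) {
    if (!v %in% names(d)) stop("no column '", v, "'", call. = FALSE)
    w <- d[[v]][d$sex == "F"]; m <- d[[v]][d$sex == "M"]
    w <- w[!is.na(w)]; m <- m[!is.na(m)]
    if (length(w) < 2L || length(m) < 2L)
      stop("need at least 2 observations per sex for '", v, "'",
           call. = FALSE)
    tt <- stats::t.test(m, w, var.equal = !welch)
    data.frame(variable = v,
               n_women = length(w), mean_women = mean(w), sd_women = stats::sd(w),
               n_men = length(m), mean_men = mean(m), sd_men = stats::sd(m),
               diff = mean(m) - mean(w),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
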