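#' Fit the longitudinal random-intercept model for one HRV index
#'
#' Fits, by REML, the linear mixed model
#' \deqn{y_{ij} = \mu + time_j + sex_i + (time \times sex)_{ij} +
#'   \beta\, baseline_i + b_i + \varepsilon_{ij}}
#' for one HRV index at a time: expedition month as a 9-level factor,
#' sex, their interaction, the subject's pre-expedition (baseline) value of
#' the same index as a covariate (mean-centred internally), and a random
#' intercept per subject. Months enter as an unordered factor; trend shapes
#' are assessed afterwards through contrasts on the adjusted means
#' ([polynomial_contrasts()], [trimester_contrasts()]), not by a
#' continuous-time fit.
#'
#' The returned object carries, besides the underlying \pkg{lme4} fit, the
#' quantities needed for Satterthwaite inference in the variance-component
#' parameterization: the fixed-effect covariance, the REML information of
#' the variance components, and the projections used by
#' [satterthwaite_df()].
#'
#' @param response Name of the response column, e.g. \code{"log_hf"}.
#' @param data Long-format cohort data.frame with columns
#'   \code{subject_id}, \code{sex} (\code{"M"}/\code{"F"}), \code{month}
#'   (including \code{"BASELINE"} rows supplying the covariate), and the
#'   response.
#' @param baseline_col Optional name of a column already holding the
#'   per-subject baseline covariate; by default the covariate is taken from
#'   the subject's \code{BASELINE} row of \code{response}.
#' @return An object of class \code{hrv_lmm}; see
#'   \code{\link{summary.hrv_lmm}}, [fixed_effect_tests()],
#'   [adjusted_means()], [polynomial_contrasts()], [trimester_contrasts()].
#' @export
hrv_lmm <- function(response, data, baseline_col = NULL) {
  stopifnot(is.character(response), length(response) == 1L,
            is.data.frame(data),
            all(c("subject_id", "sex", "month", response) %in% names(data)))
  d <- data[data$month %in% .MONTHS & !is.na(data[[response]]), , drop = FALSE]
  if (is.null(baseline_col)) {
    base <- data[data$month == "BASELINE" & !is.na(data[[response]]), ]
    if (!nrow(base))
      stop("no BASELINE rows found to supply the covariate", call. = FALSE)
    bl <- stats::setNames(base[[response]], base$subject_id)
    d$.baseline <- unname(bl[as.character(d$subject_id)])
  } else {
    d$.baseline <- d[[baseline_col]]
  }
  n_nobase <- sum(is.na(d$.baseline))
  if (n_nobase) {
    warning(n_nobase, " session(s) dropped: no baseline covariate available")
    d <- d[!is.na(d$.baseline), , drop = FALSE]
  }
  d$month <- droplevels(.month_factor(d$month))
  if (nlevels(d$month) < 2L) stop("need at least 2 months", call. = FALSE)
  d$sex <- factor(as.character(d$sex), levels = c("F", "M"))
  if (any(tapply(d$subject_id, d$sex, function(s) length(unique(s))) < 2L) ||
      anyNA(tapply(d$subject_id, d$sex, length)))
    stop("need at least 2 subjects per sex", call. = FALSE)
  d$subject_id <- factor(as.character(d$subject_id))
  stats::contrasts(d$month) <- stats::contr.sum(nlevels(d$month))
  stats::contrasts(d$sex) <- stats::contr.sum(2)
  baseline_mean <- mean(d$.baseline)
  d$baseline_c <- d$.baseline - baseline_mean
  d$.y <- d[[response]]

  fit <- lme4::lmer(.y ~ month * sex + baseline_c + (1 | subject_id),
                    data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_b2 <- vc$vcov[vc$grp == "subject_id"]
  sigma_e2 <- stats::sigma(fit)^2
  singular <- sigma_b2 < 1e-8 * sigma_e2
  if (singular)
    warning("singular fit: random-intercept variance estimated at zero")

  X <- lme4::getME(fit, "X")
  beta <- lme4::fixef(fit)
  n <- nrow(X)
  subj <- d$subject_id

  # V = sigma_b2 * ZZ' + sigma_e2 * I is block diagonal by subject;
  # invert blockwise: (1/se2) (I - rho/(1 + n_i rho) J_i), rho = sb2/se2
  rho <- sigma_b2 / sigma_e2
  Vinv <- matrix(0, n, n)
  for (lev in levels(subj)) {
    idx <- which(subj == lev)
    ni <- length(idx)
    Vinv[idx, idx] <- (diag(ni) - rho / (1 + ni * rho)) / sigma_e2
  }
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  Vbeta <- solve(XtVinvX)
  P <- Vinv - VinvX %*% tcrossprod(Vbeta, VinvX)
  # REML information in theta = (sigma_b2, sigma_e2):
  # I_kl = tr(P dV_k P dV_l) / 2 with dV_1 = ZZ', dV_2 = I
  PZ <- t(rowsum(t(P), subj))          # n x q, columns ordered by levels(subj)
  M <- rowsum(PZ, subj)                # q x q = Z'PZ
  info <- matrix(c(sum(M^2), sum(PZ^2), sum(PZ^2), sum(P^2)) / 2, 2, 2)
  theta_vcov <- tryCatch(solve(info), error = function(e) {
    s <- svd(info)
    pos <- s$d > max(s$d) * 1e-12
    s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  })

  structure(list(
    lmer = fit, response = response, data = d,
    beta = beta, Vbeta = Vbeta,
    sigma_b2 = sigma_b2, sigma_e2 = sigma_e2, singular = singular,
    theta_vcov = theta_vcov, VinvX = VinvX, subj = subj,
    assign = attr(X, "assign"),
    term_labels = attr(stats::terms(.y ~ month * sex + baseline_c),
                       "term.labels"),
    month_levels = levels(d$month), sex_levels = levels(d$sex),
    month_contrasts = stats::contrasts(d$month),
    sex_contrasts = stats::contrasts(d$sex),
    baseline_mean = baseline_mean,
    n_obs = n, n_subjects = nlevels(subj),
    logLik_REML = as.numeric(stats::logLik(fit))),
    class = "hrv_lmm")
}

#' @export
print.hrv_lmm <- function(x, ...) {
  cat(sprintf("Random-intercept mixed model (REML) for %s\n", x$response))
  cat(sprintf("  %d sessions, %d subjects, %d months\n",
              x$n_obs, x$n_subjects, length(x$month_levels)))
  cat(sprintf("  subject intercept SD %.4f, residual SD %.4f\n",
              sqrt(x$sigma_b2), sqrt(x$sigma_e2)))
  cat("  fixed effects: month * sex + baseline covariate (centred)\n")
  invisible(x)
}

#' @export
coef.hrv_lmm <- function(object, ...) object$beta

#' @export
vcov.hrv_lmm <- function(object, ...) object$Vbeta

#' @export
fitted.hrv_lmm <- function(object, ...) stats::fitted(object$lmer)

#' @export
residuals.hrv_lmm <- function(object, ...) stats::residuals(object$lmer)

#' @export
logLik.hrv_lmm <- function(object, ...) stats::logLik(object$lmer)

#' Variance components of an \code{hrv_lmm} fit
#'
#' @param fit An \code{hrv_lmm}.
#' @return Named vector with \code{sigma_b2} (random-intercept variance)
#'   and \code{sigma_e2} (residual variance).
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "hrv_lmm"))
  c(sigma_b2 = fit$sigma_b2, sigma_e2 = fit$sigma_e2)
}

#' @export
summary.hrv_lmm <- function(object, ...) {
  structure(list(fit = object, tests = fixed_effect_tests(object)),
            class = "summary.hrv_lmm")
}

#' @export
print.summary.hrv_lmm <- function(x, ...) {
  print(x$fit)
  cat("\nType III fixed-effect tests (Satterthwaite denominator df):\n")
  print(format(x$tests, digits = 4), row.names = FALSE)
  invisible(x)
}
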