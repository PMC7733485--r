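# shared fixtures, built in code at test time

# flat cohort spec (no trends, equal sex intercepts) for null simulations
null_spec <- function(...) {
  cohort_spec(effects = list(log_hf = list(intercept = c(F = 2.7, M = 2.7))),
              outlier_rate = 0, ...)
}

# independent brute-force Tukey fences: manual type-7 interpolation,
# no call to stats::quantile
brute_fences <- function(v, k = 1.5) {
  v <- v[!is.na(v)]
  s <- sort(v)
  n <- length(s)
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  q1 <- q7(0.25); q3 <- q7(0.75)
  c(q1 = q1, q3 = q3, lower = q1 - k * (q3 - q1), upper = q3 + k * (q3 - q1))
}

# contrast vector for a single named coefficient
unit_contrast <- function(fit, name) {
  v <- numeric(length(coef(fit)))
  v[which(names(coef(fit)) == name)] <- 1
  v
}

# balanced two-sex cohort with a given subject-intercept SD and iid noise,
# used for the Satterthwaite df properties
balanced_cohort <- function(sb, n = 24, sd_e = 0.2, seed = 5) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n))
  d <- expand.grid(subject_id = ids, month = expedition_months(),
                   stringsAsFactors = FALSE)
  sexes <- ifelse(seq_len(n) <= n / 2, "M", "F")
  d$sex <- sexes[match(d$subject_id, ids)]
  b <- stats::setNames(rnorm(n, 0, sb), ids)
  d$y <- b[d$subject_id] + rnorm(nrow(d), 0, sd_e)
  base <- data.frame(subject_id = ids, month = "BASELINE", sex = sexes,
                     y = rnorm(n, 0, sd_e), stringsAsFactors = FALSE)
  rbind(d[, c("subject_id", "sex", "month", "y")], base)
}

quiet_lmm <- function(...) suppressWarnings(suppressMessages(hrv_lmm(...)))

# replace the fixed effects of a fit with ones reproducing given
# (month x sex) adjusted means exactly (least-squares inversion of the
# grid model matrix); used to test contrast arithmetic identities
set_emms <- function(fit, emm_f, emm_m) {
  g <- icehrv:::.emm_grid(fit)
  target <- numeric(nrow(g$grid))
  target[g$grid$sex == "F"] <- emm_f[match(g$grid$month[g$grid$sex == "F"],
                                           fit$month_levels)]
  target[g$grid$sex == "M"] <- emm_m[match(g$grid$month[g$grid$sex == "M"],
                                           fit$month_levels)]
  bcol <- which(colnames(g$R) == "baseline_c")
  beta <- numeric(ncol(g$R))
  beta[-bcol] <- solve(g$R[, -bcol], target)
  names(beta) <- names(fit$beta)
  fit$beta <- beta
  fit
}
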