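test_that("null simulations give near-zero fixed effects; shifts move only the intercept", {
  co <- generate_cohort(null_spec(), seed = 31)
  fit <- quiet_lmm("log_hf", co)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit)[-1][names(coef(fit))[-1] != "baseline_c"]) <
                    3 * se[-1][names(coef(fit))[-1] != "baseline_c"]))

  co2 <- co
  co2$log_hf <- co2$log_hf + 5
  fit2 <- quiet_lmm("log_hf", co2)
  # baseline covariate shifts too, so the intercept moves by 5 minus the
  # covariate-absorbed part; compare predictions instead: all cell means +5
  expect_equal(adjusted_means(fit2)$emmean, adjusted_means(fit)$emmean + 5,
               tolerance = 1e-6)
  expect_equal(coef(fit2)[-1], coef(fit)[-1], tolerance = 1e-6)
})

test_that("variance components are recovered without bias at the study n", {
  sp <- null_spec(baseline_from_intercept = FALSE)
  set.seed(32)
  vc <- replicate(60, variance_components(quiet_lmm("log_hf",
                                                    generate_cohort(sp))))
  expect_lt(abs(mean(vc["sigma_b2", ]) - 0.09) / 0.09, 0.10)
  expect_lt(abs(mean(vc["sigma_e2", ]) - 0.04) / 0.04, 0.10)
})

test_that("Type III tests carry df1 = 8, 1, 8 and detect injected time effects", {
  co <- generate_cohort(cohort_spec(outlier_rate = 0), seed = 33)
  fit <- quiet_lmm("log_hf", co)
  ft <- fixed_effect_tests(fit)
  expect_equal(ft$df1[ft$effect == "Time"], 8)
  expect_equal(ft$df1[ft$effect == "Sex"], 1)
  expect_equal(ft$df1[ft$effect == "Time × Sex"], 8)
  # strong injected linear time trend, no sex trend difference
  expect_gt(ft$F[ft$effect == "Time"], ft$F[ft$effect == "Sex"])
  expect_lt(ft$p[ft$effect == "Time"], 0.001)

  # permuting month labels within subject destroys the time effect
  set.seed(34)
  perm <- co
  exp_rows <- which(perm$month != "BASELINE")
  for (sid in unique(perm$subject_id)) {
    r <- exp_rows[perm$subject_id[exp_rows] == sid]
    perm$month[r] <- sample(perm$month[r])
  }
  ftp <- fixed_effect_tests(quiet_lmm("log_hf", perm))
  expect_lt(ftp$F[ftp$effect == "Time"], ft$F[ft$effect == "Time"] / 5)
})

test_that("contrast arithmetic matches lmerTest and emmeans oracles", {
  skip_if_not_installed("lmerTest")
  skip_if_not_installed("emmeans")
  co <- generate_cohort(cohort_spec(outlier_rate = 0), seed = 35)
  fit <- quiet_lmm("log_hf", co)
  lt <- lmerTest::lmer(.y ~ month * sex + baseline_c + (1 | subject_id),
                       data = fit$data, REML = TRUE)
  # single coefficients and a composite contrast
  for (nm in c("month1", "sex1", "month3:sex1")) {
    cvec <- unit_contrast(fit, nm)
    mine <- contrast_test(fit, cvec)
    orac <- lmerTest::contest1D(lt, cvec)
    expect_equal(mine$estimate, orac$Estimate, tolerance = 1e-8)
    expect_equal(mine$se, orac$`Std. Error`, tolerance = 1e-8)
    expect_equal(mine$df, orac$df, tolerance = 0.02)
    expect_equal(mine$p, orac$`Pr(>|t|)`, tolerance = 1e-4)
  }
  # brute-force c'beta / sqrt(c'Vc) from the lme4 fit
  cvec <- rep(0, length(coef(fit))); cvec[2] <- 1; cvec[3] <- -1
  mine <- contrast_test(fit, cvec)
  expect_equal(mine$estimate,
               sum(cvec * lme4::fixef(lt)), tolerance = 1e-8)
  expect_equal(mine$se,
               sqrt(drop(t(cvec) %*% as.matrix(vcov(lt)) %*% cvec)),
               tolerance = 1e-8)
  expect_equal(mine$t, mine$estimate / mine$se, tolerance = 1e-12)

  # emmeans polynomial t statistics (orthonormal vs integer coefficients:
  # t, df, p are scale-invariant)
  pc <- polynomial_contrasts(fit)
  em <- emmeans::emmeans(lt, ~ month | sex, at = list(baseline_c = 0),
                         lmer.df = "satterthwaite")
  ec <- summary(emmeans::contrast(em, "poly", max.degree = 3))
  for (tr in c("linear", "quadratic", "cubic")) {
    for (sx in c("F", "M")) {
      g <- if (sx == "F") "Women" else "Men"
      trn <- paste0(toupper(substr(tr, 1, 1)), substr(tr, 2, nchar(tr)))
      mine <- pc[pc$contrast == trn & pc$group == g, ]
      orac <- ec[ec$contrast == tr & ec$sex == sx, ]
      expect_equal(mine$t, orac$t.ratio, tolerance = 1e-6)
      expect_equal(mine$df, orac$df, tolerance = 0.02)
    }
  }
})

test_that("F equals t^2 for single-df effects", {
  co <- generate_cohort(cohort_spec(outlier_rate = 0), seed = 36)
  fit <- quiet_lmm("log_hf", co)
  ft <- fixed_effect_tests(fit)
  ct <- contrast_test(fit, unit_contrast(fit, "sex1"))
  expect_equal(ft$F[ft$effect == "Sex"], ct$t^2, tolerance = 1e-6)
  expect_equal(ft$df2[ft$effect == "Sex"], ct$df, tolerance = 1e-6)
})

test_that("adjusted means match emmeans and are invariant to covariate centring", {
  skip_if_not_installed("emmeans")
  co <- generate_cohort(cohort_spec(outlier_rate = 0), seed = 37)
  fit <- quiet_lmm("log_hf", co)
  am <- adjusted_means(fit)
  lt <- lme4::lmer(.y ~ month * sex + baseline_c + (1 | subject_id),
                   data = fit$data, REML = TRUE)
  em <- as.data.frame(emmeans::emmeans(lt, ~ month + sex,
                                       at = list(baseline_c = 0),
                                       lmer.df = "asymptotic"))
  key <- paste(am$month, am$sex)
  ek <- paste(em$month, em$sex)
  expect_equal(am$emmean, em$emmean[match(key, ek)], tolerance = 1e-8)
  expect_equal(am$se, em$SE[match(key, ek)], tolerance = 1e-8)

  co2 <- co
  co2$log_hf[co2$month == "BASELINE"] <-
    co2$log_hf[co2$month == "BASELINE"] + 10
  am2 <- adjusted_means(quiet_lmm("log_hf", co2))
  expect_equal(am2$emmean, am$emmean, tolerance = 1e-6)

  # known cell means recovered within 3 SE
  truth <- attr(co, "truth")$spec$effects$log_hf$intercept["F"]
  w_feb <- am[am$month == "Feb" & am$sex == "F", ]
  expect_lt(abs(w_feb$emmean - truth), 3 * w_feb$se + 0.2)
})

test_that("polynomial and trimester contrast identities hold exactly", {
  co <- generate_cohort(null_spec(), seed = 38)
  fit <- quiet_lmm("log_hf", co)

  # exactly linear adjusted means: quadratic and cubic vanish
  lin <- 2 + 0.1 * (1:9)
  fitL <- set_emms(fit, lin, lin + 0.5)
  pc <- polynomial_contrasts(fitL)
  expect_lt(max(abs(pc$estimate[pc$contrast %in% c("Quadratic", "Cubic") &
                                  pc$group != "Difference"])), 1e-9)
  # linear estimate proportional to the slope (orthonormal: slope * sqrt(60))
  expect_equal(pc$estimate[pc$contrast == "Linear" & pc$group == "Women"],
               0.1 * sqrt(sum(((1:9) - 5)^2)), tolerance = 1e-9)

  # equal-sex means: every Difference row is zero
  fitE <- set_emms(fit, lin, lin)
  pcE <- polynomial_contrasts(fitE)
  tcE <- trimester_contrasts(fitE)
  expect_lt(max(abs(pcE$estimate[pcE$group == "Difference"])), 1e-9)
  expect_lt(max(abs(tcE$estimate[tcE$group == "Difference"])), 1e-9)

  # constant means: all trimester contrasts zero
  fitC <- set_emms(fit, rep(1, 9), rep(1, 9))
  expect_lt(max(abs(trimester_contrasts(fitC)$estimate)), 1e-9)

  # +d step in T3 only: T1-T2 = 0, T2-T3 = -d, T1-T3 = -d
  d <- 0.4
  step <- c(rep(0, 6), rep(d, 3))
  fitS <- set_emms(fit, step, step)
  tc <- trimester_contrasts(fitS)
  w <- tc[tc$group == "Women", ]
  expect_equal(w$estimate[w$contrast == "T1–T2"], 0, tolerance = 1e-9)
  expect_equal(w$estimate[w$contrast == "T2–T3"], -d, tolerance = 1e-9)
  expect_equal(w$estimate[w$contrast == "T1–T3"], -d, tolerance = 1e-9)
})

test_that("an injected T1 to T3 decline in women is recovered unbiasedly", {
  # linear decline of total 0.5 from T1 mean to T3 mean in women only:
  # T1-T3 contrast = +0.5; orthonormal linear coefficient = 0.5/(6/sqrt(60))
  sp <- cohort_spec(outlier_rate = 0, effects = list(
    log_hf = list(intercept = c(F = 2.8, M = 2.8),
                  linear = c(F = -0.5 * sqrt(60) / 6, M = 0))))
  set.seed(39)
  est <- replicate(40, {
    tc <- trimester_contrasts(quiet_lmm("log_hf", generate_cohort(sp)))
    tc$estimate[tc$contrast == "T1–T3" & tc$group == "Women"]
  })
  expect_lt(abs(mean(est) - 0.5), 3 * sd(est) / sqrt(length(est)))
})

test_that("women-only cubic trends are detected with the designed power", {
  sp <- cohort_spec(outlier_rate = 0, effects = list(
    log_hf = list(intercept = c(F = 2.8, M = 2.8),
                  cubic = c(F = 0.25, M = 0))))
  set.seed(40)
  ps <- replicate(60, {
    pc <- polynomial_contrasts(quiet_lmm("log_hf", generate_cohort(sp)))
    c(w = pc$p[pc$contrast == "Cubic" & pc$group == "Women"],
      m = pc$p[pc$contrast == "Cubic" & pc$group == "Men"])
  })
  expect_gt(mean(ps["w", ] < 0.05), 0.80)   # designed ~96% power at 0.25
  expect_lt(mean(ps["m", ] < 0.05), 0.20)   # men stay null
})

test_that("baseline t tests reproduce summary-statistic oracles", {
  d <- data.frame(sex = rep(c("F", "M"), c(10, 15)),
                  month = "BASELINE",
                  log_lf_hf = c(as.numeric(scale(rnorm(10))) * 0.379 + 0.004,
                                as.numeric(scale(rnorm(15))) * 0.239 + 0.334))
  # identical groups
  same <- data.frame(sex = rep(c("F", "M"), each = 5), month = "BASELINE",
                     v = rep(1:5, 2))
  ts <- baseline_ttests(same, "v")
  expect_equal(ts$diff, 0)
  expect_equal(ts$p, 1)

  # Welch and pooled t from the printed summary statistics (oracle formulas)
  tt_w <- baseline_ttests(d, "log_lf_hf", welch = TRUE)
  tt_p <- baseline_ttests(d, "log_lf_hf", welch = FALSE)
  se_w <- sqrt(0.239^2 / 15 + 0.379^2 / 10)
  sp2 <- ((15 - 1) * 0.239^2 + (10 - 1) * 0.379^2) / (15 + 10 - 2)
  se_p <- sqrt(sp2 * (1 / 15 + 1 / 10))
  expect_equal(tt_w$t, (0.334 - 0.004) / se_w, tolerance = 1e-6)
  expect_equal(tt_p$t, (0.334 - 0.004) / se_p, tolerance = 1e-6)
  expect_equal(round(tt_w$t, 2), 2.45)
  expect_equal(round(tt_p$t, 2), 2.68)

  # scale equivariance under pooled variance
  d2 <- d; d2$log_lf_hf <- 2 * d2$log_lf_hf
  tt2 <- baseline_ttests(d2, "log_lf_hf", welch = FALSE)
  expect_equal(tt2$diff, 2 * tt_p$diff, tolerance = 1e-9)
  expect_equal(tt2$t, tt_p$t, tolerance = 1e-9)

  small <- data.frame(sex = c("F", "M", "M"), month = "BASELINE", v = 1:3)
  expect_error(baseline_ttests(small, "v"), "at least 2")
})
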