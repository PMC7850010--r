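# Independent ICC oracle: mean squares straight out of base R's aov()
icc_oracle <- function(m) {
  long <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                     sess = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subj + sess, data = long))[[1]]
  msr <- tab["subj", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse)
}

test_that("the consistency ICC matches the brute-force ANOVA oracle", {
  m <- cbind(c(0, 2, 4, 6, 8, 10), c(0, 2, 4, 6, 8, 10) + c(1, -1, 1, -1, 1, -1))
  expect_equal(icc_consistency(m)$estimate, icc_oracle(m), tolerance = 1e-10)
  set.seed(1)
  for (i in 1:10) {
    n <- sample(5:40, 1); k <- sample(2:4, 1)
    mm <- matrix(rnorm(n * k, sd = 3), n, k) + rnorm(n)
    res <- icc_consistency(mm)
    expect_equal(res$estimate, icc_oracle(mm), tolerance = 1e-10)
    expect_lte(res$ci_low, res$estimate)
    expect_gte(res$ci_high, res$estimate)
  }
})

test_that("ICC consistency invariances and edge cases hold", {
  set.seed(2)
  m <- matrix(rnorm(20), 10, 2) + rnorm(10)
  base <- icc_consistency(m)$estimate
  # consistency model discounts column offsets
  shifted <- m; shifted[, 2] <- shifted[, 2] + 5
  expect_equal(icc_consistency(shifted)$estimate, base, tolerance = 1e-10)
  # affine rescaling of the whole matrix
  expect_equal(icc_consistency(3 * m - 7)$estimate, base, tolerance = 1e-10)
  # two identical columns: MS_err = 0 limit
  ident <- cbind(rnorm(8), 0)
  ident[, 2] <- ident[, 1]
  expect_equal(icc_consistency(ident)$estimate, 1)
  # degenerate inputs
  expect_error(icc_consistency(matrix(1, 10, 2)), "variance")
  expect_error(icc_consistency(matrix(rnorm(4), 2, 2)), "3")
  # listwise deletion drops incomplete rows
  m_na <- m; m_na[1, 2] <- NA
  expect_equal(icc_consistency(m_na)$n_subjects, 9)
  # qualitative labels at the published cutoffs
  expect_equal(icc_consistency(simulate_reliability_matrix(
    list(between_subject_sd = 10, day_sd = 0.1), 200))$label, "excellent")
})

test_that("one-tailed Pearson agrees with cor.test and its special cases", {
  set.seed(3)
  x <- rnorm(30); y <- -0.4 * x + rnorm(30)
  ours <- pearson_one_tailed(x, y, "negative")
  ref <- stats::cor.test(x, y, alternative = "less")
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  pos <- pearson_one_tailed(x, y, "positive")
  expect_equal(pos$p_value,
               stats::cor.test(x, y, alternative = "greater")$p.value,
               tolerance = 1e-10)
  # exact linear relation
  expect_equal(pearson_one_tailed(1:10, 2 * (1:10) + 1, "positive")$r, 1)
  # exactly uncorrelated: one-tailed p is 1/2 by symmetry
  expect_equal(pearson_one_tailed(c(-1, 0, 1), c(1, -2, 1),
                                  "negative")$p_value, 0.5, tolerance = 1e-12)
  expect_error(pearson_one_tailed(rep(1, 5), rnorm(5), "negative"),
               "variance")
})

test_that("one-tailed Welch matches t.test and the hand-computed case", {
  a <- c(0, 1, 2, 3, 4); b <- c(2, 3, 4, 5, 6)
  ours <- welch_one_tailed(a, b, "less")
  # closed form: t = (2 - 4) / sqrt(2.5/5 + 2.5/5) = -2, Welch df = 8
  expect_equal(ours$statistic, -2, tolerance = 1e-12)
  expect_equal(ours$df, 8, tolerance = 1e-12)
  ref <- stats::t.test(a, b, alternative = "less")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  set.seed(4)
  x <- rnorm(12, sd = 2); y <- rnorm(20, mean = 1)
  expect_equal(welch_one_tailed(x, y, "greater")$p_value,
               stats::t.test(x, y, alternative = "greater")$p.value,
               tolerance = 1e-10)
  # identical samples: t = 0, p = 1/2
  same <- c(1, 2, 3)
  expect_equal(welch_one_tailed(same, same, "greater")$p_value, 0.5)
  # full separation drives p to the tail
  expect_lt(welch_one_tailed(c(1, 2, 3) + 10, c(1, 2, 3), "greater")$p_value,
            0.01)
  expect_error(welch_one_tailed(c(1, 1), c(1, 1), "greater"), "variance")
})

test_that("prediction bands match lm's prediction intervals", {
  set.seed(5)
  ages <- runif(15, 6, 17)
  srts <- -4 - 0.5 * ages + rnorm(15, sd = 2)
  band <- fit_prediction_band(ages, srts)
  fit <- stats::lm(srts ~ ages)
  for (x0 in c(8, 16)) {
    ref <- stats::predict(fit, newdata = data.frame(ages = x0),
                          interval = "prediction", level = 0.95)
    ours <- predict(band, x0)
    expect_equal(ours$fit, unname(ref[1, "fit"]), tolerance = 1e-10)
    expect_equal(ours$lower, unname(ref[1, "lwr"]), tolerance = 1e-10)
    expect_equal(ours$upper, unname(ref[1, "upr"]), tolerance = 1e-10)
  }
  # noiseless data: the band collapses onto the line
  exact <- fit_prediction_band(1:10, 3 - 2 * (1:10))
  expect_equal(exact$residual_sd, 0, tolerance = 1e-10)
  pb <- predict(exact, 5)
  expect_equal(pb$lower, pb$upper, tolerance = 1e-8)
  # band is narrowest at the design mean
  widths <- with(predict(band, c(band$mean_x - 4, band$mean_x,
                                 band$mean_x + 4)), upper - lower)
  expect_true(widths[2] < widths[1] && widths[2] < widths[3])
  expect_error(fit_prediction_band(rep(8, 5), rnorm(5)), "degenerate")
})

test_that("prediction bands cover fresh observations at the nominal rate", {
  set.seed(6)
  hits <- 0L; total <- 0L
  for (rep in 1:200) {
    ages <- runif(15, 6, 17)
    srts <- -4 - 0.5 * ages + rnorm(15, sd = 2)
    band <- fit_prediction_band(ages, srts)
    newx <- runif(50, 6, 17)
    newy <- -4 - 0.5 * newx + rnorm(50, sd = 2)
    pb <- predict(band, newx)
    hits <- hits + sum(newy >= pb$lower & newy <= pb$upper)
    total <- total + 50L
  }
  expect_lt(abs(hits / total - 0.95), 0.02)
})

test_that("outlier flagging marks only points outside the band", {
  band <- fit_prediction_band(c(6, 8, 10, 12, 14, 16),
                              c(-10, -11, -12, -13, -14, -15) +
                                c(0.3, -0.3, 0.2, -0.2, 0.1, -0.1))
  on_line <- tibble::tibble(age = 11, srt = band$intercept + band$slope * 11)
  expect_false(flag_outliers(band, on_line)$flagged)
  inside <- tibble::tibble(age = c(7, 13), srt = band$intercept +
                             band$slope * c(7, 13) + c(0.2, -0.2))
  expect_equal(sum(flag_outliers(band, inside)$flagged), 0)
  far <- tibble::tibble(age = 10, srt = band$intercept + band$slope * 10 - 20)
  fl <- flag_outliers(band, far)
  expect_true(fl$flagged)
  expect_equal(fl$side, "below")
})

test_that("an anomalous-hardware listener is flagged below the lab band", {
  cfg <- preset_paper_day1()
  mid <- mean(cfg$child_age_range)
  set.seed(7)
  n_flagged <- 0L
  for (rep in 1:60) {
    # laboratory-mode normative fit: children only, no staircase noise model
    ages <- runif(15, 6.3, 17.1)
    srts <- cfg$mean_true_srt$child[["M0TPI"]] +
      cfg$age_slope * (ages - mid) + rnorm(15, sd = cfg$between_subject_sd)
    band <- fit_prediction_band(ages, srts)
    # remote listener with a +15 dB antiphasic anomaly, measured by staircase
    prof <- listener_profile(age_years = 9, group = "child",
                             mu_m0t0 = cfg$mean_true_srt$child[["M0T0"]] -
                               bildsim:::srt_offset(2),
                             bild_true = cfg$mean_bild[["child"]],
                             mu_quiet = -35, hardware_anomaly_db = 15)
    day_srt <- mean(replicate(3, run_adaptive_track(prof, "M0TPI")$srt))
    fl <- flag_outliers(band, tibble::tibble(age = 9, srt = day_srt))
    n_flagged <- n_flagged + (fl$flagged && fl$side == "below")
  }
  expect_gte(n_flagged / 60, 0.95)
})

test_that("audibility margins follow the quiet-vs-masked rule", {
  # quiet -35, lowest masked target level -12: 23 dB margin, unflagged
  res <- audibility_check(-35, -12, masker_ref = 0)
  expect_equal(res$margin_db, 23)
  expect_false(res$flagged)
  # boundary: a margin of exactly 6 dB is not flagged (strict <)
  expect_false(audibility_check(-20, -14, masker_ref = 0)$flagged)
  # audibility-limited case
  res2 <- audibility_check(-10, -8, masker_ref = 0)
  expect_equal(res2$margin_db, 2)
  expect_true(res2$flagged)
  # masker reference shifts masked levels onto the comfortable scale
  expect_equal(audibility_check(-35, c(-15, -9), masker_ref = 3)$margin_db,
               23)
  expect_true(is.na(audibility_check(NA, -12)$flagged))
  expect_error(audibility_check(-35, numeric(0)), "masked")
})

test_that("the assembled report carries means, ICCs, tests and flags", {
  cfg <- cohort_config(n_children = 10, n_adults = 4,
                       between_subject_sd = 1.5, bild_sd = 1,
                       quiet_between_sd = 3, quiet_day_sd = 1,
                       day_sd = c(M0T0 = 0.8, M0TPI = 0.8))
  set.seed(8)
  st <- simulate_study(cfg, days = c(1, 2, 7))
  rep_full <- build_report(st$runs)
  expect_s3_class(rep_full, "analysis_report")
  expect_equal(nrow(rep_full$group_means), 6)  # 2 groups x 3 days
  expect_true(all(c("measure", "pair", "estimate") %in%
                    names(rep_full$icc)))
  expect_true(all(rep_full$icc$ci_low <= rep_full$icc$estimate))
  expect_equal(nrow(rep_full$audibility), 14 * 3)
  # no quiet-limited sessions in this comfortable-margin cohort
  expect_true(all(!rep_full$audibility$flagged, na.rm = TRUE))

  # a single participant yields means but no ICC (needs n >= 3)
  one <- simulate_study(cohort_config(n_children = 1, n_adults = 0),
                        days = c(1, 2), seed = 9)
  rep_one <- build_report(one$runs)
  expect_equal(nrow(rep_one$icc), 0)
  expect_true(is.finite(
    rep_one$group_means$srt_m0t0_mean[rep_one$group_means$day == 1]))

  # prediction-band screening path
  band <- fit_prediction_band(runif(15, 6, 17), rnorm(15, -15, 3))
  rep_band <- build_report(st$runs, lab_band = list(M0TPI = band))
  expect_true(!is.null(rep_band$outliers))
  expect_true(all(rep_band$outliers$measure == "M0TPI"))
})

test_that("report tidiers return one-row summaries", {
  set.seed(10)
  m <- simulate_reliability_matrix(preset_reliability("bild-day12"), 39)
  res <- icc_consistency(m)
  td <- generics::tidy(res)
  expect_equal(nrow(td), 1)
  expect_equal(td$estimate, res$estimate)
  gl <- generics::glance(res)
  expect_equal(gl$n_subjects, 39)
  band <- fit_prediction_band(runif(10, 6, 17), rnorm(10))
  expect_equal(nrow(generics::tidy(band)), 2)
  expect_equal(generics::glance(band)$n, 10)
})
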