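#' Two-way consistency intraclass correlation (single measure)
#'
#' ICC from the two-way ANOVA decomposition without interaction: with
#' `MS_rows` (subjects), `MS_cols` (sessions) and `MS_err` mean squares,
#'
#'   ICC(C,1) = (MS_rows - MS_err) / (MS_rows + (k - 1) MS_err).
#'
#' The consistency model discounts systematic session offsets, so adding a
#' constant to any column leaves the estimate unchanged. The confidence
#' interval is the exact F-based interval for the single-measure consistency
#' ICC: with `F = MS_rows / MS_err` on (n-1) and (n-1)(k-1) df,
#' `FL = F / qf(1 - alpha/2, n-1, (n-1)(k-1))`,
#' `FU = F * qf(1 - alpha/2, (n-1)(k-1), n-1)`, and bounds
#' `(FL - 1)/(FL + k - 1)`, `(FU - 1)/(FU + k - 1)`. Reliability labels:
#' "good" for 0.75-0.90, "excellent" above 0.90.
#'
#' @param matrix numeric matrix, n subjects x k repeated measurements; rows
#'   containing missing values are listwise-deleted.
#' @param alpha CI tail mass (default 0.05 for a 95% interval).
#' @return an `icc_result`: `estimate`, `ci_low`, `ci_high`, `n_subjects`,
#'   `k_measurements`, `model`, `label`, `alpha`.
#' @export
icc_consistency <- function(matrix, alpha = 0.05) {
  m <- as.matrix(matrix)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("need at least 3 complete subjects", call. = FALSE)
  if (k < 2) stop("need at least 2 measurements", call. = FALSE)
  grand <- mean(m)
  row_means <- rowMeans(m); col_means <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total < .Machine$double.eps * n * k) {
    stop("zero total variance", call. = FALSE)
  }
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  est <- (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
  if (ms_err <= .Machine$double.eps * ms_rows) {
    est <- 1; ci <- c(1, 1)
  } else {
    f <- ms_rows / ms_err
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- f / qf(1 - alpha / 2, df1, df2)
    fu <- f * qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  label <- if (est > 0.9) "excellent" else if (est >= 0.75) "good"
           else "below good"
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 n_subjects = n, k_measurements = k,
                 model = "two-way consistency, single measure",
                 label = label, alpha = alpha),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(C,1) = %.3f (%d%% CI %.3f-%.3f), n = %d, k = %d [%s]\n",
              x$estimate, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              x$n_subjects, x$k_measurements, x$label))
  invisible(x)
}

#' One-tailed Pearson correlation test
#'
#' Product-moment correlation with the one-tailed p-value from the t
#' transform `t = r sqrt((n - 2) / (1 - r^2))` in the stated direction.
#'
#' @param x,y paired measurements.
#' @param direction predicted sign of the association: `"negative"` (e.g.
#'   thresholds improving, i.e. falling, with age) or `"positive"`.
#' @return one-row tibble: `r`, `statistic`, `df`, `p_value`, `n`,
#'   `direction`.
#' @export
pearson_one_tailed <- function(x, y, direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (direction == "negative") pt(tstat, n - 2)
       else pt(tstat, n - 2, lower.tail = FALSE)
  tibble::tibble(r = r, statistic = tstat, df = n - 2, p_value = p, n = n,
                 direction = direction)
}

#' One-tailed Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a one-tailed p-value.
#'
#' @param a,b the two samples.
#' @param direction `"greater"` tests mean(a) > mean(b); `"less"` the
#'   reverse.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `direction`.
#' @export
welch_one_tailed <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 observations per sample", call. = FALSE)
  }
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) stop("degenerate samples: no variance", call. = FALSE)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- if (direction == "greater") pt(tstat, df, lower.tail = FALSE)
       else pt(tstat, df)
  tibble::tibble(statistic = tstat, df = df, p_value = p,
                 mean_a = mean(a), mean_b = mean(b), direction = direction)
}

#' Fit a regression prediction band
#'
#' Ordinary least squares of SRT on age, with the classical prediction
#' interval for a new observation at `x0`:
#'
#'   yhat(x0) +/- t(1 - (1-level)/2, n-2) * s * sqrt(1 + 1/n +
#'     (x0 - xbar)^2 / Sxx).
#'
#' Used to screen new (e.g. remotely collected) observations against a
#' normative laboratory-style fit.
#'
#' @param ages predictor, years.
#' @param srts response, dB.
#' @param level coverage probability of the band (default 0.95).
#' @return a `prediction_band`: `slope`, `intercept`, `residual_sd`, `n`,
#'   `mean_x`, `sxx`, `level`.
#' @export
fit_prediction_band <- function(ages, srts, level = 0.95) {
  keep <- is.finite(ages) & is.finite(srts)
  ages <- ages[keep]; srts <- srts[keep]
  n <- length(ages)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  sxx <- sum((ages - mean(ages))^2)
  if (sxx == 0) stop("degenerate design: no age variance", call. = FALSE)
  fit <- stats::lm(srts ~ ages)
  s <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = s, n = n, mean_x = mean(ages), sxx = sxx,
                 level = level),
            class = "prediction_band")
}

#' Evaluate a prediction band
#'
#' @param object a `prediction_band`.
#' @param x0 ages at which to evaluate.
#' @param ... unused.
#' @return tibble: `x`, `fit`, `lower`, `upper`.
#' @export
predict.prediction_band <- function(object, x0, ...) {
  tcrit <- qt(1 - (1 - object$level) / 2, object$n - 2)
  fit <- object$intercept + object$slope * x0
  half <- tcrit * object$residual_sd *
    sqrt(1 + 1 / object$n + (x0 - object$mean_x)^2 / object$sxx)
  tibble::tibble(x = x0, fit = fit, lower = fit - half, upper = fit + half)
}

#' Flag observations outside a prediction band
#'
#' @param band a [fit_prediction_band()] result.
#' @param observations data frame with columns `age` and `srt` (extra
#'   columns pass through).
#' @return the observations with `fit`, `lower`, `upper`, `flagged`, and
#'   `side` (`"below"`, `"above"`, or NA).
#' @export
flag_outliers <- function(band, observations) {
  stopifnot(all(c("age", "srt") %in% names(observations)))
  pb <- predict(band, observations$age)
  dplyr::mutate(tibble::as_tibble(observations),
                fit = pb$fit, lower = pb$lower, upper = pb$upper,
                flagged = .data$srt < .data$lower | .data$srt > .data$upper,
                side = dplyr::case_when(.data$srt < .data$lower ~ "below",
                                        .data$srt > .data$upper ~ "above",
                                        TRUE ~ NA_character_))
}

#' Audibility check against the quiet threshold
#'
#' Compares a listener's quiet SRT with the lowest masked SRT of the same
#' session to verify that masked recognition was not limited by absolute
#' audibility. Masked SRTs (dB SNR) are converted to the dB re comfortable
#' scale as `masker_ref + SRT`, where `masker_ref` is the masker level on
#' that scale; the margin is the minimum converted masked target level minus
#' the quiet SRT, and margins below 6 dB (strictly) are flagged.
#'
#' @param quiet_srt quiet SRT, dB re comfortable (NA gives a missing flag).
#' @param masked_srts masked SRTs of the session, dB SNR.
#' @param masker_ref masker level in dB re comfortable (default 0: masker at
#'   the reference).
#' @return one-row tibble: `margin_db`, `flagged`.
#' @export
audibility_check <- function(quiet_srt, masked_srts, masker_ref = 0) {
  masked_srts <- masked_srts[is.finite(masked_srts)]
  if (length(masked_srts) == 0) stop("no masked SRTs", call. = FALSE)
  if (!is.finite(quiet_srt)) {
    return(tibble::tibble(margin_db = NA_real_, flagged = NA))
  }
  margin <- min(masker_ref + masked_srts) - quiet_srt
  tibble::tibble(margin_db = margin, flagged = margin < 6)
}

icc_pair <- function(sessions, measure, days, alpha = 0.05) {
  wide <- sessions |>
    dplyr::filter(.data$day %in% days) |>
    dplyr::select("id", "day", value = dplyr::all_of(measure)) |>
    tidyr::pivot_wider(names_from = "day", values_from = "value") |>
    dplyr::select(-"id") |>
    as.matrix()
  if (ncol(wide) < 2 || sum(stats::complete.cases(wide)) < 3) return(NULL)
  icc_consistency(wide, alpha)
}

#' Assemble the full analysis report
#'
#' Computes the statistical stage over simulated (or imported) results:
#' per-group, per-day condition means and BILDs; test-retest consistency
#' ICCs for Day 1-2 and Day 1-7 (listwise-deleted per pair) for the masked
#' SRTs, the BILD and the quiet SRT; the group contrast (Welch, one-tailed,
#' adults better) and child age correlations (Pearson, one-tailed,
#' improvement with age) on Day 1; per-session audibility flags; and, when a
#' normative band or laboratory-style data are supplied, prediction-interval
#' outlier flags for child Day-1 SRTs.
#'
#' @param runs run-level tibble from [simulate_cohort()].
#' @param lab_band optional named list of [fit_prediction_band()] objects
#'   (e.g. `list(M0T0 =, M0TPI =, bild =)`) fitted to laboratory-mode data.
#' @param masker_ref masker level re comfortable for [audibility_check()].
#' @param alpha CI tail mass for ICCs.
#' @return an `analysis_report` list: `group_means`, `icc`, `group_tests`,
#'   `age_correlations`, `audibility`, `outliers`.
#' @export
build_report <- function(runs, lab_band = NULL, masker_ref = 0,
                         alpha = 0.05) {
  sessions <- session_summary(runs)
  group_means <- sessions |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(dplyr::across(c("quiet_srt", "srt_m0t0", "srt_m0tpi",
                                     "bild"),
                                   list(mean = ~ mean(.x, na.rm = TRUE),
                                        n = ~ sum(is.finite(.x)))),
                     .groups = "drop")

  measures <- c(srt_m0t0 = "srt_m0t0", srt_m0tpi = "srt_m0tpi",
                bild = "bild", quiet_srt = "quiet_srt")
  pairs <- list(day12 = c(1, 2), day17 = c(1, 7))
  icc_tbl <- purrr::map_dfr(names(measures), function(m) {
    purrr::map_dfr(names(pairs), function(p) {
      res <- icc_pair(sessions, measures[[m]], pairs[[p]], alpha)
      if (is.null(res)) return(NULL)
      tibble::tibble(measure = m, pair = p, estimate = res$estimate,
                     ci_low = res$ci_low, ci_high = res$ci_high,
                     n = res$n_subjects, label = res$label)
    })
  })

  d1 <- dplyr::filter(sessions, .data$day == 1)
  ch <- dplyr::filter(d1, .data$group == "child")
  ad <- dplyr::filter(d1, .data$group == "adult")
  group_tests <- NULL
  if (nrow(ch) >= 2 && nrow(ad) >= 2) {
    group_tests <- purrr::map_dfr(
      c("srt_m0t0", "srt_m0tpi", "bild", "quiet_srt"),
      function(m) {
        dir <- if (m == "bild") "less" else "greater"  # adults better
        dplyr::mutate(welch_one_tailed(ch[[m]], ad[[m]], dir),
                      measure = m, .before = 1)
      })
  }
  age_correlations <- NULL
  if (nrow(ch) >= 3) {
    age_correlations <- purrr::map_dfr(
      c("srt_m0t0", "srt_m0tpi", "bild", "quiet_srt"),
      function(m) {
        ok <- is.finite(ch[[m]])
        if (sum(ok) < 3 || stats::sd(ch[[m]][ok]) == 0) return(NULL)
        dplyr::mutate(pearson_one_tailed(ch$age_years, ch[[m]], "negative"),
                      measure = m, .before = 1)
      })
  }

  audibility <- sessions |>
    dplyr::rowwise() |>
    dplyr::mutate(audibility_check(.data$quiet_srt,
                                   c(.data$srt_m0t0, .data$srt_m0tpi),
                                   masker_ref)) |>
    dplyr::ungroup() |>
    dplyr::select("id", "group", "day", "quiet_srt", "margin_db", "flagged")

  outliers <- NULL
  if (!is.null(lab_band)) {
    obs_for <- function(m) {
      tibble::tibble(id = ch$id, age = ch$age_years, srt = ch[[m]])
    }
    map_m <- c(M0T0 = "srt_m0t0", M0TPI = "srt_m0tpi", bild = "bild")
    outliers <- purrr::map_dfr(names(lab_band), function(nm) {
      m <- map_m[[nm]]
      dplyr::mutate(flag_outliers(lab_band[[nm]], obs_for(m)),
                    measure = nm, .before = 1)
    })
  }

  structure(list(group_means = group_means, icc = icc_tbl,
                 group_tests = group_tests,
                 age_correlations = age_correlations,
                 audibility = audibility, outliers = outliers),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Group means (by group x day) ==\n")
  print(x$group_means, n = Inf)
  cat("\n== Test-retest consistency ICCs ==\n")
  print(x$icc, n = Inf)
  if (!is.null(x$group_tests)) {
    cat("\n== Group contrasts (Welch, one-tailed) ==\n")
    print(x$group_tests)
  }
  if (!is.null(x$age_correlations)) {
    cat("\n== Child age correlations (Pearson, one-tailed) ==\n")
    print(x$age_correlations)
  }
  n_flag <- sum(x$audibility$flagged, na.rm = TRUE)
  cat("\nAudibility margins < 6 dB: ", n_flag, " of ",
      sum(is.finite(x$audibility$margin_db)), " sessions\n", sep = "")
  if (!is.null(x$outliers)) {
    cat("Prediction-band outlier flags: ",
        sum(x$outliers$flagged, na.rm = TRUE), "\n", sep = "")
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' @param report an `analysis_report`.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(purrr::map(unclass(report),
                                  ~ if (is.data.frame(.x)) as.data.frame(.x)
                                    else .x),
                       path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
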