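#' Cohort generative configuration
#'
#' Population-level parameters for sampling simulated listeners. Group mean
#' thresholds are specified as true SRTs at the two-down/one-up convergence
#' point (the 70.7% level); psychometric midpoints are back-computed from
#' slope, guess and lapse. The additive model per child is
#'
#'   srt_m0t0 = group mean + age_slope * (age - midrange) + b,  b ~ N(0, sd_b)
#'
#' with `bild ~ N(mean_bild, bild_sd)` and `srt_m0tpi = srt_m0t0 - bild`, so
#' the antiphasic condition inherits both sources of spread. Day-to-day
#' variation adds an independent per-condition perturbation with `day_sd`
#' before each session.
#'
#' @param n_children,n_adults group sizes.
#' @param child_age_range,adult_age_range ages sampled uniformly, years.
#' @param mean_true_srt named list `child`/`adult`, each `c(M0T0=, M0TPI=)`
#'   in dB SNR.
#' @param between_subject_sd between-subject SD of the M0T0 true SRT, dB.
#' @param day_sd named per-condition day-to-day SD `c(M0T0=, M0TPI=)`, dB.
#' @param age_slope child threshold change per year, dB/year (negative =
#'   better with age); applied to the M0T0 anchor so both masked conditions
#'   shift together.
#' @param mean_bild named `c(child=, adult=)` group mean true BILD, dB.
#' @param bild_sd between-subject SD of the true BILD, dB.
#' @param quiet_mean named `c(child=, adult=)` quiet true SRT, dB re
#'   comfortable.
#' @param quiet_between_sd,quiet_day_sd quiet-scale variance components, dB.
#' @param outlier_rate probability a listener gets the anomalous-hardware
#'   antiphasic advantage.
#' @param outlier_advantage_range dB interval for the uniform anomaly size.
#' @param slope,lapse_rate psychometric parameters given to every listener.
#' @param seed optional integer seed used by [sample_cohort()].
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_children = 28, n_adults = 11,
                          child_age_range = c(6.7, 17.6),
                          adult_age_range = c(22.8, 45.8),
                          mean_true_srt = list(
                            child = c(M0T0 = -8.9, M0TPI = -15.0),
                            adult = c(M0T0 = -11.3, M0TPI = -17.1)),
                          between_subject_sd = 2.5,
                          day_sd = c(M0T0 = 1.05, M0TPI = 0.69),
                          age_slope = -0.55,
                          mean_bild = c(child = 6.1, adult = 5.8),
                          bild_sd = 2,
                          quiet_mean = c(child = -35.1, adult = -42.1),
                          quiet_between_sd = 8, quiet_day_sd = 6.9,
                          outlier_rate = 0,
                          outlier_advantage_range = c(7.1, 9.6),
                          slope = 2, lapse_rate = 0.02, seed = NULL) {
  stopifnot(n_children >= 0, n_adults >= 0, between_subject_sd >= 0,
            all(day_sd >= 0), bild_sd >= 0, quiet_between_sd >= 0,
            quiet_day_sd >= 0, outlier_rate >= 0, outlier_rate <= 1,
            slope > 0)
  structure(list(n_children = n_children, n_adults = n_adults,
                 child_age_range = child_age_range,
                 adult_age_range = adult_age_range,
                 mean_true_srt = mean_true_srt,
                 between_subject_sd = between_subject_sd, day_sd = day_sd,
                 age_slope = age_slope, mean_bild = mean_bild,
                 bild_sd = bild_sd, quiet_mean = quiet_mean,
                 quiet_between_sd = quiet_between_sd,
                 quiet_day_sd = quiet_day_sd, outlier_rate = outlier_rate,
                 outlier_advantage_range = outlier_advantage_range,
                 slope = slope, lapse_rate = lapse_rate, seed = seed),
            class = "cohort_config")
}

#' Study-calibrated Day-1 cohort preset
#'
#' The default cohort: 28 children (ages 6.7-17.6) and 11 adults (22.8-45.8)
#' with group-mean true SRTs of -8.9/-11.3 dB SNR (children/adults, diotic
#' M0T0), -15.0/-17.1 dB SNR (antiphasic M0Tpi) and quiet means of
#' -35.1/-42.1 dB re comfortable. Group mean BILD parameters are the
#' condition-mean differences (6.1 dB children, 5.8 dB adults). No outlier
#' listeners are injected. Variance components sit at the documented
#' defaults; day-to-day SDs come from the Day 1-2 reliability presets.
#'
#' @return a [cohort_config()].
#' @export
preset_paper_day1 <- function() {
  r_t0 <- preset_reliability("m0t0-day12")
  r_tpi <- preset_reliability("m0tpi-day12")
  cohort_config(day_sd = c(M0T0 = r_t0$day_sd, M0TPI = r_tpi$day_sd))
}

#' Reliability variance-component presets
#'
#' Between-subject and day-to-day standard deviations whose population
#' consistency ICC, `sd_b^2 / (sd_b^2 + sd_d^2)`, equals the study's printed
#' test-retest point estimate for the given measure and day pair. Used to
#' generate n x 2 SRT matrices directly (bypassing the staircase) in
#' reliability-recovery checks.
#'
#' @param condition_pair one of `"m0t0-day12"`, `"m0t0-day17"`,
#'   `"m0tpi-day12"`, `"m0tpi-day17"`, `"bild-day12"`, `"bild-day17"`.
#' @return list with `between_subject_sd`, `day_sd`, `icc`, `pair`.
#' @export
preset_reliability <- function(condition_pair) {
  iccs <- c("m0t0-day12" = 0.85, "m0t0-day17" = 0.47,
            "m0tpi-day12" = 0.93, "m0tpi-day17" = 0.83,
            "bild-day12" = 0.89, "bild-day17" = 0.76)
  if (!condition_pair %in% names(iccs)) {
    stop("unknown condition pair: ", condition_pair, call. = FALSE)
  }
  icc <- unname(iccs[condition_pair])
  sd_b <- if (startsWith(condition_pair, "bild")) 2 else 2.5
  sd_d <- sd_b * sqrt((1 - icc) / icc)
  list(between_subject_sd = sd_b, day_sd = sd_d, icc = icc,
       pair = condition_pair)
}

#' Sample a cohort of listener profiles
#'
#' Draws listeners from the additive population model in [cohort_config()].
#' Ages are uniform within each group's range; the child age effect is
#' centred at the midrange so the group mean is preserved in expectation.
#' Printed-scale true SRTs are converted to psychometric midpoints via the
#' 70.7%-point offset, which cancels in all BILD differences.
#'
#' @param config a [cohort_config()].
#' @param seed optional integer; overrides `config$seed`.
#' @return tibble with one row per listener: `id`, `group`, `age_years`,
#'   `mu_m0t0`, `bild_true`, `mu_quiet`, `slope`, `guess_rate`, `lapse_rate`,
#'   `hardware_anomaly_db`, `outlier`.
#' @export
sample_cohort <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  off <- srt_offset(config$slope, 1 / 3, config$lapse_rate)
  sample_group <- function(n, group) {
    if (n == 0) return(NULL)
    rng <- if (group == "child") config$child_age_range else config$adult_age_range
    age <- runif(n, rng[1], rng[2])
    m <- config$mean_true_srt[[group]]
    age_term <- if (group == "child") {
      config$age_slope * (age - mean(rng))
    } else {
      0
    }
    srt_t0 <- m[["M0T0"]] + age_term + rnorm(n, 0, config$between_subject_sd)
    bild <- rnorm(n, config$mean_bild[[group]], config$bild_sd)
    quiet <- config$quiet_mean[[group]] + rnorm(n, 0, config$quiet_between_sd)
    anomaly <- ifelse(rbinom(n, 1, config$outlier_rate) == 1,
                      runif(n, config$outlier_advantage_range[1],
                            config$outlier_advantage_range[2]), 0)
    tibble::tibble(group = group, age_years = age,
                   mu_m0t0 = srt_t0 - off, bild_true = bild,
                   mu_quiet = quiet - off, slope = config$slope,
                   guess_rate = 1 / 3, lapse_rate = config$lapse_rate,
                   hardware_anomaly_db = anomaly, outlier = anomaly > 0)
  }
  out <- dplyr::bind_rows(sample_group(config$n_children, "child"),
                          sample_group(config$n_adults, "adult"))
  out <- dplyr::mutate(out, id = sprintf("P%02d", dplyr::row_number()),
                       .before = 1)
  class(out) <- c("listener_cohort", class(out))
  out
}

#' Generate an n x k SRT matrix from variance components
#'
#' Direct draw from the additive two-way model `y[i, j] = b[i] + e[i, j]`
#' with `b ~ N(0, between_subject_sd^2)` and `e ~ N(0, day_sd^2)`; measures
#' repeat sessions without running staircases.
#'
#' @param components output of [preset_reliability()] (or any list with
#'   `between_subject_sd` and `day_sd`).
#' @param n_subjects,k_measurements matrix dimensions.
#' @param mean_level constant added to every cell (does not affect the
#'   consistency ICC).
#' @return numeric matrix, subjects in rows.
#' @export
simulate_reliability_matrix <- function(components, n_subjects = 39,
                                        k_measurements = 2, mean_level = 0) {
  b <- rnorm(n_subjects, 0, components$between_subject_sd)
  e <- matrix(rnorm(n_subjects * k_measurements, 0, components$day_sd),
              n_subjects, k_measurements)
  mean_level + b + e
}

#' Serialize / load a cohort as JSON
#'
#' @param cohort tibble from [sample_cohort()].
#' @param path file path.
#' @export
write_cohort_json <- function(cohort, path) {
  jsonlite::write_json(as.data.frame(cohort), path, digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_cohort_json
#' @export
read_cohort_json <- function(path) {
  out <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  class(out) <- c("listener_cohort", class(out))
  out
}
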