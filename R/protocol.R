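plan_conditions <- function() {
  blocks <- unlist(lapply(1:3, function(b) sample(c("M0T0", "M0TPI"))))
  c("QUIET", blocks)
}

#' Plan one test session
#'
#' A session is seven adaptive runs: one quiet run first, then three blocks
#' of two masked runs, the order of the diotic (M0T0) and antiphasic (M0Tpi)
#' conditions randomized independently within each block.
#'
#' @param day session day: 1, 2 or 7.
#' @return a `session_plan` tibble: `day`, `run_index` (1-7), `block` (NA for
#'   the quiet run), `condition`.
#' @export
plan_session <- function(day) {
  if (!(length(day) == 1 && day %in% c(1, 2, 7))) {
    stop("day must be 1, 2 or 7", call. = FALSE)
  }
  out <- tibble::tibble(day = as.integer(day), run_index = 1:7,
                        block = c(NA_integer_, rep(1:3, each = 2)),
                        condition = plan_conditions())
  class(out) <- c("session_plan", class(out))
  out
}

session_configs <- function(configs = NULL) {
  if (is.null(configs)) {
    configs <- list(masked = masked_staircase_config(),
                    quiet = quiet_staircase_config())
  }
  stopifnot(all(c("masked", "quiet") %in% names(configs)))
  configs
}

zero_delta <- c(M0T0 = 0, M0TPI = 0, QUIET = 0)

# Runs the 7 tracks of one session for one listener. `day_delta` shifts the
# day's true thresholds per condition (dB). Returns the list of run_results.
run_session_tracks <- function(profile, day, configs, day_delta,
                               keep_trials = TRUE) {
  conds <- plan_conditions()
  lapply(seq_along(conds), function(i) {
    cond <- conds[i]
    mu <- profile_mu(profile, cond) + day_delta[[cond]]
    cfg <- if (cond == "QUIET") configs$quiet else configs$masked
    out <- run_track_engine(mu, profile$slope, profile$guess_rate,
                            profile$lapse_rate, cfg,
                            keep_trials = keep_trials)
    new_run_result(out, cond, day = as.integer(day), run_index = i)
  })
}

summarize_session_runs <- function(runs) {
  srt_of <- function(cond) {
    v <- purrr::map_dbl(runs, "srt")[purrr::map_chr(runs, "condition") == cond &
                                       purrr::map_lgl(runs, "valid")]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  quiet <- srt_of("QUIET"); t0 <- srt_of("M0T0"); tpi <- srt_of("M0TPI")
  tibble::tibble(day = runs[[1]]$day, quiet_srt = quiet, srt_m0t0 = t0,
                 srt_m0tpi = tpi, bild = t0 - tpi)
}

#' Run one session (seven tracks) for a listener
#'
#' Executes the session plan: the quiet run, then three randomized blocks of
#' the two masked conditions. Per-condition day means are averaged over valid
#' runs only; if every run of a condition is invalid the day's SRT (and the
#' BILD, if a masked condition is affected) is missing. The session BILD is
#' the day's mean M0T0 SRT minus mean M0Tpi SRT.
#'
#' @param profile a [listener_profile()] or one row of [sample_cohort()].
#' @param day 1, 2 or 7.
#' @param configs list with `masked` and `quiet` [staircase_config()]s.
#' @param day_delta named per-condition dB shift of the listener's true
#'   thresholds for this day (the day-to-day variance component).
#' @return a `session_result`: `runs` (list of `run_result`), `summary`
#'   (one-row tibble: `day`, `quiet_srt`, `srt_m0t0`, `srt_m0tpi`, `bild`).
#' @export
run_session <- function(profile, day = 1, configs = NULL,
                        day_delta = zero_delta) {
  if (!(length(day) == 1 && day %in% c(1, 2, 7))) {
    stop("day must be 1, 2 or 7", call. = FALSE)
  }
  configs <- session_configs(configs)
  runs <- run_session_tracks(profile, day, configs, day_delta)
  structure(list(runs = runs, summary = summarize_session_runs(runs)),
            class = "session_result")
}

#' Run the full multi-day protocol for one listener
#'
#' One session per requested day (default Days 1, 2 and 7), with independent
#' per-condition day effects drawn before each session: N(0, `day_sd`) for
#' the masked conditions and N(0, `quiet_day_sd`) for quiet. Day effects
#' perturb the listener's true thresholds; the mean structure has no drift
#' over days.
#'
#' @inheritParams run_session
#' @param days vector drawn from {1, 2, 7}.
#' @param day_sd named `c(M0T0=, M0TPI=)` day-to-day SD in dB.
#' @param quiet_day_sd quiet day-to-day SD in dB.
#' @return list of `session_result`, one per day.
#' @export
run_participant <- function(profile, days = c(1, 2, 7), configs = NULL,
                            day_sd = c(M0T0 = 1.05, M0TPI = 0.69),
                            quiet_day_sd = 6.9) {
  configs <- session_configs(configs)
  lapply(days, function(d) {
    delta <- c(M0T0 = rnorm(1, 0, day_sd[["M0T0"]]),
               M0TPI = rnorm(1, 0, day_sd[["M0TPI"]]),
               QUIET = rnorm(1, 0, quiet_day_sd))
    run_session(profile, d, configs, delta)
  })
}

#' Simulate a whole cohort through the protocol
#'
#' Runs every listener through every requested day, returning a long
#' run-level table. An optional missing-data mechanism drops each run's
#' record with probability `missing_rate` (emulating upload failures);
#' dropped runs have `missing = TRUE` and no SRT.
#'
#' @param cohort tibble from [sample_cohort()].
#' @param config the generating [cohort_config()] (supplies day-effect SDs).
#' @param days days to simulate.
#' @param configs staircase configs as in [run_session()].
#' @param missing_rate per-run record-loss probability (default 0).
#' @return tibble: `id`, `group`, `age_years`, `day`, `run_index`,
#'   `condition`, `srt`, `valid`, `n_trials`, `missing`.
#' @export
simulate_cohort <- function(cohort, config, days = c(1, 2, 7),
                            configs = NULL, missing_rate = 0) {
  configs <- session_configs(configs)
  n_rows <- nrow(cohort) * length(days) * 7
  id <- character(n_rows); grp <- character(n_rows); age <- numeric(n_rows)
  dy <- integer(n_rows); ri <- integer(n_rows); cond <- character(n_rows)
  srt <- numeric(n_rows); val <- logical(n_rows); ntr <- integer(n_rows)
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    prof <- cohort[i, ]
    for (d in days) {
      delta <- c(M0T0 = rnorm(1, 0, config$day_sd[["M0T0"]]),
                 M0TPI = rnorm(1, 0, config$day_sd[["M0TPI"]]),
                 QUIET = rnorm(1, 0, config$quiet_day_sd))
      runs <- run_session_tracks(prof, d, configs, delta,
                                 keep_trials = FALSE)
      for (r in runs) {
        k <- k + 1L
        id[k] <- prof$id; grp[k] <- prof$group; age[k] <- prof$age_years
        dy[k] <- r$day; ri[k] <- r$run_index; cond[k] <- r$condition
        srt[k] <- r$srt; val[k] <- r$valid; ntr[k] <- r$n_trials
      }
    }
  }
  out <- tibble::tibble(id = id, group = grp, age_years = age, day = dy,
                        run_index = ri, condition = cond, srt = srt,
                        valid = val, n_trials = ntr, missing = FALSE)
  if (missing_rate > 0) {
    drop <- runif(n_rows) < missing_rate
    out$missing[drop] <- TRUE
    out$srt[drop] <- NA_real_
    out$valid[drop] <- FALSE
  }
  out
}

#' Per-participant, per-day session summaries
#'
#' Aggregates a run-level table to day-level outcomes: the quiet SRT, the
#' per-condition means over valid runs, and the BILD (M0T0 mean minus M0Tpi
#' mean).
#'
#' @param runs tibble from [simulate_cohort()].
#' @return tibble: `id`, `group`, `age_years`, `day`, `quiet_srt`,
#'   `srt_m0t0`, `srt_m0tpi`, `bild`.
#' @export
session_summary <- function(runs) {
  runs |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$id, .data$group, .data$age_years, .data$day,
                    .data$condition) |>
    dplyr::summarise(srt = mean(.data$srt), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "srt") |>
    (\(d) {
      for (col in c("QUIET", "M0T0", "M0TPI")) {
        if (!col %in% names(d)) d[[col]] <- NA_real_
      }
      d
    })() |>
    dplyr::transmute(.data$id, .data$group, .data$age_years, .data$day,
                     quiet_srt = .data$QUIET, srt_m0t0 = .data$M0T0,
                     srt_m0tpi = .data$M0TPI,
                     bild = .data$M0T0 - .data$M0TPI)
}

#' Sample and simulate a study in one call
#'
#' Convenience wrapper: [sample_cohort()] then [simulate_cohort()] then
#' [session_summary()].
#'
#' @inheritParams simulate_cohort
#' @param config a [cohort_config()].
#' @param seed optional seed for the whole study.
#' @return list: `cohort`, `runs`, `sessions`.
#' @export
simulate_study <- function(config = preset_paper_day1(), days = c(1, 2, 7),
                           configs = NULL, missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cohort <- sample_cohort(config, seed = NULL)
  runs <- simulate_cohort(cohort, config, days, configs, missing_rate)
  list(cohort = cohort, runs = runs, sessions = session_summary(runs))
}

#' Write run-level results as long-format CSV
#'
#' @param runs tibble from [simulate_cohort()].
#' @param path file path.
#' @export
write_runs_csv <- function(runs, path) {
  utils::write.csv(as.data.frame(runs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_runs_csv
#' @export
read_runs_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
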