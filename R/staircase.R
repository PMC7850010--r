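#' Adaptive staircase configuration
#'
#' Rules for the transformed up-down (two-down/one-up) track: after
#' `down_count` consecutive correct responses the level drops one step, after
#' any error it rises one step; the run ends at `reversals_total` direction
#' reversals (or `max_trials` as a guard) and the SRT is the mean of the last
#' `reversals_averaged` reversal levels. The step size starts at
#' `step_initial` and switches to `step_final` after
#' `step_change_after_reversals` reversals, the conventional Levitt schedule.
#'
#' `masked_staircase_config()` gives the defaults on the dB SNR scale;
#' `quiet_staircase_config()` starts lower and allows a deeper floor, since
#' quiet thresholds live on the dB re comfortable scale some 30-40 dB below
#' full scale. Both presets enable `initial_descent = "single"`: during the
#' initial descent (before the first error) the level drops after every
#' correct response, the conventional hunting phase of adaptive
#' speech-reception tests. It reaches threshold quickly from an easy start,
#' which keeps reversals away from the suprathreshold descent and removes
#' most of the small upward bias that lapses during a long two-down descent
#' would otherwise put into the reversal average. `staircase_config()`
#' itself defaults to `"rule"` (the strict transformed up-down rule from the
#' very first trial).
#'
#' @param down_count,up_count consecutive-correct rule (2-down/1-up).
#' @param reversals_total reversals ending the run (8).
#' @param reversals_averaged tail reversals averaged into the SRT (6).
#' @param initial_level starting level, dB.
#' @param step_initial,step_final step sizes in dB.
#' @param step_change_after_reversals reversal count after which the step
#'   shrinks.
#' @param level_bounds c(min, max) clamp in dB.
#' @param max_trials guard against non-converging responders.
#' @param initial_descent `"rule"` (apply the down-count rule throughout) or
#'   `"single"` (1-down hunting phase until the first error).
#' @return a `staircase_config` list.
#' @export
staircase_config <- function(down_count = 2, up_count = 1,
                             reversals_total = 8, reversals_averaged = 6,
                             initial_level = 0, step_initial = 4,
                             step_final = 2, step_change_after_reversals = 2,
                             level_bounds = c(-40, 20), max_trials = 150,
                             initial_descent = c("rule", "single")) {
  initial_descent <- match.arg(initial_descent)
  stopifnot(reversals_averaged <= reversals_total,
            step_initial > 0, step_final > 0,
            length(level_bounds) == 2, level_bounds[1] < level_bounds[2],
            max_trials >= 20, down_count >= 1, up_count == 1)
  structure(list(down_count = down_count, up_count = up_count,
                 reversals_total = reversals_total,
                 reversals_averaged = reversals_averaged,
                 initial_level = initial_level, step_initial = step_initial,
                 step_final = step_final,
                 step_change_after_reversals = step_change_after_reversals,
                 level_bounds = level_bounds, max_trials = max_trials,
                 initial_descent = initial_descent),
            class = "staircase_config")
}

#' @rdname staircase_config
#' @export
masked_staircase_config <- function() {
  staircase_config(initial_descent = "single")
}

#' @rdname staircase_config
#' @export
quiet_staircase_config <- function() {
  staircase_config(initial_level = -25, level_bounds = c(-70, 0),
                   initial_descent = "single")
}

#' Fresh staircase state
#'
#' @param config a [staircase_config()].
#' @return a `staircase_state` list: `current_level`, `consecutive_correct`,
#'   `direction` (`"none"`, `"down"`, `"up"`), `reversal_levels`,
#'   `trial_count`, `finished`.
#' @export
staircase_init <- function(config) {
  structure(list(current_level = config$initial_level,
                 consecutive_correct = 0L, direction = "none",
                 reversal_levels = numeric(0), trial_count = 0L,
                 hunting = identical(config$initial_descent, "single"),
                 finished = FALSE),
            class = "staircase_state")
}

#' Advance the staircase by one trial
#'
#' Applies the two-down/one-up rule to one response. A reversal is recorded
#' at the level where the track's direction of movement flips; the first
#' up-move after the initial descent records reversal 1. Levels are clamped
#' to the configured bounds, with direction bookkeeping driven by the
#' intended move, not the clamped position.
#'
#' @param state a `staircase_state` (not finished).
#' @param config the matching [staircase_config()].
#' @param correct logical response for this trial.
#' @return the updated `staircase_state`.
#' @export
staircase_step <- function(state, config, correct) {
  if (state$finished) stop("staircase already finished", call. = FALSE)
  state$trial_count <- state$trial_count + 1L
  move <- NULL
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    need <- if (isTRUE(state$hunting)) 1L else config$down_count
    if (state$consecutive_correct >= need) {
      move <- "down"
      state$consecutive_correct <- 0L
    }
  } else {
    move <- "up"
    state$consecutive_correct <- 0L
    state$hunting <- FALSE
  }
  if (!is.null(move)) {
    if (state$direction != "none" && state$direction != move) {
      state$reversal_levels <- c(state$reversal_levels, state$current_level)
    }
    step <- if (length(state$reversal_levels) <
                config$step_change_after_reversals) {
      config$step_initial
    } else {
      config$step_final
    }
    delta <- if (move == "down") -step else step
    state$current_level <- min(max(state$current_level + delta,
                                   config$level_bounds[1]),
                               config$level_bounds[2])
    state$direction <- move
  }
  if (length(state$reversal_levels) >= config$reversals_total ||
      state$trial_count >= config$max_trials) {
    state$finished <- TRUE
  }
  state
}

# Tight inner loop shared by the track runners: psychometric parameters are
# scalars, trial storage preallocated. Uses the global RNG (one uniform per
# trial, then two for word-set metadata) so runs are seed-reproducible.
run_track_engine <- function(mu, slope, guess, lapse, config,
                             n_word_sets = 25, n_words = 3,
                             keep_trials = TRUE) {
  state <- staircase_init(config)
  mt <- config$max_trials
  lev <- numeric(mt); cor <- logical(mt); rev_flag <- logical(mt)
  wset <- integer(mt); wrd <- integer(mt)
  while (!state$finished) {
    i <- state$trial_count + 1L
    lev[i] <- state$current_level
    p <- guess + (1 - guess - lapse) /
      (1 + exp(-(state$current_level - mu) / slope))
    correct <- runif(1) < p
    wset[i] <- sample.int(n_word_sets, 1L)
    wrd[i] <- sample.int(n_words, 1L)
    n_rev_before <- length(state$reversal_levels)
    state <- staircase_step(state, config, correct)
    cor[i] <- correct
    rev_flag[i] <- length(state$reversal_levels) > n_rev_before
  }
  n <- state$trial_count
  valid <- length(state$reversal_levels) >= config$reversals_total
  srt <- if (valid) {
    mean(utils::tail(state$reversal_levels, config$reversals_averaged))
  } else {
    NA_real_
  }
  trials <- if (keep_trials) {
    tibble::tibble(trial = seq_len(n), level_db = lev[seq_len(n)],
                   correct = cor[seq_len(n)], reversal = rev_flag[seq_len(n)],
                   word_set = wset[seq_len(n)], word = wrd[seq_len(n)])
  } else {
    NULL
  }
  list(srt = srt, valid = valid, n_trials = n,
       reversal_levels = state$reversal_levels, trials = trials)
}

new_run_result <- function(engine_out, condition, day = NA_integer_,
                           run_index = NA_integer_) {
  structure(c(list(condition = condition, day = day, run_index = run_index),
              engine_out),
            class = "run_result")
}

#' Run one adaptive track against a simulated listener
#'
#' Drives [staircase_step()] with responses drawn from the listener's
#' psychometric function until the run finishes. A run is valid when the full
#' reversal count is reached within the trial budget; its SRT is the mean of
#' the last six (by default) reversal levels. Each trial also draws a word
#' set (of 25) and word (of 3) uniformly as presentation metadata (1-based
#' indices); word identity never affects the simulated response.
#'
#' @param profile a [listener_profile()].
#' @param condition `"M0T0"`, `"M0TPI"` or `"QUIET"`.
#' @param config a [staircase_config()]; defaults to
#'   [masked_staircase_config()] or [quiet_staircase_config()] by condition.
#' @return a `run_result`: `condition`, `srt`, `valid`, `reversal_levels`,
#'   `trials` tibble, `day`, `run_index`.
#' @export
run_adaptive_track <- function(profile, condition, config = NULL) {
  check_condition(condition)
  if (is.null(config)) {
    config <- if (condition == "QUIET") quiet_staircase_config()
              else masked_staircase_config()
  }
  out <- run_track_engine(profile_mu(profile, condition), profile$slope,
                          profile$guess_rate, profile$lapse_rate, config)
  new_run_result(out, condition)
}

#' @rdname run_adaptive_track
#' @export
quiet_track <- function(profile, config = quiet_staircase_config()) {
  run_adaptive_track(profile, "QUIET", config)
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result> ", x$condition,
      if (!is.na(x$day)) paste0(" day ", x$day),
      ": SRT ", if (x$valid) sprintf("%.2f dB", x$srt) else "invalid",
      " (", x$n_trials, " trials, ", length(x$reversal_levels),
      " reversals)\n", sep = "")
  invisible(x)
}

#' Flatten run results to a trials table
#'
#' @param runs a `run_result` or list of them.
#' @return tibble with one row per trial: `day`, `run_index`, `condition`,
#'   `trial`, `level_db`, `correct`, `reversal`, `word_set`, `word`.
#' @export
trials_table <- function(runs) {
  if (inherits(runs, "run_result")) runs <- list(runs)
  purrr::map_dfr(runs, function(r) {
    dplyr::mutate(r$trials, day = r$day, run_index = r$run_index,
                  condition = r$condition, .before = 1)
  })
}
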