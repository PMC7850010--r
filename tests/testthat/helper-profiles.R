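# shared fixtures: listeners and small configs used across test files

default_listener <- function(...) {
  args <- utils::modifyList(list(mu_m0t0 = -10, bild_true = 6,
                                 mu_quiet = -40, slope = 2,
                                 lapse_rate = 0.02), list(...))
  do.call(listener_profile, args)
}

steep_listener <- function(...) {
  args <- utils::modifyList(list(mu_m0t0 = -10, bild_true = 6,
                                 mu_quiet = -40, slope = 0.2,
                                 lapse_rate = 0), list(...))
  do.call(listener_profile, args)
}

# closed-form 70.7% point of the guess/lapse-corrected logistic observer:
# the independent oracle against the root-finding implementation
analytic_srt <- function(mu, slope, lapse = 0.02, guess = 1 / 3) {
  p <- (2^(-1 / 2) - guess) / (1 - guess - lapse)
  mu + slope * log(p / (1 - p))
}

# degenerate cohort: every listener identical to the group mean
degenerate_config <- function(...) {
  args <- utils::modifyList(
    list(between_subject_sd = 0, day_sd = c(M0T0 = 0, M0TPI = 0),
         age_slope = 0, bild_sd = 0, quiet_between_sd = 0,
         quiet_day_sd = 0), list(...))
  do.call(cohort_config, args)
}
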