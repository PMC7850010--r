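#' Simulated listener profile
#'
#' A simulated participant is a guess-corrected logistic psychometric
#' observer. The 3AFC task fixes the guess rate at 1/3; a lapse rate allows
#' occasional errors on easy trials. The diotic masked condition (M0T0) has
#' psychometric midpoint `mu_m0t0`; the antiphasic condition's midpoint is
#' shifted better (lower) by the listener's true BILD, plus any
#' hardware-anomaly advantage; quiet runs use `mu_quiet` on the dB re
#' comfortable scale.
#'
#' @param age_years age in years.
#' @param group `"child"` or `"adult"`.
#' @param mu_m0t0 psychometric midpoint for M0T0, dB SNR.
#' @param bild_true true binaural advantage in dB; midpoint for M0Tpi is
#'   `mu_m0t0 - bild_true - hardware_anomaly_db`.
#' @param mu_quiet quiet midpoint, dB re comfortable.
#' @param slope psychometric spread in dB (> 0); the logistic scale
#'   parameter.
#' @param guess_rate chance level; 1/3 for 3AFC.
#' @param lapse_rate probability of an attention lapse, in \[0, 0.1\].
#' @param hardware_anomaly_db extra antiphasic advantage in dB (>= 0);
#'   nonzero for the anomalous-hardware outlier mode.
#' @return one-row tibble of class `listener_profile`.
#' @export
listener_profile <- function(age_years = 30, group = c("adult", "child"),
                             mu_m0t0 = -10, bild_true = 6, mu_quiet = -40,
                             slope = 2, guess_rate = 1 / 3, lapse_rate = 0.02,
                             hardware_anomaly_db = 0) {
  group <- match.arg(group)
  stopifnot(slope > 0, lapse_rate >= 0, lapse_rate <= 0.1,
            is.finite(bild_true), hardware_anomaly_db >= 0,
            isTRUE(all.equal(guess_rate, 1 / 3)))
  out <- tibble::tibble(age_years = age_years, group = group,
                        mu_m0t0 = mu_m0t0, bild_true = bild_true,
                        mu_quiet = mu_quiet, slope = slope,
                        guess_rate = guess_rate, lapse_rate = lapse_rate,
                        hardware_anomaly_db = hardware_anomaly_db)
  class(out) <- c("listener_profile", class(out))
  out
}

profile_mu <- function(profile, condition) {
  check_condition(condition)
  switch(condition,
         QUIET = profile$mu_quiet,
         M0T0 = profile$mu_m0t0,
         M0TPI = profile$mu_m0t0 - profile$bild_true -
           profile$hardware_anomaly_db)
}

#' Probability of a correct response
#'
#' The psychometric function: `gamma + (1 - gamma - lambda) * L((x - mu) /
#' slope)` with `L` the standard logistic, `gamma` the 3AFC guess rate and
#' `lambda` the lapse rate. Nondecreasing in level.
#'
#' @param profile a [listener_profile()] (one row).
#' @param condition `"QUIET"`, `"M0T0"` or `"M0TPI"`.
#' @param level presentation level: dB SNR (masked) or dB re comfortable
#'   (quiet). Vectorized.
#' @return probability (or vector of probabilities) of a correct response.
#' @export
p_correct <- function(profile, condition, level) {
  stopifnot(all(is.finite(level)))
  mu <- profile_mu(profile, condition)
  psy_fun(level, mu, profile$slope, profile$guess_rate, profile$lapse_rate)
}

psy_fun <- function(level, mu, slope, guess, lapse) {
  guess + (1 - guess - lapse) * stats::plogis((level - mu) / slope)
}

#' Simulate a single trial response
#'
#' Bernoulli draw from [p_correct()] using R's global random stream.
#'
#' @inheritParams p_correct
#' @return logical: was the response correct.
#' @export
simulate_response <- function(profile, condition, level) {
  runif(1) < p_correct(profile, condition, level)
}

#' Analytic convergence point of the two-down/one-up track
#'
#' The level at which the probability of a correct response equals
#' `2^(-1/2)` (~0.707), the asymptotic convergence point of a
#' two-down/one-up staircase; located by root-finding on the psychometric
#' function.
#'
#' @inheritParams p_correct
#' @return level in dB (SNR or re comfortable, by condition).
#' @export
true_srt <- function(profile, condition) {
  target <- 2^(-1 / 2)
  if (1 - profile$lapse_rate <= target) {
    stop("lapse rate too high: the 70.7% point is unreachable", call. = FALSE)
  }
  mu <- profile_mu(profile, condition)
  f <- function(x) psy_fun(x, mu, profile$slope, profile$guess_rate,
                           profile$lapse_rate) - target
  uniroot(f, interval = mu + c(-100, 100) * profile$slope,
          extendInt = "upX", tol = 1e-10)$root
}

# dB offset between the psychometric midpoint and the 0.707 true-SRT point;
# cancels in BILD differences when slope and lapse are shared.
srt_offset <- function(slope, guess = 1 / 3, lapse = 0.02) {
  target <- 2^(-1 / 2)
  p <- (target - guess) / (1 - guess - lapse)
  slope * stats::qlogis(p)
}
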