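#' @importFrom stats fft rnorm runif approx uniroot qf pf pt qt rbinom
#' @importFrom rlang .data
NULL

CONDITIONS <- c("QUIET", "M0T0", "M0TPI")

#' Root-mean-square amplitude
#'
#' @param x numeric waveform.
#' @return RMS of `x`.
#' @export
rms <- function(x) sqrt(mean(x^2))

check_condition <- function(condition) {
  if (!(is.character(condition) && length(condition) == 1 &&
        condition %in% CONDITIONS)) {
    stop("`condition` must be one of ", paste(CONDITIONS, collapse = ", "),
         call. = FALSE)
  }
  condition
}

#' One-third-octave band centre frequencies
#'
#' Centre frequencies on a base-2 third-octave ladder anchored at 1 kHz,
#' spanning the requested range.
#'
#' @param fmin,fmax range limits in Hz.
#' @return numeric vector of centre frequencies (Hz, ascending).
#' @export
third_octave_centers <- function(fmin = 100, fmax = 10000) {
  k <- seq(ceiling(3 * log2(fmin / 1000)), floor(3 * log2(fmax / 1000)))
  1000 * 2^(k / 3)
}

#' Long-term average spectrum of a corpus
#'
#' Estimates the band-averaged power spectrum of a speech (or other) corpus by
#' Welch periodogram averaging of the concatenated waveforms, then averaging
#' power density within one-third-octave bands. Magnitudes are the per-band
#' mean power density in dB (so white noise is flat), normalized so that the
#' bandwidth-weighted power sum over bands is unity: the overall level of the
#' spectrum is 0 dB re the corpus RMS.
#'
#' @param waveforms a single numeric vector or a list of mono waveforms
#'   sharing `sample_rate`.
#' @param sample_rate sampling rate in Hz.
#' @param band_resolution currently only `"third-octave"`.
#' @param fmin,fmax analysis band range in Hz.
#' @param nfft segment length for periodogram averaging (power of two).
#' @return a `bild_spectrum`: tibble with columns `frequency_hz`,
#'   `magnitude_db`, and a `band_resolution` attribute.
#' @export
compute_ltas <- function(waveforms, sample_rate,
                         band_resolution = "third-octave",
                         fmin = 100, fmax = 10000, nfft = 4096) {
  if (is.numeric(waveforms)) waveforms <- list(waveforms)
  waveforms <- purrr::keep(waveforms, ~ length(.x) > 0)
  if (length(waveforms) == 0) stop("empty corpus", call. = FALSE)
  if (band_resolution != "third-octave") {
    stop("unsupported band resolution: ", band_resolution, call. = FALSE)
  }
  x <- unlist(waveforms, use.names = FALSE)
  if (all(x == 0)) stop("silent corpus (all samples zero)", call. = FALSE)

  nfft <- min(nfft, 2^floor(log2(length(x))))
  if (nfft < 64) stop("corpus too short for spectral estimation", call. = FALSE)
  hop <- nfft %/% 2
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)  # Hann
  starts <- seq(1, length(x) - nfft + 1, by = hop)
  pxx <- numeric(nfft)
  for (s in starts) pxx <- pxx + Mod(fft(x[s:(s + nfft - 1)] * win))^2
  pxx <- pxx / length(starts)
  freqs <- (seq_len(nfft) - 1) * sample_rate / nfft
  keep <- seq_len(nfft %/% 2 + 1)  # one-sided
  pxx <- pxx[keep]
  freqs <- freqs[keep]

  centers <- third_octave_centers(fmin, fmax)
  lo <- centers * 2^(-1 / 6)
  hi <- pmin(centers * 2^(1 / 6), sample_rate / 2)  # cap at Nyquist
  keep_bands <- hi > lo
  centers <- centers[keep_bands]; lo <- lo[keep_bands]; hi <- hi[keep_bands]
  band_power <- purrr::map_dbl(seq_along(centers), function(i) {
    sum(pxx[freqs >= lo[i] & freqs < hi[i]])
  })
  if (any(band_power == 0)) {
    band_power[band_power == 0] <- .Machine$double.xmin
  }
  bw <- hi - lo
  psd <- band_power / bw
  mag <- 10 * log10(psd / sum(band_power))
  out <- tibble::tibble(frequency_hz = centers, magnitude_db = mag)
  structure(out, band_resolution = band_resolution,
            class = c("bild_spectrum", class(out)))
}

#' Shape white noise to a target spectrum
#'
#' Generates Gaussian white noise and imposes the target long-term average
#' spectrum by multiplying its FFT magnitude by the target band gains (one
#' realization per seed). Gains are piecewise constant within bands, with
#' band boundaries at the geometric midpoints between centre frequencies, so
#' re-analysing the shaped noise with [compute_ltas()] recovers the target
#' band-for-band even when the target has sharp peaks or notches. The result
#' is normalized to unit RMS; its absolute level is set downstream when a
#' trial is assembled.
#'
#' @param target a `bild_spectrum` (columns `frequency_hz`, `magnitude_db`).
#' @param duration length in seconds (must be at least 0.5 s so the band
#'   levels can be estimated).
#' @param sample_rate sampling rate in Hz.
#' @param rng_seed integer seed; the same seed gives a bit-identical waveform.
#' @return numeric waveform, unit RMS.
#' @export
shape_noise <- function(target, duration, sample_rate, rng_seed) {
  if (duration < 0.5) stop("duration must be at least 0.5 s", call. = FALSE)
  stopifnot(is.data.frame(target),
            all(c("frequency_hz", "magnitude_db") %in% names(target)))
  n <- round(duration * sample_rate)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)
  x <- rnorm(n)
  bin_f <- pmin(0:(n - 1), n - (0:(n - 1))) * sample_rate / n
  # piecewise-constant band gains; boundaries at geometric midpoints
  fc <- target$frequency_hz
  inner <- sqrt(fc[-length(fc)] * fc[-1])
  idx <- findInterval(bin_f, inner) + 1L
  g <- 10^(target$magnitude_db[idx] / 20)
  y <- Re(fft(fft(x) * g, inverse = TRUE)) / n
  y / rms(y)
}

#' Assemble a binaural trial stimulus
#'
#' Builds the stereo waveform for one trial. The masker is diotic (identical
#' in both channels, M0) and fixed at the reference level; the target is
#' scaled to the commanded SNR and presented either in phase across ears
#' (M0T0) or with the right-channel target inverted (M0Tpi, the antiphasic
#' condition). In quiet the masker amplitude is zero and `snr_db` is read as
#' the target level in dB re the comfortable reference.
#'
#' @param target_word mono waveform of the target word.
#' @param masker mono waveform at least as long as the target.
#' @param condition `"QUIET"`, `"M0T0"` or `"M0TPI"`.
#' @param snr_db target RMS re masker RMS in dB (masked conditions), or dB re
#'   comfortable (quiet).
#' @param sample_rate sampling rate in Hz.
#' @param masker_level_db dB SPL-equivalent mapped to the unit-RMS masker
#'   (bookkeeping only in simulation).
#' @return a `trial_stimulus` list: `left`, `right`, `sample_rate`,
#'   `condition`, `snr_db`, `masker_level_db`.
#' @export
assemble_trial <- function(target_word, masker, condition, snr_db,
                           sample_rate, masker_level_db = 60) {
  check_condition(condition)
  if (length(target_word) == 0) stop("empty target", call. = FALSE)
  if (condition == "QUIET") {
    tgt <- target_word / rms(target_word) * 10^(snr_db / 20)
    left <- tgt
    right <- tgt
  } else {
    if (!is.finite(snr_db)) stop("snr_db must be finite in masked conditions",
                                 call. = FALSE)
    if (length(masker) < length(target_word)) {
      stop("masker shorter than target", call. = FALSE)
    }
    m <- masker[seq_along(target_word)]
    m <- m / rms(m)
    tgt <- target_word / rms(target_word) * 10^(snr_db / 20)
    sgn <- if (condition == "M0TPI") -1 else 1
    left <- m + tgt
    right <- m + sgn * tgt
  }
  structure(list(left = left, right = right, sample_rate = sample_rate,
                 condition = condition, snr_db = snr_db,
                 masker_level_db = masker_level_db),
            class = "trial_stimulus")
}

#' Synthetic target-word corpus
#'
#' A bundled stand-in for the recorded monosyllabic word corpus: 25 sets of
#' three formant-like harmonic complexes from a female-range fundamental
#' (~200 Hz), each word in a set sharing its envelope shape but differing in
#' first/second formant placement, mimicking vowel contrasts. A low-level
#' broadband component (consonant frication and breath noise, ~18 dB below
#' the voiced part) keeps the long-term spectrum speech-like rather than a
#' bare harmonic comb. Synthetic only; it makes the stimulus chain testable,
#' it does not reproduce the original recordings.
#'
#' @param n_sets number of word sets (default 25).
#' @param words_per_set words per set (default 3).
#' @param sample_rate sampling rate in Hz.
#' @param duration_s word duration in seconds.
#' @param seed integer seed.
#' @return list with `waveforms` (list of mono waves), `set`, `word` index
#'   vectors, and `sample_rate`.
#' @export
synth_word_corpus <- function(n_sets = 25, words_per_set = 3,
                              sample_rate = 16000, duration_s = 0.5,
                              seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- round(duration_s * sample_rate)
  t <- seq_len(n) / sample_rate
  ramp <- pmin(1, t / 0.05, rev(t) / 0.05)  # 50 ms raised ramps
  waves <- list(); set_idx <- integer(0); word_idx <- integer(0)
  for (s in seq_len(n_sets)) {
    f0 <- runif(1, 180, 230)
    for (w in seq_len(words_per_set)) {
      # vowel-like formant placement, varied across words within a set
      f1 <- runif(1, 300, 900)
      f2 <- runif(1, max(f1 + 300, 900), 2500)
      f3 <- runif(1, 2500, 3400)
      # declining f0 contour (+10% to -10% across the word), as in natural
      # prosody; harmonics sweep rather than sit on a fixed comb
      f0_t <- f0 * (1.1 - 0.2 * t / duration_s)
      phase0 <- 2 * pi * cumsum(f0_t) / sample_rate
      n_harm <- floor(min(5000, sample_rate / 2 - 100) / (1.1 * f0))
      harm <- f0 * seq_len(n_harm)
      amp <- exp(-((log(harm / f1))^2) / 0.08) +
        0.6 * exp(-((log(harm / f2))^2) / 0.05) +
        0.3 * exp(-((log(harm / f3))^2) / 0.04)
      ph <- runif(n_harm, 0, 2 * pi)
      x <- numeric(n)
      for (k in seq_len(n_harm)) x <- x + amp[k] * sin(k * phase0 + ph[k])
      x <- x / rms(x)
      x <- (x + 10^(-18 / 20) * rnorm(n)) * ramp  # frication / breath floor
      waves[[length(waves) + 1]] <- x / rms(x)
      set_idx <- c(set_idx, s); word_idx <- c(word_idx, w)
    }
  }
  list(waveforms = waves, set = set_idx, word = word_idx,
       sample_rate = sample_rate)
}

#' @export
print.bild_spectrum <- function(x, ...) {
  cat("<bild_spectrum> ", nrow(x), " ", attr(x, "band_resolution"),
      " bands, ", round(min(x$frequency_hz)), "-",
      round(max(x$frequency_hz)), " Hz\n", sep = "")
  NextMethod()
}

#' Write / read a spectrum as two-column CSV
#'
#' @param spectrum a `bild_spectrum`.
#' @param path file path.
#' @return `read_spectrum_csv` returns a `bild_spectrum`.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum)[, c("frequency_hz", "magnitude_db")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @param band_resolution resolution descriptor to attach on read.
#' @export
read_spectrum_csv <- function(path, band_resolution = "third-octave") {
  df <- utils::read.csv(path)
  out <- tibble::as_tibble(df[, c("frequency_hz", "magnitude_db")])
  structure(out, band_resolution = band_resolution,
            class = c("bild_spectrum", class(out)))
}
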