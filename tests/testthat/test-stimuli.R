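test_that("LTAS of white noise is flat and a pure tone peaks in its band", {
  fs <- 16000
  set.seed(42)
  spec <- compute_ltas(rnorm(60 * fs), fs)
  expect_s3_class(spec, "bild_spectrum")
  expect_true(all(diff(spec$frequency_hz) > 0))
  expect_gte(nrow(spec), 10)
  dev <- spec$magnitude_db - mean(spec$magnitude_db)
  expect_lt(max(abs(dev)), 1.5)

  tone <- sin(2 * pi * 1000 * seq_len(10 * fs) / fs)
  spec_t <- compute_ltas(tone, fs)
  peak_band <- which.min(abs(log(spec_t$frequency_hz / 1000)))
  octave_away <- which(abs(log2(spec_t$frequency_hz / 1000)) >= 1)
  expect_true(all(spec_t$magnitude_db[peak_band] -
                    spec_t$magnitude_db[octave_away] >= 30))
})

test_that("LTAS rejects empty and silent corpora", {
  expect_error(compute_ltas(list(), 16000), "empty")
  expect_error(compute_ltas(numeric(0), 16000), "empty")
  expect_error(compute_ltas(rep(0, 16000), 16000), "silent")
})

test_that("noise shaping round-trips the target spectrum within 2 dB", {
  fs <- 16000
  corpus <- synth_word_corpus(n_sets = 6, sample_rate = fs, seed = 5)
  target <- compute_ltas(corpus$waveforms, fs)
  noise <- shape_noise(target, duration = 6, sample_rate = fs, rng_seed = 9)
  expect_equal(rms(noise), 1, tolerance = 1e-10)
  measured <- compute_ltas(noise, fs)
  in_range <- target$frequency_hz >= 200 & target$frequency_hz <= 8000
  err <- measured$magnitude_db[in_range] - target$magnitude_db[in_range]
  # shaping fixes relative band levels; compare shapes net of overall offset
  expect_lt(max(abs(err - mean(err))), 2)
})

test_that("shaping a flat target leaves the noise white", {
  fs <- 16000
  flat <- compute_ltas(rnorm(30 * fs), fs)
  flat$magnitude_db[] <- mean(flat$magnitude_db)
  noise <- shape_noise(flat, 6, fs, rng_seed = 2)
  m <- compute_ltas(noise, fs)
  expect_lt(max(abs(m$magnitude_db - mean(m$magnitude_db))), 2)
})

test_that("noise shaping is bit-reproducible under a fixed seed", {
  fs <- 16000
  set.seed(123)
  target <- compute_ltas(rnorm(fs), fs)
  expect_identical(shape_noise(target, 1, fs, rng_seed = 7),
                   shape_noise(target, 1, fs, rng_seed = 7))
  expect_error(shape_noise(target, 0.2, fs, rng_seed = 7), "0.5")
})

test_that("assembled trials honour the SNR, phase and quiet contracts", {
  fs <- 16000
  set.seed(8)
  word <- synth_word_corpus(n_sets = 1, sample_rate = fs, duration_s = 1,
                            seed = 3)$waveforms[[1]]
  masker <- shape_noise(compute_ltas(word, fs), 2, fs, rng_seed = 1)

  tr <- assemble_trial(word, masker, "M0TPI", -10, fs)
  expect_equal(length(tr$left), length(tr$right))
  # antiphasic: target component in the right channel is the sample-wise
  # negation of the left one, so L - R isolates twice the target
  tgt <- (tr$left - tr$right) / 2
  msk <- (tr$left + tr$right) / 2
  expect_equal(rms(tgt) / rms(msk), 10^(-10 / 20), tolerance = 1e-6)
  # commanded SNR recovered within 0.1 dB
  expect_lt(abs(20 * log10(rms(tgt) / rms(msk)) - (-10)), 0.1)
  # target RMS at snr -10 with unit-RMS masker
  expect_equal(rms(tgt), 0.3162278, tolerance = 1e-4)
  # the difference channel holds no masker energy: its correlation with the
  # masker is zero in expectation (averaged over masker realizations, since
  # a single finite-sample r between colored signals scatters a few percent)
  spec_w <- compute_ltas(word, fs)
  rs <- purrr::map_dbl(1:24, function(sd) {
    m <- shape_noise(spec_w, 2, fs, rng_seed = sd)
    tri <- assemble_trial(word, m, "M0TPI", -10, fs)
    cor((tri$left - tri$right) / 2, (tri$left + tri$right) / 2)
  })
  expect_lt(abs(mean(rs)), 0.01)

  t0 <- assemble_trial(word, masker, "M0T0", -10, fs)
  expect_identical(t0$left, t0$right)

  q <- assemble_trial(word, masker, "QUIET", -30, fs)
  expect_identical(q$left, q$right)
  expect_equal(rms(q$left), 10^(-30 / 20), tolerance = 1e-10)

  expect_error(assemble_trial(word, masker, "M0T0", NaN, fs), "finite")
  expect_error(assemble_trial(word, masker[1:10], "M0T0", -5, fs), "shorter")
  expect_error(assemble_trial(word, masker, "M0T5", -5, fs), "condition")
})

test_that("the synthetic corpus has the advertised structure", {
  corp <- synth_word_corpus(n_sets = 4, seed = 11)
  expect_length(corp$waveforms, 12)
  expect_equal(as.integer(table(corp$set)), rep(3L, 4))
  expect_true(all(purrr::map_dbl(corp$waveforms, rms) - 1 < 1e-9))
})

test_that("spectrum CSV and WAV files round-trip", {
  fs <- 16000
  set.seed(21)
  spec <- compute_ltas(rnorm(2 * fs), fs)
  f <- tempfile(fileext = ".csv")
  write_spectrum_csv(spec, f)
  back <- read_spectrum_csv(f)
  expect_equal(back$frequency_hz, spec$frequency_hz, tolerance = 1e-8)
  expect_equal(back$magnitude_db, spec$magnitude_db, tolerance = 1e-8)

  x <- cbind(sin(2 * pi * 440 * seq_len(fs) / fs) * 0.5,
             sin(2 * pi * 880 * seq_len(fs) / fs) * 0.25)
  for (bits in c(16, 24, 32)) {
    w <- tempfile(fileext = ".wav")
    write_wav(x, fs, w, bits = bits)
    back <- read_wav(w)
    expect_equal(back$sample_rate, fs)
    expect_equal(dim(back$samples), dim(x))
    expect_equal(back$samples, x,
                 tolerance = if (bits == 32) 1e-7 else 2^-(bits - 2))
  }
})
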