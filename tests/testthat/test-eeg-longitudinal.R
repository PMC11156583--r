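test_that("Morlet power localizes a pure tone to its frequency", {
  fs <- 128
  t <- seq(0, 12, by = 1 / fs)
  P <- morlet_power(sin(2 * pi * 10 * t), fs)
  fr <- attr(P, "freqs_hz")
  mid <- seq(4 * fs, 8 * fs)  # away from edge effects
  peak_freqs <- fr[apply(P[mid, ], 1, which.max)]
  # within one log-spaced bin of 10 Hz
  bin_ratio <- fr[2] / fr[1]
  expect_true(all(peak_freqs / 10 < bin_ratio & 10 / peak_freqs < bin_ratio))
  expect_true(all(P >= 0))
})

test_that("an all-zero trace has all-zero power", {
  expect_equal(max(morlet_power(numeric(1300), 128)), 0)
})

test_that("Morlet parameters are validated", {
  expect_error(morlet_power(rnorm(1300), 128,
                            morlet_params(freq_hi_hz = 80)), "Nyquist")
  expect_error(morlet_power(rnorm(200), 128), "longest wavelet")
  expect_error(morlet_params(n_cycles = 2), "n_cycles")
  expect_error(morlet_params(freq_lo_hz = 50, freq_hi_hz = 10), "freq_lo")
})

test_that("chirp ridge agrees with the short-time-FFT oracle", {
  fs <- 128
  t <- seq(0, 20, by = 1 / fs)
  chirp <- sin(2 * pi * (5 * t + (40 - 5) / (2 * 20) * t^2))
  P <- morlet_power(chirp, fs)
  fr <- attr(P, "freqs_hz")
  ridge_m <- fr[apply(P, 1, which.max)]
  sg <- signal::specgram(chirp, n = 256, Fs = fs, overlap = 192)
  ridge_stft <- sg$f[apply(Mod(sg$S)^2, 2, which.max)]
  ridge_m_at <- approx(t, ridge_m, sg$t)$y
  expect_gt(cor(ridge_m_at, ridge_stft), 0.95)
  # ridge increases monotonically through the sweep (small jitter allowed)
  core <- ridge_m[(2 * fs):(18 * fs)]
  expect_gt(mean(diff(core) >= 0), 0.95)
})

test_that("injected ictal bursts are detected with Jaccard >= 0.5", {
  fs <- 128
  sim <- gen_eeg_trace(seed = 5, fs_hz = fs, duration_s = 5400,
                       event_times_s = c(400, 1500, 2800, 4400),
                       ictal_dur_s = 15, ictal_gain = 8,
                       band_hz = c(0.5, 50))
  sz <- detect_seizures(sim$trace, fs)
  expect_equal(nrow(sz), 4)
  for (i in 1:4) {
    expect_gte(interval_jaccard(sim$events$t_onset_s[i],
                                sim$events$t_offset_s[i],
                                sz$t_onset_s[i], sz$t_offset_s[i]), 0.5)
  }
})

test_that("baseline-only traces yield no events; brief lulls merge", {
  fs <- 128
  base <- gen_eeg_trace(seed = 9, fs_hz = fs, duration_s = 900,
                        event_times_s = numeric(0), band_hz = c(0.5, 50))
  expect_equal(nrow(detect_seizures(base$trace, fs)), 0)
  # one burst interrupted by a brief lull -> a single merged event
  # (each 8 s half alone would fall below the 10 s duration gate, so the
  # test fails unless the merge rule joins them)
  lull <- gen_eeg_trace(seed = 10, fs_hz = fs, duration_s = 1800,
                        event_times_s = c(600, 610), ictal_dur_s = 8,
                        ictal_gain = 8, band_hz = c(0.5, 50))
  sz <- detect_seizures(lull$trace, fs)
  expect_equal(nrow(sz), 1)
  expect_lt(abs(sz$t_onset_s - 600), 5)
  expect_lt(abs(sz$t_offset_s - 618), 5)
  # constant trace -> empty result; too-short trace -> error
  expect_equal(nrow(detect_seizures(rep(1, 60 * fs), fs)), 0)
  expect_error(detect_seizures(rnorm(5 * fs), fs), "shorter")
})

test_that("seizure detector is calibrated across seeds", {
  fs <- 128
  tp <- fp <- fn <- 0L
  for (seed in 1:20) {
    t0 <- 200 + 25 * seed
    sim <- gen_eeg_trace(seed = seed, fs_hz = fs, duration_s = 900,
                         event_times_s = t0, ictal_dur_s = 15,
                         ictal_gain = 8, band_hz = c(0.5, 50))
    sz <- detect_seizures(sim$trace, fs)
    hit <- nrow(sz) > 0 &&
      any(abs((sz$t_onset_s + sz$t_offset_s) / 2 - (t0 + 7.5)) < 10)
    tp <- tp + hit
    fn <- fn + !hit
    fp <- fp + nrow(sz) - hit
  }
  expect_gte(tp / (tp + fn), 0.9)
  expect_gte(tp / (tp + fp), 0.9)
})

test_that("daily frequency normalizes sessions to 24 h", {
  sess <- data.frame(animal = c(1, 1, 2),
                     hours_recorded = c(72, 24, 24),
                     n_seizures = c(6, 0, 4))
  df <- daily_frequency(sess)
  expect_equal(df$sessions$daily_frequency, c(2, 0, 4))
  a1 <- df$by_animal[df$by_animal$animal == 1, ]
  expect_equal(a1$mean, 1)
  expect_equal(a1$n, 2)
  # [2, 4] per day -> mean 3
  two <- daily_frequency(data.frame(animal = 1, hours_recorded = c(24, 24),
                                    n_seizures = c(2, 4)))
  expect_equal(two$by_animal$mean, 3)
  expect_error(daily_frequency(data.frame(animal = 1, hours_recorded = 0,
                                          n_seizures = 1)), "positive")
  expect_error(daily_frequency(data.frame(x = 1)), "columns")
})

test_that("phase comparison reproduces the exact enumeration p-values", {
  # identical lists -> symmetric null, p = 1
  same <- compare_phases(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_true(all(same$tests$p_two_sided == 1))
  # complete separation of pre vs post at n = 4 -> exact 2/70
  cp <- compare_phases(c(3, 4, 5, 6), c(1.5, 1.6, 1.7, 1.8),
                       c(0, 0.1, 0.2, 0.3))
  p <- cp$tests$p_two_sided[cp$tests$comparison == "pre vs post"]
  expect_equal(p, 2 / 70)
  # seizure freedom flags
  free <- compare_phases(c(3, 4, 5, 6, 2, 7), c(1, 1, 2, 2, 1, 3),
                         rep(0, 6))
  flags <- free$seizure_free
  expect_true(all(flags$seizure_free[flags$phase == "post"]))
  expect_false(any(flags$seizure_free[flags$phase == "pre"]))
  expect_error(compare_phases(1, c(1, 2), c(1, 2)), "at least 2")
})

test_that("per-phase summaries are self-consistent", {
  cp <- compare_phases(c(3, 4, 5, 6), c(1, 2, 2, 4), c(0, 1, 0, 2))
  for (i in seq_len(nrow(cp$stats))) {
    s <- cp$stats[i, ]
    expect_equal(s$sem * sqrt(s$n), s$sd, tolerance = 1e-12)
  }
})
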