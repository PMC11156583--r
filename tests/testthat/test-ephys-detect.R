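test_that("band-pass filter matches the frequency-response oracle", {
  fs <- 10000
  t <- seq(0, 5, by = 1 / fs)
  # in-band tone passes with < 5% amplitude error
  y10 <- bandpass_filter(sin(2 * pi * 10 * t), fs, 1, 40)
  mid <- (length(t) %/% 4):(3 * length(t) %/% 4)
  expect_lt(abs(max(abs(y10[mid])) - 1), 0.05)
  # out-of-band tone is strongly attenuated
  x300 <- sin(2 * pi * 300 * t)
  y300 <- bandpass_filter(x300, fs, 1, 40)
  expect_lt(sqrt(mean(y300[mid]^2)) / sqrt(mean(x300[mid]^2)), 0.10)
  # linearity: zero in, zero out
  expect_equal(bandpass_filter(numeric(1000), fs, 1, 40), numeric(1000))
  # degenerate bands rejected
  expect_error(bandpass_filter(t, fs, 40, 1), "band")
  expect_error(bandpass_filter(t, fs, -5, 40), "band")
  expect_error(bandpass_filter(t, fs, 100, 6000), "band")
})

test_that("normalized squared signal has mean 0 and SD 1", {
  set.seed(3)
  z <- power_normalize(rnorm(50000))
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sd(z) - 1), 1e-6)
  expect_true(all(is.na(power_normalize(rep(2, 100)))))
})

test_that("injected IILDs are recovered with <= 20 ms peak error", {
  cfg <- small_mea_cfg(seed = 11, duration_s = 90, iild_rate_per_min = 2)
  sim <- gen_mea_recording(cfg)
  gt <- sim$ground_truth
  expect_gt(length(gt$network_times_s), 0)
  for (ch in cfg$core_electrodes) {
    tt <- gt$events$t_s[gt$events$channel == ch & gt$events$kind == "IILD"]
    ev <- detect_iilds(sim$recording$traces[ch, ], cfg$fs_hz, channel = ch)
    expect_equal(nrow(ev), length(tt))
    expect_true(all(ev$kind == "IILD"))
    # events sorted by onset, half-open and threshold-consistent
    expect_true(all(diff(ev$t_onset_s) >= 0))
    expect_true(all(ev$t_onset_s <= ev$t_peak_s & ev$t_peak_s < ev$t_offset_s))
    for (t0 in tt) expect_lt(min(abs(ev$t_peak_s - t0)), 0.020)
  }
})

test_that("degenerate traces yield no IILD events or clean errors", {
  fs <- 10000
  expect_equal(nrow(detect_iilds(numeric(2 * fs), fs)), 0)
  expect_equal(nrow(detect_iilds(rep(3.3, 2 * fs), fs)), 0)
  expect_error(detect_iilds(numeric(100), fs), "1 s")
  expect_error(detect_mua(numeric(100), fs), "1 s")
})

test_that("noise-only traces produce at most one spurious IILD per minute", {
  fs <- 10000
  spurious <- integer(20)
  for (seed in 1:20) {
    set.seed(seed + 400)
    spurious[seed] <- nrow(detect_iilds(rnorm(60 * fs, 0, 10), fs))
  }
  expect_true(all(spurious <= 1))
  expect_lte(mean(spurious), 0.25)
})

test_that("spikes at known times are recovered within 1 ms", {
  fs <- 10000
  set.seed(21)
  x <- rnorm(60 * fs, 0, 10)
  spike <- epimosaic:::spike_waveform(fs, 1, 75)
  half <- length(spike) %/% 2
  # 50 well-separated spike times (jittered 1.1 s grid)
  true_t <- seq(1, by = 1.1, length.out = 50) + runif(50, 0, 0.5)
  for (t0 in true_t) {
    x <- epimosaic:::add_at(x, round(t0 * fs) - half + 1L, spike)
  }
  ev <- detect_mua(x, fs)
  expect_equal(nrow(ev), 50)
  for (t0 in true_t) expect_lt(min(abs(ev$t_peak_s - t0)), 0.001)
})

test_that("crossings within the refractory window collapse to one spike", {
  fs <- 10000
  set.seed(5)
  x <- rnorm(2 * fs, 0, 10)
  spike <- epimosaic:::spike_waveform(fs, 0.3, 80)
  # two threshold crossings 0.5 ms apart
  x <- epimosaic:::add_at(x, round(1.0 * fs), spike)
  x <- epimosaic:::add_at(x, round(1.0005 * fs), spike)
  ev <- detect_mua(x, fs)
  expect_equal(nrow(ev), 1)
})

test_that("event classification separates discharges from spikes", {
  cfg <- small_mea_cfg(seed = 13, duration_s = 60)
  sim <- gen_mea_recording(cfg)
  det <- detect_recording(sim$recording)
  agree <- 0L; tot <- 0L
  for (i in seq_len(nrow(det$events))) {
    ev <- det$events[i, ]
    cl <- classify_event(sim$recording$traces[ev$channel, ], cfg$fs_hz, ev)
    tot <- tot + 1L
    agree <- agree + (cl$kind == ev$kind)
    expect_true(all(cl$spectrogram$S >= 0))
  }
  expect_gte(agree / tot, 0.95)

  # a pure slow burst with no ripple is an IILD (slow fraction 1)
  fs <- 10000
  t <- seq(0, 1, by = 1 / fs)
  x <- sin(2 * pi * 10 * t) * exp(-(t - 0.5)^2 / 0.01)
  ev <- data.frame(t_onset_s = 0.35, t_peak_s = 0.5, t_offset_s = 0.65)
  cl <- classify_event(x, fs, ev)
  expect_equal(cl$kind, "IILD")
  expect_gt(cl$slow_fraction, 0.99)
  expect_error(classify_event(x, fs, data.frame(t_onset_s = 2, t_peak_s = 2,
                                                t_offset_s = 2)),
               "window")
})

test_that("electrode classification follows the count rules", {
  mk <- function(n) if (n == 0) NULL else data.frame(idx = seq_len(n))
  a <- summarize_electrode(mk(0), mk(30), 60)
  expect_equal(a$mua_rate_hz, 0.5)
  expect_equal(a$cls, "MUA_ONLY")
  expect_equal(summarize_electrode(mk(3), mk(30), 60)$cls, "IILD_MUA")
  s <- summarize_electrode(mk(0), mk(0), 60)
  expect_equal(s$cls, "SILENT")
  expect_equal(s$mua_rate_hz, 0)
  expect_equal(summarize_electrode(mk(0), mk(5), 60)$cls, "SILENT")
  expect_equal(summarize_electrode(mk(5), mk(50), 60,
                                   defective = TRUE)$cls, "DEFECTIVE")
  expect_error(summarize_electrode(NULL, NULL, -1), "positive")
})

test_that("synchronous IILDs on adjacent channels group into network events", {
  lay <- small_layout()
  ev <- function(ch, tp) {
    data.frame(channel = ch, t_peak_s = tp, kind = "IILD")
  }
  # 20 ms apart on adjacent channels 7 and 8 -> one network event of size 2
  g <- group_network_iilds(rbind(ev(7, 1.00), ev(8, 1.02)), lay)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_channels, 2)
  expect_equal(g$t_consensus_s, 1.01)
  # 500 ms apart on the same channel -> two network events
  g2 <- group_network_iilds(rbind(ev(7, 1.0), ev(7, 1.5)), lay)
  expect_equal(nrow(g2), 2)
  # non-adjacent channels never group (channels 1 and 20 are far apart)
  g3 <- group_network_iilds(rbind(ev(1, 1.0), ev(20, 1.01)), lay)
  expect_equal(nrow(g3), 2)
  # empty input -> empty output
  expect_equal(nrow(group_network_iilds(ev(1, 1)[0, ], lay)), 0)
  expect_error(group_network_iilds(ev(999, 1.0), lay), "channel")
  expect_error(group_network_iilds(
    data.frame(channel = 1, t_peak_s = 1, kind = "MUA_SPIKE"), lay), "IILD")
})

test_that("full recordings group network IILDs across the core", {
  cfg <- small_mea_cfg(seed = 3, duration_s = 120)
  sim <- gen_mea_recording(cfg)
  det <- detect_recording(sim$recording)
  il <- det$events[det$events$kind == "IILD", ]
  net <- group_network_iilds(il, cfg$layout)
  expect_equal(nrow(net), length(sim$ground_truth$network_times_s))
  expect_true(all(net$n_channels == length(cfg$core_electrodes)))
})
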