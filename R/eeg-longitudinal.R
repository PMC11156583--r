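#' Morlet wavelet parameters
#'
#' @param freq_lo_hz,freq_hi_hz frequency band, Hz (`0 < lo < hi`).
#' @param n_freqs number of log-spaced frequencies.
#' @param n_cycles wavelet width in cycles (>= 3).
#' @return an object of class `morlet_params`.
#' @export
morlet_params <- function(freq_lo_hz = 1, freq_hi_hz = 50, n_freqs = 50L,
                          n_cycles = 7) {
  chk_num(freq_lo_hz, "freq_lo_hz", lo = 1e-9)
  chk_num(freq_hi_hz, "freq_hi_hz", lo = 1e-9)
  chk_num(n_freqs, "n_freqs", lo = 1)
  chk_num(n_cycles, "n_cycles", lo = 3)
  if (freq_lo_hz >= freq_hi_hz) stop_input("need freq_lo < freq_hi")
  structure(list(freq_lo_hz = freq_lo_hz, freq_hi_hz = freq_hi_hz,
                 n_freqs = as.integer(n_freqs), n_cycles = n_cycles),
            class = "morlet_params")
}

morlet_freqs <- function(mp) {
  exp(seq(log(mp$freq_lo_hz), log(mp$freq_hi_hz),
          length.out = mp$n_freqs))
}

# Complex Morlet kernel at frequency f, L2-normalized, odd length.
morlet_kernel <- function(f, fs_hz, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f)
  h <- ceiling(4 * sigma_t * fs_hz)
  t <- (-h:h) / fs_hz
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

# FFT convolution of a real trace with a complex kernel, same-length output
# aligned to the trace samples.
conv_complex <- function(x, w) {
  n <- length(x); m <- length(w); h <- (m - 1L) %/% 2L
  n2 <- stats::nextn(n + m - 1L, 2)
  y <- stats::fft(stats::fft(c(x, rep(0, n2 - n))) *
                    stats::fft(c(w, rep(0, n2 - m))), inverse = TRUE) / n2
  y[(h + 1L):(h + n)]
}

#' Morlet wavelet time-frequency power
#'
#' Convolves the trace with L2-normalized complex Morlet wavelets at
#' log-spaced frequencies and returns squared magnitudes.
#'
#' @param x numeric trace.
#' @param fs_hz sampling rate, Hz.
#' @param params a [morlet_params()]; the band must stay below Nyquist.
#' @return time-by-frequency non-negative power matrix with attribute
#'   `freqs_hz`.
#' @export
morlet_power <- function(x, fs_hz, params = morlet_params()) {
  stopifnot(inherits(params, "morlet_params"))
  if (params$freq_hi_hz >= fs_hz / 2) {
    stop_input("frequency band exceeds Nyquist")
  }
  freqs <- morlet_freqs(params)
  longest <- 2L * ceiling(4 * params$n_cycles /
                            (2 * pi * freqs[1]) * fs_hz) + 1L
  if (length(x) <= longest) {
    stop_input("trace shorter than the longest wavelet")
  }
  P <- matrix(0, nrow = length(x), ncol = length(freqs))
  for (k in seq_along(freqs)) {
    P[, k] <- Mod(conv_complex(x, morlet_kernel(freqs[k], fs_hz,
                                                params$n_cycles)))^2
  }
  attr(P, "freqs_hz") <- freqs
  P
}

# Total band power per time bin, accumulated frequency by frequency to
# bound memory on long traces.
band_power_bins <- function(x, fs_hz, mp, bin_s) {
  spb <- round(bin_s * fs_hz)
  n_bins <- length(x) %/% spb
  if (n_bins < 1L) stop_input("trace shorter than one bin")
  freqs <- morlet_freqs(mp)
  acc <- numeric(n_bins)
  for (f in freqs) {
    p <- Mod(conv_complex(x, morlet_kernel(f, fs_hz, mp$n_cycles)))^2
    acc <- acc + colMeans(matrix(p[seq_len(n_bins * spb)], nrow = spb))
  }
  acc
}

#' Seizure detection parameters
#'
#' @param bin_s power integration bin, seconds.
#' @param power_threshold_sd detection threshold in SD of the binned band
#'   power (z-scored over the recording).
#' @param min_dur_s minimum event duration, seconds.
#' @param merge_gap_s events separated by less than this merge into one.
#' @return an object of class `seizure_detect_params`.
#' @export
seizure_detect_params <- function(bin_s = 1, power_threshold_sd = 6,
                                  min_dur_s = 10, merge_gap_s = 5) {
  chk_num(bin_s, "bin_s", lo = 1e-9)
  chk_num(power_threshold_sd, "power_threshold_sd", lo = 1e-9)
  chk_num(min_dur_s, "min_dur_s", lo = 1e-9)
  chk_num(merge_gap_s, "merge_gap_s", lo = 1e-9)
  structure(list(bin_s = bin_s, power_threshold_sd = power_threshold_sd,
                 min_dur_s = min_dur_s, merge_gap_s = merge_gap_s),
            class = "seizure_detect_params")
}

#' Detect ictal events on an EEG trace
#'
#' Total Morlet band power per time bin -> z-score over the recording ->
#' supra-threshold runs -> merge runs separated by less than
#' `merge_gap_s` -> keep runs lasting at least `min_dur_s`. The procedure
#' automates a semi-automatic ictal-screening workflow; the returned
#' candidate windows can be exported for visual review.
#'
#' @param x numeric EEG trace.
#' @param fs_hz sampling rate, Hz.
#' @param mp a [morlet_params()].
#' @param sp a [seizure_detect_params()].
#' @return data.frame of ictal events: `t_onset_s`, `t_offset_s`,
#'   `duration_s`, `peak_z`.
#' @export
detect_seizures <- function(x, fs_hz, mp = morlet_params(),
                            sp = seizure_detect_params()) {
  if (length(x) < sp$min_dur_s * fs_hz) {
    stop_input("trace shorter than the minimum event duration")
  }
  pb <- band_power_bins(x, fs_hz, mp, sp$bin_s)
  sdv <- stats::sd(pb)
  empty <- data.frame(t_onset_s = numeric(0), t_offset_s = numeric(0),
                      duration_s = numeric(0), peak_z = numeric(0))
  if (!is.finite(sdv) || sdv == 0) return(empty)
  z <- (pb - mean(pb)) / sdv
  runs <- true_runs(z >= sp$power_threshold_sd)
  if (nrow(runs) == 0L) return(empty)
  gap_bins <- ceiling(sp$merge_gap_s / sp$bin_s) - 1L
  runs <- merge_runs(runs, max(0L, gap_bins))
  dur <- (runs[, "end"] - runs[, "start"] + 1L) * sp$bin_s
  keep <- dur >= sp$min_dur_s
  if (!any(keep)) return(empty)
  runs <- runs[keep, , drop = FALSE]
  data.frame(
    t_onset_s = (runs[, "start"] - 1L) * sp$bin_s,
    t_offset_s = runs[, "end"] * sp$bin_s,
    duration_s = (runs[, "end"] - runs[, "start"] + 1L) * sp$bin_s,
    peak_z = vapply(seq_len(nrow(runs)), function(i) {
      max(z[runs[i, "start"]:runs[i, "end"]])
    }, numeric(1)))
}

#' Per-session daily seizure frequency and per-animal summaries
#'
#' Normalizes each recording session to a 24 h seizure frequency
#' (`n_seizures / hours_recorded x 24`) and summarizes each animal across
#' its sessions with [summary_stats()].
#'
#' @param sessions data.frame with columns `animal`, `hours_recorded`,
#'   `n_seizures` and optionally `phase`.
#' @return list with `sessions` (input plus `daily_frequency`) and
#'   `by_animal` (one [summary_stats()] row per animal).
#' @export
daily_frequency <- function(sessions) {
  req <- c("animal", "hours_recorded", "n_seizures")
  if (!is.data.frame(sessions) || !all(req %in% names(sessions))) {
    stop_input("`sessions` needs columns animal, hours_recorded, n_seizures")
  }
  if (any(sessions$hours_recorded <= 0)) {
    stop_input("every session must have positive recorded hours")
  }
  sessions$daily_frequency <-
    sessions$n_seizures / sessions$hours_recorded * 24
  animals <- unique(sessions$animal)
  by_animal <- do.call(rbind, lapply(animals, function(a) {
    st <- summary_stats(sessions$daily_frequency[sessions$animal == a])
    cbind(data.frame(animal = a), st)
  }))
  rownames(by_animal) <- NULL
  list(sessions = sessions, by_animal = by_animal)
}

#' Compare treatment phases of a longitudinal seizure study
#'
#' Pairwise two-tailed exact Mann-Whitney tests between the per-animal
#' daily seizure frequencies of the pre-treatment, end-of-treatment and
#' post-treatment phases, per-phase descriptive statistics, and a
#' seizure-freedom flag per animal and phase.
#'
#' @param freq_pre,freq_end,freq_post numeric vectors of per-animal mean
#'   daily frequencies (>= 2 animals per phase; name elements by animal to
#'   propagate ids).
#' @return an object of class `phase_comparison`: list with `stats`
#'   (per-phase [summary_stats()]), `tests` (pairwise U and p), and
#'   `seizure_free` (animal x phase logical table).
#' @export
compare_phases <- function(freq_pre, freq_end, freq_post) {
  phases <- list(pre = freq_pre, end = freq_end, post = freq_post)
  for (ph in names(phases)) {
    if (!is.numeric(phases[[ph]]) || length(phases[[ph]]) < 2L) {
      stop_input(sprintf("phase `%s` needs at least 2 values", ph))
    }
  }
  stats_tab <- do.call(rbind, lapply(names(phases), function(ph) {
    cbind(data.frame(phase = ph), summary_stats(phases[[ph]]))
  }))
  pairs <- utils::combn(names(phases), 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- phases[[pairs[1, j]]]; b <- phases[[pairs[2, j]]]
    mw <- mann_whitney_exact(a, b)
    data.frame(comparison = paste(pairs[1, j], "vs", pairs[2, j]),
               u_statistic = mw$u_statistic, p_two_sided = mw$p_two_sided,
               method = mw$method)
  }))
  sf <- do.call(rbind, lapply(names(phases), function(ph) {
    v <- phases[[ph]]
    ids <- names(v) %||% as.character(seq_along(v))
    data.frame(animal = ids, phase = ph, seizure_free = v == 0)
  }))
  rownames(stats_tab) <- rownames(tests) <- rownames(sf) <- NULL
  structure(list(stats = stats_tab, tests = tests, seizure_free = sf),
            class = "phase_comparison")
}

#' @export
print.phase_comparison <- function(x, ...) {
  cat("Phase comparison (daily seizure frequency)\n")
  print(x$stats, row.names = FALSE)
  print(x$tests, row.names = FALSE)
  invisible(x)
}
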