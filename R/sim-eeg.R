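#' Configuration for a synthetic longitudinal EEG seizure study
#'
#' Emulates a longitudinal senolytic-treatment design: each animal is
#' recorded daily across ordered phases (baseline, treatment, end-of-
#' treatment, post-treatment follow-up), with Poisson daily seizure counts.
#' From the end of the treatment phase onward the per-animal rate is
#' multiplied by `treatment_multiplier` (0 models complete seizure
#' freedom, 1 no effect).
#'
#' @param seed RNG seed.
#' @param n_animals number of animals.
#' @param fs_hz sampling rate of raw traces, Hz.
#' @param band_hz acquisition band `(low, high)`, Hz.
#' @param session_hours recorded hours per session-day.
#' @param phase_schedule ordered named numeric vector of phase durations in
#'   days, e.g. `c(pre = 14, treat = 9, end = 2, post = 28)`.
#' @param baseline_rate_per_day per-animal Poisson mean (scalar, or vector
#'   of length `n_animals`).
#' @param treatment_multiplier rate multiplier applied from treatment end.
#' @param treatment_phase name of the treatment phase in `phase_schedule`;
#'   phases after it receive the multiplier.
#' @param ictal_dur_s ictal burst duration for raw traces, seconds.
#' @param ictal_gain ictal amplitude multiplier for raw traces.
#' @return an object of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(seed, n_animals = 6L, fs_hz = 2048,
                           band_hz = c(0.5, 70), session_hours = 24,
                           phase_schedule = c(pre = 14, treat = 9,
                                              end = 2, post = 28),
                           baseline_rate_per_day = 3,
                           treatment_multiplier = 0.1,
                           treatment_phase = "treat", ictal_dur_s = 15,
                           ictal_gain = 8) {
  chk_num(seed, "seed"); chk_num(n_animals, "n_animals", lo = 1)
  chk_num(fs_hz, "fs_hz", lo = 1e-9)
  chk_num(treatment_multiplier, "treatment_multiplier", lo = 0)
  chk_num(session_hours, "session_hours", lo = 1e-9)
  if (length(phase_schedule) < 1L || is.null(names(phase_schedule)) ||
      any(phase_schedule <= 0)) {
    stop_input("`phase_schedule` must be a non-empty named vector of days")
  }
  if (!treatment_phase %in% names(phase_schedule)) {
    stop_input("`treatment_phase` must name a phase of the schedule")
  }
  if (!is.numeric(baseline_rate_per_day) || any(baseline_rate_per_day < 0) ||
      !length(baseline_rate_per_day) %in% c(1L, n_animals)) {
    stop_input("`baseline_rate_per_day` must be a non-negative scalar or per-animal vector")
  }
  structure(list(seed = seed, n_animals = as.integer(n_animals),
                 fs_hz = fs_hz, band_hz = band_hz,
                 session_hours = session_hours,
                 phase_schedule = phase_schedule,
                 baseline_rate_per_day = baseline_rate_per_day,
                 treatment_multiplier = treatment_multiplier,
                 treatment_phase = treatment_phase,
                 ictal_dur_s = ictal_dur_s, ictal_gain = ictal_gain),
            class = "eeg_sim_config")
}

#' Generate a synthetic longitudinal EEG seizure study
#'
#' For every animal and study day draws the seizure count from
#' `Poisson(rate x phase multiplier)` and uniform event times within the
#' recorded session. Raw traces are not materialized here (see
#' [gen_eeg_trace()] for a single session trace with injected ictal
#' bursts).
#'
#' @param cfg an [eeg_sim_config()].
#' @return list with `daily` (data.frame: `animal`, `day`, `phase`,
#'   `hours_recorded`, `n_seizures`, `true_rate_per_day`) and `events`
#'   (data.frame: `animal`, `day`, `t_s` within the session).
#' @export
gen_eeg_study <- function(cfg) {
  stopifnot(inherits(cfg, "eeg_sim_config"))
  with_seed(cfg$seed, {
    phases <- names(cfg$phase_schedule)
    days_per <- as.numeric(cfg$phase_schedule)
    phase_of_day <- rep(phases, times = days_per)
    n_days <- length(phase_of_day)
    treat_idx <- match(cfg$treatment_phase, phases)
    mult_of_phase <- ifelse(seq_along(phases) > treat_idx,
                            cfg$treatment_multiplier, 1)
    base <- rep(cfg$baseline_rate_per_day, length.out = cfg$n_animals)

    rows <- vector("list", cfg$n_animals)
    evs <- vector("list", cfg$n_animals)
    for (a in seq_len(cfg$n_animals)) {
      mult <- mult_of_phase[match(phase_of_day, phases)]
      rate <- base[a] * mult
      n_sz <- stats::rpois(n_days, rate)
      rows[[a]] <- data.frame(animal = a, day = seq_len(n_days),
                              phase = phase_of_day,
                              hours_recorded = cfg$session_hours,
                              n_seizures = n_sz,
                              true_rate_per_day = rate)
      if (sum(n_sz) > 0L) {
        evs[[a]] <- data.frame(
          animal = a, day = rep(seq_len(n_days), n_sz),
          t_s = stats::runif(sum(n_sz), 0, cfg$session_hours * 3600))
      }
    }
    daily <- do.call(rbind, rows)
    events <- do.call(rbind, evs)
    if (is.null(events)) {
      events <- data.frame(animal = integer(0), day = integer(0),
                           t_s = numeric(0))
    }
    rownames(daily) <- rownames(events) <- NULL
    list(daily = daily, events = events)
  })
}

#' Generate a raw EEG trace with injected ictal bursts
#'
#' Background activity is band-limited Gaussian noise in the acquisition
#' band; at each requested event time a broadband ictal burst
#' (independent band-limited noise at `ictal_gain` times the background
#' amplitude, with 1 s cosine on/off ramps) is added for `ictal_dur_s`
#' seconds.
#'
#' @param seed RNG seed.
#' @param fs_hz sampling rate, Hz.
#' @param duration_s trace duration, seconds.
#' @param event_times_s ictal onset times, seconds (may be empty).
#' @param ictal_dur_s,ictal_gain burst duration and amplitude multiplier.
#' @param band_hz acquisition band, Hz; upper edge must be below Nyquist.
#' @return list with `trace` (uV-scaled numeric vector), `fs_hz` and
#'   `events` (data.frame `t_onset_s`, `t_offset_s`).
#' @export
gen_eeg_trace <- function(seed, fs_hz = 256, duration_s = 600,
                          event_times_s = numeric(0), ictal_dur_s = 15,
                          ictal_gain = 8, band_hz = c(0.5, 50)) {
  chk_num(fs_hz, "fs_hz", lo = 1e-9)
  chk_num(duration_s, "duration_s", lo = 1e-9)
  if (band_hz[2] >= fs_hz / 2) {
    stop_input("band upper edge must be below Nyquist")
  }
  if (length(event_times_s) &&
      any(event_times_s < 0 | event_times_s + ictal_dur_s > duration_s)) {
    stop_input("ictal events must fall inside the trace")
  }
  with_seed(seed, {
    n <- round(duration_s * fs_hz)
    x <- bandpass_filter(stats::rnorm(n), fs_hz, band_hz[1], band_hz[2])
    bg_sd <- stats::sd(x)
    x <- x / bg_sd * 20  # ~20 uV RMS background
    ramp_n <- round(min(1, ictal_dur_s / 4) * fs_hz)
    m <- round(ictal_dur_s * fs_hz)
    env <- rep(1, m)
    if (ramp_n > 0L) {
      up <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
      env[seq_len(ramp_n)] <- up
      env[(m - ramp_n + 1L):m] <- rev(up)
    }
    for (t0 in event_times_s) {
      burst <- bandpass_filter(stats::rnorm(m + 2L * ramp_n), fs_hz,
                               band_hz[1], band_hz[2])
      burst <- burst[(ramp_n + 1L):(ramp_n + m)]
      burst <- burst / stats::sd(burst) * 20 * ictal_gain * env
      x <- add_at(x, round(t0 * fs_hz) + 1L, burst)
    }
    events <- data.frame(t_onset_s = sort(event_times_s),
                         t_offset_s = sort(event_times_s) + ictal_dur_s)
    list(trace = x, fs_hz = fs_hz, events = events)
  })
}
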