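#' Configuration for synthetic MEA recordings
#'
#' Defines the study conditions of a simulated acute-slice recording: a
#' spatial activity gradient with a core zone bearing both interictal-like
#' discharges (IILDs) and multi-unit activity (MUA), a surround zone with
#' sparse MUA only, and silent electrodes. Default rates follow the
#' recorded contrast between IILD-positive and IILD-negative electrodes
#' (0.74 vs 0.05 Hz) and the default IILD rate is 2 events/min in the core.
#'
#' Waveform amplitudes are free parameters of the generator, fixed at
#' typical extracellular magnitudes: 10 uV noise SD, 75 uV spike peak,
#' 300 uV IILD slow-component peak and 20 uV ripple peak.
#'
#' @param seed RNG seed; all randomness of one generator call flows from it.
#' @param duration_s recording duration, seconds.
#' @param fs_hz sampling rate, Hz; must exceed twice the upper ripple band
#'   edge.
#' @param noise_sd_uv white-noise standard deviation, uV.
#' @param layout an [mea_layout()].
#' @param core_electrodes,surround_electrodes,silent_electrodes disjoint
#'   channel-index sets; by default a 2x2 core block at the grid centre, its
#'   8-neighbourhood ring as surround, and all remaining channels silent.
#' @param mua_rate_core_hz,mua_rate_surround_hz Poisson spike rates, Hz.
#' @param iild_rate_per_min network IILD rate in the core, events/min.
#' @param iild_slow_dur_ms IILD slow-component duration, ms.
#' @param iild_ripple_band_hz ripple frequency band `(low, high)`, Hz.
#' @param spike_width_ms extracellular spike width, ms.
#' @param amp_spike_uv,amp_iild_uv,amp_ripple_uv waveform peak amplitudes, uV.
#' @param iild_jitter_ms uniform network-event jitter across core channels
#'   (+/- this value), ms.
#' @param high_k logical; if `TRUE` the pro-convulsive high-K+ condition is
#'   simulated: all MUA rates are multiplied by `high_k_mua_multiplier`
#'   while IILD placement is unchanged.
#' @param high_k_mua_multiplier MUA rate multiplier of the high-K+ condition.
#' @return an object of class `mea_sim_config`.
#' @export
mea_sim_config <- function(seed, duration_s = 600, fs_hz = 10000,
                           noise_sd_uv = 10, layout = mea_layout(),
                           core_electrodes = NULL, surround_electrodes = NULL,
                           silent_electrodes = NULL,
                           mua_rate_core_hz = 0.74,
                           mua_rate_surround_hz = 0.05,
                           iild_rate_per_min = 2, iild_slow_dur_ms = 300,
                           iild_ripple_band_hz = c(100, 500),
                           spike_width_ms = 1, amp_spike_uv = 75,
                           amp_iild_uv = 300, amp_ripple_uv = 20,
                           iild_jitter_ms = 10, high_k = FALSE,
                           high_k_mua_multiplier = 5) {
  stopifnot(inherits(layout, "mea_layout"))
  chk_num(seed, "seed"); chk_num(duration_s, "duration_s", lo = 1e-9)
  chk_num(fs_hz, "fs_hz", lo = 1e-9)
  chk_num(noise_sd_uv, "noise_sd_uv", lo = 0)
  chk_num(mua_rate_core_hz, "mua_rate_core_hz", lo = 0)
  chk_num(mua_rate_surround_hz, "mua_rate_surround_hz", lo = 0)
  chk_num(iild_rate_per_min, "iild_rate_per_min", lo = 0)
  chk_num(iild_slow_dur_ms, "iild_slow_dur_ms", lo = 1e-9)
  chk_num(iild_ripple_band_hz, "iild_ripple_band_hz", lo = 0, len = 2L)
  chk_num(high_k_mua_multiplier, "high_k_mua_multiplier", lo = 0)
  if (fs_hz <= 2 * iild_ripple_band_hz[2]) {
    stop_input("`fs_hz` must exceed twice the upper ripple band edge")
  }

  if (is.null(core_electrodes) || is.null(surround_electrodes)) {
    z <- default_mea_zones(layout)
    core_electrodes <- core_electrodes %||% z$core
    surround_electrodes <- surround_electrodes %||% z$surround
  }
  core_electrodes <- as.integer(core_electrodes)
  surround_electrodes <- as.integer(surround_electrodes)
  all_ch <- seq_len(layout$n_channels)
  silent_electrodes <- as.integer(silent_electrodes %||%
    setdiff(all_ch, c(core_electrodes, surround_electrodes)))
  zones <- c(core_electrodes, surround_electrodes, silent_electrodes)
  if (anyDuplicated(zones)) {
    stop_input("core/surround/silent electrode sets must be disjoint")
  }
  if (!all(zones %in% all_ch)) {
    stop_input("electrode sets must lie within the layout")
  }

  structure(list(seed = seed, duration_s = duration_s, fs_hz = fs_hz,
                 noise_sd_uv = noise_sd_uv, layout = layout,
                 core_electrodes = core_electrodes,
                 surround_electrodes = surround_electrodes,
                 silent_electrodes = silent_electrodes,
                 mua_rate_core_hz = mua_rate_core_hz,
                 mua_rate_surround_hz = mua_rate_surround_hz,
                 iild_rate_per_min = iild_rate_per_min,
                 iild_slow_dur_ms = iild_slow_dur_ms,
                 iild_ripple_band_hz = iild_ripple_band_hz,
                 spike_width_ms = spike_width_ms,
                 amp_spike_uv = amp_spike_uv, amp_iild_uv = amp_iild_uv,
                 amp_ripple_uv = amp_ripple_uv,
                 iild_jitter_ms = iild_jitter_ms, high_k = high_k,
                 high_k_mua_multiplier = high_k_mua_multiplier),
            class = "mea_sim_config")
}

# Central 2x2 core block plus its 8-neighbourhood ring.
default_mea_zones <- function(layout) {
  pos <- electrode_positions(layout)
  r0 <- max(1L, layout$rows %/% 2)
  c0 <- max(1L, layout$cols %/% 2)
  core_rows <- unique(pmin(c(r0, r0 + 1L), layout$rows))
  core_cols <- unique(pmin(c(c0, c0 + 1L), layout$cols))
  core <- pos$channel[pos$row %in% core_rows & pos$col %in% core_cols]
  ring <- pos$channel[pos$row >= min(core_rows) - 1L &
                        pos$row <= max(core_rows) + 1L &
                        pos$col >= min(core_cols) - 1L &
                        pos$col <= max(core_cols) + 1L]
  list(core = core, surround = setdiff(ring, core))
}

# Per-channel configured MUA rate (Hz), including the high-K+ multiplier.
mea_true_rates <- function(cfg) {
  mult <- if (isTRUE(cfg$high_k)) cfg$high_k_mua_multiplier else 1
  rate <- numeric(cfg$layout$n_channels)
  rate[cfg$core_electrodes] <- cfg$mua_rate_core_hz * mult
  rate[cfg$surround_electrodes] <- cfg$mua_rate_surround_hz * mult
  rate
}

# Stage 1 of the generator: draw all event-level randomness.
# Network IILDs are drawn first so that toggling `high_k` (which only
# changes MUA rates) leaves IILD placement identical for the same seed.
sim_mea_events_impl <- function(cfg) {
  dur <- cfg$duration_s
  n_net <- stats::rpois(1L, cfg$iild_rate_per_min / 60 * dur)
  margin <- cfg$iild_slow_dur_ms / 1000
  net_t <- sort(stats::runif(n_net, margin, max(margin, dur - margin)))
  ripple_f <- stats::runif(n_net, cfg$iild_ripple_band_hz[1],
                           cfg$iild_ripple_band_hz[2])
  n_core <- length(cfg$core_electrodes)
  jit <- matrix(stats::runif(n_net * n_core, -cfg$iild_jitter_ms,
                             cfg$iild_jitter_ms) / 1000,
                nrow = n_net)
  amp_scale <- stats::runif(n_net, 0.9, 1.1)

  rates <- mea_true_rates(cfg)
  ev <- vector("list", cfg$layout$n_channels)
  for (ch in seq_len(cfg$layout$n_channels)) {
    n_sp <- stats::rpois(1L, rates[ch] * dur)
    sp_t <- sort(stats::runif(n_sp, 0, dur))
    rows <- list()
    if (n_sp > 0L) {
      rows[[1]] <- data.frame(channel = ch, t_s = sp_t, kind = "MUA_SPIKE")
    }
    if (n_net > 0L && ch %in% cfg$core_electrodes) {
      k <- match(ch, cfg$core_electrodes)
      rows[[length(rows) + 1L]] <-
        data.frame(channel = ch, t_s = net_t + jit[, k], kind = "IILD")
    }
    ev[[ch]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  events <- do.call(rbind, ev)
  if (is.null(events)) {
    events <- data.frame(channel = integer(0), t_s = numeric(0),
                         kind = character(0))
  }
  events <- events[order(events$channel, events$t_s), , drop = FALSE]
  rownames(events) <- NULL
  iild_rate <- numeric(cfg$layout$n_channels)
  iild_rate[cfg$core_electrodes] <- n_net / dur
  structure(list(events = events,
                 mua_rate_hz = rates, iild_rate_hz = iild_rate,
                 network_times_s = net_t, ripple_freq_hz = ripple_f,
                 network_channels = cfg$core_electrodes,
                 amp_scale = amp_scale, jitter_s = jit,
                 duration_s = dur),
            class = "mea_ground_truth")
}

#' Ground-truth event times of a synthetic MEA recording
#'
#' Draws the event-level randomness of [gen_mea_recording()] without
#' rasterizing traces: Poisson MUA spike trains per channel at the zone
#' rate, and network IILDs shared (with small uniform jitter) across all
#' core channels. Calling this with the same config yields exactly the
#' events of the corresponding full recording.
#'
#' @param cfg an [mea_sim_config()].
#' @return an object of class `mea_ground_truth`: per-channel event table
#'   (`events`: channel, t_s, kind), configured per-channel rates
#'   (`mua_rate_hz`, `iild_rate_hz`), and network-IILD times with
#'   participating channels.
#' @export
gen_mea_events <- function(cfg) {
  stopifnot(inherits(cfg, "mea_sim_config"))
  with_seed(cfg$seed, sim_mea_events_impl(cfg))
}

# -- waveforms ---------------------------------------------------------------

# 1 ms biphasic extracellular spike: single sine cycle under a Hann window,
# energy well above 250 Hz. Peak magnitude normalized to `amp`.
spike_waveform <- function(fs_hz, width_ms, amp) {
  n <- max(4L, round(width_ms / 1000 * fs_hz))
  u <- seq(0, 1, length.out = n)
  w <- sin(2 * pi * u) * (0.5 - 0.5 * cos(2 * pi * u))
  amp * w / max(abs(w))
}

# Biphasic IILD slow component: dominant sharp first deflection followed by
# a slower rebound of opposite sign (double Gaussian). Dominant energy sits
# well below 40 Hz for the default 300 ms duration. Returns the waveform and
# the sample offset of its dominant peak, which defines the ground-truth
# event time.
iild_waveform <- function(fs_hz, dur_ms, amp, ripple_amp, ripple_freq_hz) {
  T <- dur_ms / 1000
  n <- max(8L, round(T * fs_hz))
  t <- seq(0, T, length.out = n)
  g1 <- exp(-(t - 0.35 * T)^2 / (2 * (0.08 * T)^2))
  g2 <- exp(-(t - 0.68 * T)^2 / (2 * (0.16 * T)^2))
  slow <- g1 - 0.5 * g2
  slow <- amp * slow / max(abs(slow))
  # amplitude-modulated ripple burst riding on the dominant deflection
  rip_dur <- min(0.1, T / 3)
  env <- exp(-(t - 0.35 * T)^2 / (2 * (rip_dur / 4)^2))
  ripple <- ripple_amp * env * sin(2 * pi * ripple_freq_hz * (t - 0.35 * T))
  list(wave = slow + ripple, peak_offset = which.max(abs(slow)) - 1L)
}

add_at <- function(x, idx0, wave) {
  # add `wave` into x starting at sample index idx0 (1-based), clipping edges
  n <- length(x); m <- length(wave)
  a <- max(1L, idx0); b <- min(n, idx0 + m - 1L)
  if (a > b) return(x)
  x[a:b] <- x[a:b] + wave[(a - idx0 + 1L):(b - idx0 + 1L)]
  x
}

#' Generate a synthetic MEA recording with ground truth
#'
#' Rasterizes one extracellular trace per layout electrode: white Gaussian
#' background noise, Poisson multi-unit spikes at the zone rate, and -- on
#' core channels only -- synchronous biphasic IILDs with a superimposed
#' ripple burst. Under the high-K+ condition all MUA rates are multiplied by
#' the configured factor while IILD placement is unchanged.
#'
#' @param cfg an [mea_sim_config()].
#' @return a list with `recording` (class `mea_recording`: `traces` channels
#'   x samples matrix in uV, `fs_hz`, `channel_ids`, `layout`, `condition`)
#'   and `ground_truth` (as returned by [gen_mea_events()]).
#' @examples
#' cfg <- mea_sim_config(seed = 1, duration_s = 2, layout = mea_layout(3, 4),
#'                       core_electrodes = c(6, 7), surround_electrodes = c(2, 3))
#' sim <- gen_mea_recording(cfg)
#' dim(sim$recording$traces)
#' @export
gen_mea_recording <- function(cfg) {
  stopifnot(inherits(cfg, "mea_sim_config"))
  with_seed(cfg$seed, {
    gt <- sim_mea_events_impl(cfg)
    n <- round(cfg$duration_s * cfg$fs_hz)
    n_ch <- cfg$layout$n_channels
    traces <- matrix(0, nrow = n_ch, ncol = n)
    spike <- spike_waveform(cfg$fs_hz, cfg$spike_width_ms, cfg$amp_spike_uv)
    half_spike <- length(spike) %/% 2L
    for (ch in seq_len(n_ch)) {
      x <- if (cfg$noise_sd_uv > 0) stats::rnorm(n, 0, cfg$noise_sd_uv)
           else numeric(n)
      evc <- gt$events[gt$events$channel == ch, , drop = FALSE]
      sp <- evc$t_s[evc$kind == "MUA_SPIKE"]
      for (t0 in sp) {
        x <- add_at(x, round(t0 * cfg$fs_hz) - half_spike + 1L, spike)
      }
      if (ch %in% cfg$core_electrodes) {
        il <- which(evc$kind == "IILD")
        for (j in seq_along(il)) {
          k <- il[j]  # j-th network event on this channel (times are sorted)
          wf <- iild_waveform(cfg$fs_hz, cfg$iild_slow_dur_ms,
                              cfg$amp_iild_uv * gt$amp_scale[j],
                              cfg$amp_ripple_uv, gt$ripple_freq_hz[j])
          x <- add_at(x, round(evc$t_s[k] * cfg$fs_hz) - wf$peak_offset + 1L,
                      wf$wave)
        }
      }
      traces[ch, ] <- x
    }
    rec <- structure(list(traces = traces, fs_hz = cfg$fs_hz,
                          channel_ids = seq_len(n_ch), layout = cfg$layout,
                          condition = if (isTRUE(cfg$high_k)) "high_K"
                                      else "control_ACSF",
                          duration_s = cfg$duration_s),
                     class = "mea_recording")
    list(recording = rec, ground_truth = gt)
  })
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("MEA recording: %d channels x %d samples @ %g Hz (%s)\n",
              nrow(x$traces), ncol(x$traces), x$fs_hz, x$condition))
  invisible(x)
}
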