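#' Detection parameters for IILD and MUA detection
#'
#' The detector follows a filter - square - normalize - threshold scheme.
#' IILDs are sought in the 1-40 Hz band, MUA in the > 250 Hz band, and the
#' 100-500 Hz band is used for display/spectral discrimination. Thresholds
#' are user-defined, expressed in amplitude SD units of the band-filtered
#' trace: a threshold of k marks samples whose squared signal exceeds
#' k^2 times its mean square, i.e. |x| >= k x RMS. On the z-normalized
#' squared signal this corresponds to z >= (mean(s) * (k^2 - 1)) / sd(s).
#'
#' @param iild_band_hz IILD detection band, Hz.
#' @param mua_highpass_hz MUA high-pass corner, Hz.
#' @param display_band_hz ripple/display band, Hz.
#' @param filter_order filter order (applied forward-backward, zero phase).
#' @param iild_threshold_sd,mua_threshold_sd detection thresholds, amplitude
#'   SD units.
#' @param iild_smooth_ms,mua_smooth_ms width of the centred moving-average
#'   window applied to the squared signal before thresholding (an energy
#'   envelope over the expected event timescale; suppresses single-sample
#'   noise excursions).
#' @param iild_min_sep_ms supra-threshold regions closer than this merge
#'   into one IILD.
#' @param iild_min_dur_ms minimum total supra-threshold time of a merged
#'   event; shorter events are discarded (suppresses brief noise crossings).
#' @param mua_refractory_ms threshold crossings within this window collapse
#'   to one spike.
#' @param slow_fraction_cut IILD-vs-spike call: an event is an IILD when
#'   slow_energy / (slow_energy + fast_energy) >= this cut.
#' @param detrend,notch_hz preprocessing: linear detrend (on by default) and
#'   optional mains notch frequency (off when `NULL`).
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(iild_band_hz = c(1, 40), mua_highpass_hz = 250,
                             display_band_hz = c(100, 500), filter_order = 2,
                             iild_threshold_sd = 3, mua_threshold_sd = 5,
                             iild_smooth_ms = 10, mua_smooth_ms = 0.5,
                             iild_min_sep_ms = 200, iild_min_dur_ms = 40,
                             mua_refractory_ms = 1, slow_fraction_cut = 0.5,
                             detrend = TRUE, notch_hz = NULL) {
  chk_num(iild_band_hz, "iild_band_hz", lo = 0, len = 2L)
  chk_num(mua_highpass_hz, "mua_highpass_hz", lo = 0)
  chk_num(iild_threshold_sd, "iild_threshold_sd", lo = 1e-9)
  chk_num(mua_threshold_sd, "mua_threshold_sd", lo = 1e-9)
  if (iild_band_hz[1] >= iild_band_hz[2]) stop_input("invalid `iild_band_hz`")
  structure(list(iild_band_hz = iild_band_hz,
                 mua_highpass_hz = mua_highpass_hz,
                 display_band_hz = display_band_hz,
                 filter_order = filter_order,
                 iild_threshold_sd = iild_threshold_sd,
                 mua_threshold_sd = mua_threshold_sd,
                 iild_smooth_ms = iild_smooth_ms,
                 mua_smooth_ms = mua_smooth_ms,
                 iild_min_sep_ms = iild_min_sep_ms,
                 iild_min_dur_ms = iild_min_dur_ms,
                 mua_refractory_ms = mua_refractory_ms,
                 slow_fraction_cut = slow_fraction_cut,
                 detrend = detrend, notch_hz = notch_hz),
            class = "detection_params")
}

#' Zero-phase band-pass filter
#'
#' Order-`order` Butterworth filter applied forward-backward
#' ([signal::filtfilt()]), giving a zero-phase band-limited signal of the
#' same length as the input. `low_hz = 0` yields a pure low-pass and
#' `high_hz = fs/2` a pure high-pass.
#'
#' @param x numeric trace.
#' @param fs_hz sampling rate, Hz.
#' @param low_hz,high_hz band edges, Hz, with `0 <= low < high <= fs/2`.
#' @param order filter order.
#' @return filtered trace, same length as `x`.
#' @examples
#' fs <- 1000; t <- seq(0, 2, by = 1 / fs)
#' y <- bandpass_filter(sin(2 * pi * 10 * t), fs, 1, 40)
#' @export
bandpass_filter <- function(x, fs_hz, low_hz, high_hz, order = 2) {
  nyq <- fs_hz / 2
  if (!is.numeric(low_hz) || !is.numeric(high_hz) || low_hz < 0 ||
      low_hz >= high_hz || high_hz > nyq) {
    stop_input("invalid band: need 0 <= low < high <= fs/2")
  }
  if (low_hz <= 0 && high_hz >= nyq) return(x)
  flt <- if (low_hz <= 0) {
    signal::butter(order, high_hz / nyq, type = "low")
  } else if (high_hz >= nyq) {
    signal::butter(order, low_hz / nyq, type = "high")
  } else {
    signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(flt, x))
}

#' Normalized squared signal
#'
#' Squares a (band-filtered) trace and z-normalizes the squared signal over
#' its full length: the result has mean 0 and SD 1. This is the signal on
#' which detection thresholds operate.
#'
#' @param x numeric trace (already filtered to the band of interest).
#' @return z-scored squared trace, or all-`NA` if the input has zero
#'   variance.
#' @export
power_normalize <- function(x) {
  s <- x^2
  sdv <- stats::sd(s)
  if (!is.finite(sdv) || sdv == 0) return(rep(NA_real_, length(x)))
  (s - mean(s)) / sdv
}

preprocess_trace <- function(x, fs_hz, params) {
  if (isTRUE(params$detrend)) {
    t <- seq_along(x)
    x <- stats::lm.fit(cbind(1, t), x)$residuals
  }
  if (!is.null(params$notch_hz)) {
    f0 <- params$notch_hz
    x <- x - bandpass_filter(x, fs_hz, max(f0 - 2, 0.1), f0 + 2,
                             params$filter_order)
  }
  x
}

# Centred moving average (energy envelope) with edge shrinkage.
smooth_env <- function(s, w) {
  if (w <= 1L) return(s)
  n <- length(s)
  h <- w %/% 2L
  cs <- cumsum(c(0, s))
  a <- pmax(1L, seq_len(n) - h)
  b <- pmin(n, seq_len(n) + h)
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}

# Shared threshold machinery: squares the filtered trace, smooths it into
# an energy envelope over `smooth_ms`, and marks samples whose envelope
# exceeds `mean(envelope) * k^2` (i.e. amplitude >= k x RMS). Returns the
# supra-threshold runs plus the z-normalized envelope and the z-equivalent
# threshold.
threshold_runs <- function(xf, k, smooth_ms = 0, fs_hz = 1) {
  s <- xf^2
  w <- max(1L, round(smooth_ms / 1000 * fs_hz))
  if (w %% 2L == 0L) w <- w + 1L
  s <- smooth_env(s, w)
  m <- mean(s)
  sdv <- stats::sd(s)
  if (!is.finite(sdv) || sdv == 0 || m == 0) return(NULL)
  thr_s <- m * k^2
  list(s = s, z = (s - m) / sdv, thr_s = thr_s, z_cut = (thr_s - m) / sdv,
       runs = true_runs(s >= thr_s))
}

merge_runs <- function(runs, max_gap_samples) {
  if (nrow(runs) <= 1L) return(runs)
  grp <- cumsum(c(1L, (runs[-1L, "start"] - runs[-nrow(runs), "end"]) >
                        max_gap_samples))
  starts <- tapply(runs[, "start"], grp, min)
  ends <- tapply(runs[, "end"], grp, max)
  supra <- tapply(runs[, "end"] - runs[, "start"] + 1L, grp, sum)
  cbind(start = as.integer(starts), end = as.integer(ends),
        supra = as.integer(supra))
}

empty_events <- function() {
  data.frame(channel = integer(0), t_onset_s = numeric(0),
             t_peak_s = numeric(0), t_offset_s = numeric(0),
             kind = character(0), peak_z = numeric(0),
             slow_energy = numeric(0), fast_energy = numeric(0))
}

#' Detect interictal-like discharges on one trace
#'
#' Pipeline: denoise (linear detrend, optional mains notch) -> zero-phase
#' band-pass in the IILD band -> square and smooth into an energy envelope
#' -> z-normalize over the full trace -> mark supra-threshold regions ->
#' merge regions closer than
#' `iild_min_sep_ms` -> discard merged events with less than
#' `iild_min_dur_ms` of total supra-threshold time -> extend event bounds to
#' the half-threshold crossings. Events are returned sorted by onset, with
#' half-open `[onset, offset)` intervals in seconds from trace start.
#'
#' @param x numeric trace, uV; at least 1 s of samples.
#' @param fs_hz sampling rate, Hz.
#' @param params a [detection_params()].
#' @param channel channel id recorded in the output (default `NA`).
#' @return event data.frame: `channel`, `t_onset_s`, `t_peak_s`,
#'   `t_offset_s`, `kind` (`"IILD"`), `peak_z` (SD units of the normalized
#'   squared signal) and band energies `slow_energy` / `fast_energy` around
#'   the event.
#' @export
detect_iilds <- function(x, fs_hz, params = detection_params(),
                         channel = NA_integer_) {
  if (length(x) < fs_hz) stop_input("trace shorter than 1 s")
  x <- preprocess_trace(x, fs_hz, params)
  xf <- bandpass_filter(x, fs_hz, params$iild_band_hz[1],
                        params$iild_band_hz[2], params$filter_order)
  th <- threshold_runs(xf, params$iild_threshold_sd, params$iild_smooth_ms,
                       fs_hz)
  if (is.null(th) || nrow(th$runs) == 0L) return(empty_events())
  ev <- merge_runs(th$runs, round(params$iild_min_sep_ms / 1000 * fs_hz))
  if (!"supra" %in% colnames(ev)) {
    ev <- cbind(ev, supra = ev[, "end"] - ev[, "start"] + 1L)
  }
  ev <- ev[ev[, "supra"] >= params$iild_min_dur_ms / 1000 * fs_hz, ,
           drop = FALSE]
  if (nrow(ev) == 0L) return(empty_events())

  half <- th$thr_s / 2
  n <- length(xf)
  out <- lapply(seq_len(nrow(ev)), function(i) {
    a <- ev[i, "start"]; b <- ev[i, "end"]
    while (a > 1L && th$s[a - 1L] >= half) a <- a - 1L
    while (b < n && th$s[b + 1L] >= half) b <- b + 1L
    pk <- a - 1L + which.max(th$s[a:b])
    data.frame(channel = channel, t_onset_s = (a - 1L) / fs_hz,
               t_peak_s = (pk - 1L) / fs_hz, t_offset_s = b / fs_hz,
               kind = "IILD", peak_z = th$z[pk],
               slow_energy = band_energy(x[a:b], fs_hz, c(0, 40)),
               fast_energy = band_energy(x[a:b], fs_hz, c(100, 500)))
  })
  res <- do.call(rbind, out)
  res[order(res$t_onset_s), , drop = FALSE]
}

#' Detect multi-unit activity spikes on one trace
#'
#' Applies the same square / normalize / threshold scheme as
#' [detect_iilds()] to the signal high-pass filtered above
#' `mua_highpass_hz`. Successive threshold crossings within
#' `mua_refractory_ms` collapse to a single spike.
#'
#' @inheritParams detect_iilds
#' @return event data.frame as in [detect_iilds()], with `kind =
#'   "MUA_SPIKE"` (band energies are not computed per spike and are `NA`).
#' @export
detect_mua <- function(x, fs_hz, params = detection_params(),
                       channel = NA_integer_) {
  if (length(x) < fs_hz) stop_input("trace shorter than 1 s")
  x <- preprocess_trace(x, fs_hz, params)
  xf <- bandpass_filter(x, fs_hz, params$mua_highpass_hz, fs_hz / 2,
                        params$filter_order)
  th <- threshold_runs(xf, params$mua_threshold_sd, params$mua_smooth_ms,
                       fs_hz)
  if (is.null(th) || nrow(th$runs) == 0L) return(empty_events())
  ev <- merge_runs(th$runs, round(params$mua_refractory_ms / 1000 * fs_hz))
  if (!"supra" %in% colnames(ev)) {
    ev <- cbind(ev, supra = ev[, "end"] - ev[, "start"] + 1L)
  }
  out <- lapply(seq_len(nrow(ev)), function(i) {
    a <- ev[i, "start"]; b <- ev[i, "end"]
    pk <- a - 1L + which.max(th$s[a:b])
    data.frame(channel = channel, t_onset_s = (a - 1L) / fs_hz,
               t_peak_s = (pk - 1L) / fs_hz, t_offset_s = b / fs_hz,
               kind = "MUA_SPIKE", peak_z = th$z[pk],
               slow_energy = NA_real_, fast_energy = NA_real_)
  })
  res <- do.call(rbind, out)
  res[order(res$t_onset_s), , drop = FALSE]
}

#' Classify a detected event as IILD or isolated spike
#'
#' Computes the slow (< 40 Hz) and fast (100-500 Hz) band energies in a
#' window around the event and calls the event an IILD when the slow
#' fraction `slow / (slow + fast)` reaches `slow_fraction_cut`; otherwise it
#' is an isolated multi-unit spike. The event window is padded to at least
#' 100 ms (centred on the peak) so that the slow band is spectrally
#' resolved. A short-time spectrogram of the window is returned alongside.
#'
#' @param x numeric trace the event was detected on.
#' @param fs_hz sampling rate, Hz.
#' @param event one-row event data.frame (as returned by the detectors).
#' @param params a [detection_params()].
#' @return list with `kind` (`"IILD"` or `"MUA_SPIKE"`), `slow_energy`,
#'   `fast_energy`, `slow_fraction` and `spectrogram` (list `S` time x
#'   frequency power, `f`, `t`).
#' @export
classify_event <- function(x, fs_hz, event, params = detection_params()) {
  stopifnot(is.data.frame(event), nrow(event) == 1L)
  a <- round(event$t_onset_s * fs_hz) + 1L
  b <- round(event$t_offset_s * fs_hz)
  if (b < a || a > length(x) || b < 1L) stop_input("empty event window")
  min_w <- round(0.1 * fs_hz)
  if (b - a + 1L < min_w) {
    c0 <- round(event$t_peak_s * fs_hz) + 1L
    a <- max(1L, c0 - min_w %/% 2L)
    b <- min(length(x), a + min_w - 1L)
  }
  seg <- x[a:b]
  slow <- band_energy(seg, fs_hz, c(0, 40))
  fast <- band_energy(seg, fs_hz, params$display_band_hz)
  frac <- if (slow + fast == 0) 0 else slow / (slow + fast)
  nfft <- min(256L, 2^floor(log2(length(seg))))
  sg <- signal::specgram(seg, n = nfft, Fs = fs_hz,
                         window = signal::hanning(nfft),
                         overlap = nfft %/% 2L)
  list(kind = if (frac >= params$slow_fraction_cut) "IILD" else "MUA_SPIKE",
       slow_energy = slow, fast_energy = fast, slow_fraction = frac,
       spectrogram = list(S = t(Mod(sg$S)^2), f = sg$f, t = sg$t))
}

#' Summarize the activity of one electrode
#'
#' Classifies an electrode from its detected events: `IILD_MUA` when at
#' least `min_iilds` IILDs were detected, otherwise `MUA_ONLY` when at least
#' `min_spikes` spikes were detected, otherwise `SILENT`.
#'
#' @param iild_events,mua_events event data.frames for this electrode.
#' @param duration_s recording duration, seconds (> 0).
#' @param min_spikes,min_iilds classification thresholds.
#' @param channel channel id for the output row.
#' @param defective logical; defective electrodes are labelled `DEFECTIVE`
#'   regardless of counts.
#' @return one-row data.frame: `channel`, `mua_rate_hz`, `n_spikes`,
#'   `iild_count`, `cls`.
#' @export
summarize_electrode <- function(iild_events, mua_events, duration_s,
                                min_spikes = 10L, min_iilds = 2L,
                                channel = NA_integer_, defective = FALSE) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop_input("`duration_s` must be positive")
  }
  n_sp <- if (is.null(mua_events)) 0L else nrow(mua_events)
  n_il <- if (is.null(iild_events)) 0L else nrow(iild_events)
  cls <- if (isTRUE(defective)) "DEFECTIVE"
         else if (n_il >= min_iilds) "IILD_MUA"
         else if (n_sp >= min_spikes) "MUA_ONLY"
         else "SILENT"
  data.frame(channel = channel, mua_rate_hz = n_sp / duration_s,
             n_spikes = n_sp, iild_count = n_il, cls = cls)
}

#' Run IILD and MUA detection over a full recording
#'
#' Convenience wrapper applying [detect_iilds()] and [detect_mua()] to every
#' channel of a recording and summarizing each electrode with
#' [summarize_electrode()].
#'
#' @param rec an `mea_recording` (see [gen_mea_recording()]).
#' @param params a [detection_params()].
#' @param min_spikes,min_iilds electrode classification thresholds.
#' @return list with `events` (all detected events) and `activity`
#'   (per-electrode summary).
#' @export
detect_recording <- function(rec, params = detection_params(),
                             min_spikes = 10L, min_iilds = 2L) {
  stopifnot(inherits(rec, "mea_recording"))
  dur <- ncol(rec$traces) / rec$fs_hz
  ev <- vector("list", nrow(rec$traces))
  act <- vector("list", nrow(rec$traces))
  for (ch in seq_len(nrow(rec$traces))) {
    x <- rec$traces[ch, ]
    il <- detect_iilds(x, rec$fs_hz, params, channel = ch)
    mu <- detect_mua(x, rec$fs_hz, params, channel = ch)
    ev[[ch]] <- rbind(il, mu)
    act[[ch]] <- summarize_electrode(il, mu, dur, min_spikes, min_iilds,
                                     channel = ch,
                                     defective = ch %in% rec$layout$defective)
  }
  list(events = do.call(rbind, ev), activity = do.call(rbind, act))
}

#' Group synchronous IILDs into network events
#'
#' Single-linkage grouping of IILDs whose peak times differ by at most
#' `window_ms` on channels adjacent in the grid (8-neighbourhood). Isolated
#' IILDs form singleton network events.
#'
#' @param events IILD event data.frame (`channel`, `t_peak_s`; all rows of
#'   kind `"IILD"`).
#' @param layout the [mea_layout()] the channels refer to.
#' @param window_ms synchrony window, ms.
#' @return data.frame with one row per network event: `network_id`,
#'   `t_consensus_s` (median member peak time), `n_channels`, and a list
#'   column `channels`.
#' @export
group_network_iilds <- function(events, layout, window_ms = 50) {
  stopifnot(inherits(layout, "mea_layout"))
  if (is.null(events) || nrow(events) == 0L) {
    return(data.frame(network_id = integer(0), t_consensus_s = numeric(0),
                      n_channels = integer(0)))
  }
  if (any(events$kind != "IILD")) stop_input("all events must be IILDs")
  if (any(!(events$channel %in% seq_len(layout$n_channels)))) {
    stop_input("unknown channel in `events`")
  }
  n <- nrow(events)
  ord <- order(events$t_peak_s)
  tp <- events$t_peak_s[ord]
  ch <- events$channel[ord]
  win <- window_ms / 1000
  edges <- list()
  j0 <- 1L
  for (i in seq_len(n)) {
    while (tp[i] - tp[j0] > win) j0 <- j0 + 1L
    js <- j0:i
    js <- js[js < i]
    if (length(js)) {
      adj <- channels_adjacent(layout, ch[i], ch[js])
      if (any(adj)) edges[[length(edges) + 1L]] <- cbind(i, js[adj])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, as.vector(t(em)))
  }
  comp <- igraph::components(g)$membership
  ids <- sort(unique(comp))
  res <- data.frame(
    network_id = seq_along(ids),
    t_consensus_s = vapply(ids, function(k) stats::median(tp[comp == k]),
                           numeric(1)),
    n_channels = vapply(ids, function(k) length(unique(ch[comp == k])),
                        integer(1)))
  res$channels <- lapply(ids, function(k) sort(unique(ch[comp == k])))
  res[order(res$t_consensus_s), , drop = FALSE]
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one matching of detected peak times to true event times
#' within a tolerance, yielding sensitivity and precision.
#'
#' @param true_t,detected_t numeric vectors of event times, seconds.
#' @param tol_s matching tolerance, seconds.
#' @return list with `tp`, `fn`, `fp`, `sensitivity`, `precision`.
#' @export
event_match_stats <- function(true_t, detected_t, tol_s) {
  true_t <- sort(true_t); detected_t <- sort(detected_t)
  used <- rep(FALSE, length(detected_t))
  tp <- 0L
  for (t0 in true_t) {
    d <- abs(detected_t - t0)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fn <- length(true_t) - tp
  fp <- length(detected_t) - tp
  list(tp = tp, fn = fn, fp = fp,
       sensitivity = if (length(true_t)) tp / length(true_t) else NA_real_,
       precision = if (length(detected_t)) tp / length(detected_t)
                   else NA_real_)
}
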