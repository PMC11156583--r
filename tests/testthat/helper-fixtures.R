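# Shared fixtures: a small recording grid and zone-faithful activity tables.

small_layout <- function() mea_layout(4, 5, pitch_h_um = 1000, pitch_v_um = 1000)

small_mea_cfg <- function(seed, duration_s = 60, ...) {
  mea_sim_config(seed = seed, duration_s = duration_s, layout = small_layout(),
                 ...)
}

# activity table matching the generator's zone structure
zone_activity <- function(cfg) {
  n <- cfg$layout$n_channels
  data.frame(channel = seq_len(n),
             cls = ifelse(seq_len(n) %in% cfg$core_electrodes, "IILD_MUA",
                   ifelse(seq_len(n) %in% cfg$surround_electrodes,
                          "MUA_ONLY", "SILENT")))
}

# per-channel sensitivity/precision of a detector run against ground truth
recovery_stats <- function(gt_events, det_events, kind, tol_s, n_channels) {
  tp <- fp <- fn <- 0L
  for (ch in seq_len(n_channels)) {
    tt <- gt_events$t_s[gt_events$channel == ch & gt_events$kind == kind]
    dd <- det_events$t_peak_s[det_events$channel == ch &
                                det_events$kind == kind]
    st <- event_match_stats(tt, dd, tol_s)
    tp <- tp + st$tp; fp <- fp + st$fp; fn <- fn + st$fn
  }
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = tp / max(1L, tp + fn),
       precision = tp / max(1L, tp + fp))
}

# interval Jaccard index
interval_jaccard <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1))
  inter / (max(a2, b2) - min(a1, b1))
}

# single-zone cell-map config used for image-based counting
uniform_cell_cfg <- function(seed, density_mm2, field_w_mm = 1.5,
                             field_h_mm = 1) {
  cell_sim_config(seed = seed, field_w_mm = field_w_mm,
                  field_h_mm = field_h_mm,
                  core_rect_mm = c(0, 0, field_w_mm, field_h_mm),
                  surround_rect_mm = c(0, 0, field_w_mm, field_h_mm),
                  dn_density_core_mm2 = density_mm2,
                  dn_density_surround_mm2 = 0, normal_density_mm2 = 0)
}
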