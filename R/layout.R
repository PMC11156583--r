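#' Multi-electrode array layout
#'
#' Describes a planar recording grid. The default mirrors a 120-electrode
#' chamber: 10 rows x 12 columns of 30 um electrodes spaced 1,500 um
#' horizontally and 1,000 um vertically. Channels are numbered row-major
#' starting at the top-left electrode.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param pitch_h_um,pitch_v_um horizontal / vertical electrode spacing, um.
#' @param electrode_diam_um electrode diameter, um.
#' @param defective integer set of defective channel indices.
#' @return an object of class `mea_layout`.
#' @examples
#' lay <- mea_layout()
#' lay$n_channels  # 120
#' @export
mea_layout <- function(rows = 10L, cols = 12L, pitch_h_um = 1500,
                       pitch_v_um = 1000, electrode_diam_um = 30,
                       defective = integer(0)) {
  chk_num(rows, "rows", lo = 1); chk_num(cols, "cols", lo = 1)
  chk_num(pitch_h_um, "pitch_h_um", lo = 1e-9)
  chk_num(pitch_v_um, "pitch_v_um", lo = 1e-9)
  chk_num(electrode_diam_um, "electrode_diam_um", lo = 0)
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols
  defective <- as.integer(defective)
  if (length(defective) && (any(defective < 1L) || any(defective > n))) {
    stop_input("`defective` must be a subset of the layout channels")
  }
  structure(list(rows = rows, cols = cols, pitch_h_um = pitch_h_um,
                 pitch_v_um = pitch_v_um,
                 electrode_diam_um = electrode_diam_um,
                 defective = defective, n_channels = n),
            class = "mea_layout")
}

#' Electrode coordinates of a layout
#'
#' Row-major grid with the origin at the top-left electrode; x advances by
#' the horizontal pitch along columns, y by the vertical pitch along rows
#' (image convention, y increasing downward).
#'
#' @param layout an [mea_layout()].
#' @return data.frame with columns `channel`, `row`, `col`, `x_um`, `y_um`.
#' @export
electrode_positions <- function(layout) {
  stopifnot(inherits(layout, "mea_layout"))
  ch <- seq_len(layout$n_channels)
  row <- (ch - 1L) %/% layout$cols + 1L
  col <- (ch - 1L) %% layout$cols + 1L
  data.frame(channel = ch, row = row, col = col,
             x_um = (col - 1L) * layout$pitch_h_um,
             y_um = (row - 1L) * layout$pitch_v_um)
}

# 8-neighbourhood adjacency test for channel pairs of one layout.
channels_adjacent <- function(layout, ch_a, ch_b) {
  cols <- layout$cols
  ra <- (ch_a - 1L) %/% cols; ca <- (ch_a - 1L) %% cols
  rb <- (ch_b - 1L) %/% cols; cb <- (ch_b - 1L) %% cols
  (abs(ra - rb) <= 1L) & (abs(ca - cb) <= 1L) & (ch_a != ch_b)
}
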