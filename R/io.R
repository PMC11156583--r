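# Plain-text (CSV) interchange for the package's tabular artifacts:
# detected event tables, electrode summaries, cell maps, landmark sets and
# longitudinal study tables. Multi-channel images go through the `tiff`
# package when installed.

#' Write / read a detected-event table
#'
#' Columns: `channel`, `t_onset_s`, `t_peak_s`, `t_offset_s`, `kind`,
#' `peak_z`.
#'
#' @param events event data.frame (from [detect_iilds()] / [detect_mua()]).
#' @param path CSV file path.
#' @return `read_events_csv` returns the event data.frame.
#' @export
write_events_csv <- function(events, path) {
  cols <- c("channel", "t_onset_s", "t_peak_s", "t_offset_s", "kind",
            "peak_z")
  utils::write.csv(events[, intersect(cols, names(events)), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a cell map
#'
#' Columns: `x_um`, `y_um`, `diam_um` plus one 0/1 column per marker.
#'
#' @param cells cell-map data.frame (as from [gen_cell_map()]).
#' @param path CSV file path.
#' @return `read_cell_map_csv` returns the cell data.frame.
#' @export
write_cell_map_csv <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_map_csv
#' @export
read_cell_map_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a landmark table for affine registration
#'
#' Expected columns: `layout_x_um`, `layout_y_um`, `image_x_um`,
#' `image_y_um`.
#'
#' @param path CSV file path.
#' @return list with `layout_pts` and `image_pts` matrices, ready for
#'   [fit_affine()].
#' @export
read_landmarks_csv <- function(path) {
  d <- utils::read.csv(path)
  req <- c("layout_x_um", "layout_y_um", "image_x_um", "image_y_um")
  if (!all(req %in% names(d))) {
    stop_input("landmark CSV needs columns layout_x_um, layout_y_um, image_x_um, image_y_um")
  }
  list(layout_pts = as.matrix(d[, c("layout_x_um", "layout_y_um")]),
       image_pts = as.matrix(d[, c("image_x_um", "image_y_um")]))
}

#' Write / read a longitudinal EEG study table
#'
#' Columns: `animal`, `day`, `phase`, `hours_recorded`, `n_seizures`.
#'
#' @param daily study data.frame (as `gen_eeg_study()$daily`).
#' @param path CSV file path.
#' @return `read_eeg_study_csv` returns the study data.frame.
#' @export
write_eeg_study_csv <- function(daily, path) {
  utils::write.csv(daily, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_study_csv
#' @export
read_eeg_study_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a multi-channel histology image as TIFF
#'
#' Intensities are clipped to `[0, 1]`. Requires the `tiff` package.
#'
#' @param image y-by-x(-by-channel) numeric array.
#' @param path TIFF file path.
#' @return the path, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop_input("the `tiff` package is required to write TIFF images")
  }
  img <- pmin(1, pmax(0, image))
  if (length(dim(img)) == 3L) {
    layers <- lapply(seq_len(dim(img)[3]), function(k) img[, , k])
    tiff::writeTIFF(layers, path)
  } else {
    tiff::writeTIFF(img, path)
  }
  invisible(path)
}
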