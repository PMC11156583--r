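#' Segmentation parameters for histology images
#'
#' @param threshold_mode `"fixed"` (a user-set intensity threshold,
#'   transferable between experimental groups) or `"otsu"` (automatic).
#' @param threshold_value intensity cut when `threshold_mode = "fixed"`.
#' @param min_area_px2 objects of area less than or equal to this many
#'   pixels squared are discarded (the counting rule keeps objects
#'   *greater than* 25 px2 by default; the gate is in pixel units on
#'   purpose).
#' @param watershed logical; split touching objects via distance-transform
#'   watershed.
#' @param um_per_px image resolution, um per pixel (may also come from the
#'   image's `um_per_px` attribute).
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_mode = c("fixed", "otsu"),
                                threshold_value = NULL, min_area_px2 = 25,
                                watershed = FALSE, um_per_px = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed" && is.null(threshold_value)) {
    stop_input("`threshold_value` is required in fixed threshold mode")
  }
  chk_num(min_area_px2, "min_area_px2", lo = 0)
  if (!is.null(um_per_px)) chk_num(um_per_px, "um_per_px", lo = 1e-9)
  structure(list(threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 min_area_px2 = min_area_px2, watershed = watershed,
                 um_per_px = um_per_px),
            class = "segmentation_params")
}

# Otsu threshold of an arbitrary-range intensity matrix.
otsu_cut <- function(mat) {
  rg <- range(mat, finite = TRUE)
  if (rg[1] >= rg[2]) return(rg[1])
  EBImage::otsu(EBImage::Image(mat), range = rg)
}

# 8-connectivity connected-component labeling of a binary matrix.
label_components8 <- function(binary) {
  ny <- nrow(binary); nx <- ncol(binary)
  fg <- which(binary)
  lab <- matrix(0L, ny, nx)
  if (!length(fg)) return(lab)
  idmap <- integer(ny * nx)
  idmap[fg] <- seq_along(fg)
  row <- (fg - 1L) %% ny + 1L
  col <- (fg - 1L) %/% ny + 1L
  edges <- list()
  # neighbours in the down, right, down-right and up-right directions cover
  # the full 8-neighbourhood once per unordered pair
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + d[1]; c2 <- col + d[2]
    ok <- r2 >= 1L & r2 <= ny & c2 >= 1L & c2 <= nx
    nb <- (c2[ok] - 1L) * ny + r2[ok]
    hit <- idmap[nb] > 0L
    if (any(hit)) {
      edges[[length(edges) + 1L]] <-
        cbind(idmap[fg[ok]][hit], idmap[nb][hit])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, as.vector(t(do.call(rbind, edges))))
  }
  lab[fg] <- as.integer(igraph::components(g)$membership)
  lab
}

#' Segment cells in a histology image channel
#'
#' Threshold (fixed or Otsu) -> binarize -> optional distance-transform
#' watershed split -> 8-connectivity connected components -> discard
#' objects with area `<= min_area_px2` -> per-object centroid, area and
#' equivalent diameter. Marker positivity for additional channels is
#' called when the object's mean intensity in that channel exceeds the
#' channel's Otsu cut.
#'
#' @param image single-channel 2-D numeric matrix (y-by-x), or a
#'   y-by-x-by-channel array together with `channel`.
#' @param params a [segmentation_params()].
#' @param channel channel name/index when `image` is a multi-channel array.
#' @param marker_images named list of additional channel matrices for
#'   positivity calls (or names of channels of the array).
#' @return data.frame with one row per retained object: `x_um`, `y_um`,
#'   `area_px2`, `area_um2`, `diam_um` (`2 * sqrt(area_um2 / pi)`),
#'   `mean_intensity`, and for each marker channel a 0/1 positivity column
#'   and a `<marker>_mean` intensity column.
#' @export
segment_cells <- function(image, params, channel = NULL,
                          marker_images = NULL) {
  stopifnot(inherits(params, "segmentation_params"))
  um_per_px <- params$um_per_px %||% attr(image, "um_per_px")
  if (is.null(um_per_px)) {
    stop_input("um-per-px metadata is required (params or image attribute)")
  }
  if (length(dim(image)) == 3L) {
    if (is.null(channel)) stop_input("`channel` required for an image stack")
    if (is.null(marker_images)) {
      marker_images <- setdiff(dimnames(image)[[3]], channel)
    }
    if (is.character(marker_images)) {
      marker_images <- stats::setNames(
        lapply(marker_images, function(ch) image[, , ch]), marker_images)
    }
    image <- image[, , channel]
  }
  if (!is.matrix(image) || length(image) == 0L) {
    stop_input("`image` must be a non-empty 2-D matrix")
  }

  thr <- if (params$threshold_mode == "fixed") params$threshold_value
         else otsu_cut(image)
  binary <- image > thr
  if (!any(binary)) return(empty_cell_table(marker_images))

  lab <- if (isTRUE(params$watershed)) {
    w <- EBImage::watershed(EBImage::distmap(EBImage::Image(binary * 1)))
    matrix(as.integer(EBImage::imageData(w)), nrow(binary), ncol(binary))
  } else {
    label_components8(binary)
  }

  ids <- which(lab > 0L)
  labs <- lab[ids]
  area <- tabulate(labs)
  keep <- which(area > params$min_area_px2)
  if (!length(keep)) return(empty_cell_table(marker_images))

  row <- (ids - 1L) %% nrow(lab) + 1L
  col <- (ids - 1L) %/% nrow(lab) + 1L
  cy <- tapply(row, labs, mean)[as.character(keep)]
  cx <- tapply(col, labs, mean)[as.character(keep)]
  mi <- tapply(image[ids], labs, mean)[as.character(keep)]
  area_px2 <- area[keep]
  area_um2 <- area_px2 * um_per_px^2
  out <- data.frame(x_um = (as.numeric(cx) - 0.5) * um_per_px,
                    y_um = (as.numeric(cy) - 0.5) * um_per_px,
                    area_px2 = area_px2, area_um2 = area_um2,
                    diam_um = 2 * sqrt(area_um2 / pi),
                    mean_intensity = as.numeric(mi))
  for (mk in names(marker_images)) {
    mimg <- marker_images[[mk]]
    cut <- otsu_cut(mimg)
    means <- tapply(mimg[ids], labs, mean)[as.character(keep)]
    out[[mk]] <- as.integer(means > cut)
    out[[paste0(mk, "_mean")]] <- as.numeric(means)
  }
  rownames(out) <- NULL
  out
}

empty_cell_table <- function(marker_images) {
  out <- data.frame(x_um = numeric(0), y_um = numeric(0),
                    area_px2 = numeric(0), area_um2 = numeric(0),
                    diam_um = numeric(0), mean_intensity = numeric(0))
  for (mk in names(marker_images)) {
    out[[mk]] <- integer(0)
    out[[paste0(mk, "_mean")]] <- numeric(0)
  }
  out
}

#' Co-labeling fraction with exact binomial interval
#'
#' Fraction of reference-marker-positive cells that are also positive for
#' the test marker, with a Clopper-Pearson 95% confidence interval.
#'
#' @param cells data.frame with 0/1 positivity columns (from
#'   [segment_cells()] or [gen_cell_map()]).
#' @param ref_marker,test_marker column names.
#' @return an object of class `colabel_result`: list with `ref_marker`,
#'   `test_marker`, `n_ref`, `n_double`, `fraction`, `ci95`.
#' @examples
#' panel <- gen_colabel_panel(seed = 1, n = 200)
#' colabel_fraction(panel, "SABGAL", "P53")
#' @export
colabel_fraction <- function(cells, ref_marker, test_marker) {
  for (mk in c(ref_marker, test_marker)) {
    if (!mk %in% names(cells)) stop_input(sprintf("missing marker `%s`", mk))
  }
  ref <- cells[[ref_marker]] == 1
  n_ref <- sum(ref)
  if (n_ref < 1L) {
    stop_input("undefined fraction: no reference-positive cells")
  }
  n_double <- sum(ref & cells[[test_marker]] == 1)
  ci <- stats::binom.test(n_double, n_ref)$conf.int
  structure(list(ref_marker = ref_marker, test_marker = test_marker,
                 n_ref = n_ref, n_double = n_double,
                 fraction = n_double / n_ref, ci95 = as.numeric(ci)),
            class = "colabel_result")
}

#' @export
print.colabel_result <- function(x, ...) {
  cat(sprintf("%s+%s+ / %s+: %d / %d = %.1f%% (95%% CI %.1f-%.1f%%)\n",
              x$ref_marker, x$test_marker, x$ref_marker, x$n_double,
              x$n_ref, 100 * x$fraction, 100 * x$ci95[1], 100 * x$ci95[2]))
  invisible(x)
}

#' Mutant-cell fraction from variant allele frequency
#'
#' Under heterozygosity each mutant cell carries one variant allele, so the
#' fraction of mutant cells is twice the variant allele frequency (capped
#' at 1). A VAF above 0.5 is inconsistent with a purely heterozygous
#' variant and triggers a warning.
#'
#' @param vaf variant allele frequency (fraction in `[0, 1]`), vectorized.
#' @return data.frame with `vaf`, `cell_fraction = min(1, 2 * vaf)` and
#'   `heterozygous_consistent`.
#' @examples
#' mutant_cell_fraction(0.42)$cell_fraction  # 0.84
#' @export
mutant_cell_fraction <- function(vaf) {
  if (!is.numeric(vaf) || length(vaf) < 1L || anyNA(vaf) ||
      any(vaf < 0) || any(vaf > 1)) {
    stop_input("`vaf` must lie in [0, 1]")
  }
  if (any(vaf > 0.5)) {
    warning("VAF > 0.5 is inconsistent with a heterozygous variant",
            call. = FALSE)
  }
  data.frame(vaf = vaf, cell_fraction = pmin(1, 2 * vaf),
             heterozygous_consistent = vaf <= 0.5)
}

#' Cell density in a region of interest
#'
#' @param cells data.frame of cells (or a plain count).
#' @param roi_area_mm2 region area, mm2 (> 0).
#' @return cells per mm2.
#' @export
cell_density <- function(cells, roi_area_mm2) {
  if (!is.numeric(roi_area_mm2) || length(roi_area_mm2) != 1L ||
      roi_area_mm2 <= 0) {
    stop_input("`roi_area_mm2` must be positive")
  }
  n <- if (is.data.frame(cells)) nrow(cells) else as.numeric(cells)
  n / roi_area_mm2
}
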