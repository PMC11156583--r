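#' Fit a 2-D affine transform from landmark pairs
#'
#' Least-squares affine mapping layout coordinates onto image coordinates,
#' minimizing the sum of squared image-space residuals. At least three
#' non-collinear pairs are required; for affine-consistent pairs the fit is
#' exact (residual at machine precision).
#'
#' @param layout_pts,image_pts n x 2 matrices (or data.frames) of matched
#'   points, um.
#' @return an object of class `affine2d`: list with `A` (2 x 2 linear
#'   part), `b` (offset) and `rms_residual_um`.
#' @examples
#' src <- cbind(c(0, 1, 0), c(0, 0, 1))
#' fit_affine(src, src)$rms_residual_um  # 0
#' @export
fit_affine <- function(layout_pts, image_pts) {
  src <- as.matrix(layout_pts); dst <- as.matrix(image_pts)
  if (!is.numeric(src) || !is.numeric(dst) || ncol(src) != 2L ||
      ncol(dst) != 2L || nrow(src) != nrow(dst)) {
    stop_input("landmark sets must be matched n x 2 coordinate matrices")
  }
  if (nrow(src) < 3L) {
    stop_input("underdetermined: at least 3 landmark pairs are required")
  }
  X <- cbind(src, 1)
  qr_x <- qr(X)
  if (qr_x$rank < 3L) {
    stop_input("underdetermined: landmark points are collinear")
  }
  B <- qr.coef(qr_x, dst)  # 3 x 2
  A <- t(B[1:2, , drop = FALSE])
  b <- as.numeric(B[3, ])
  if (abs(det(A)) <= 1e-12) {
    stop_input("degenerate transform: linear part is not invertible")
  }
  resid <- X %*% B - dst
  structure(list(A = A, b = b,
                 rms_residual_um = sqrt(mean(rowSums(resid^2)))),
            class = "affine2d")
}

#' Apply an affine transform to points
#'
#' @param tf an `affine2d` from [fit_affine()] (or [affine_identity()]).
#' @param pts n x 2 matrix of points.
#' @return n x 2 matrix of transformed points.
#' @export
apply_affine <- function(tf, pts) {
  stopifnot(inherits(tf, "affine2d"))
  pts <- as.matrix(pts)
  sweep(pts %*% t(tf$A), 2L, -tf$b)
}

#' Identity affine transform
#' @return an `affine2d` mapping points to themselves.
#' @export
affine_identity <- function() {
  structure(list(A = diag(2), b = c(0, 0), rms_residual_um = 0),
            class = "affine2d")
}

#' Dysmorphic-neuron density per electrode-activity class
#'
#' Registers the electrode grid into image space, lets every non-defective
#' electrode claim its Voronoi cell (clipped to the analysis field), unions
#' same-class cells into class regions, and counts qualifying cells per
#' region. A cell qualifies as a dysmorphic neuron when it is positive for
#' every marker in `dn_markers` and its soma diameter exceeds
#' `min_diam_um`. Region areas are integrated on a regular grid over the
#' field, so the class regions partition the field exactly (no double
#' counting).
#'
#' @param cells cell-map data.frame with `x_um`, `y_um`, `diam_um` and one
#'   0/1 column per marker (image coordinates, um).
#' @param activity per-electrode data.frame with `channel` and `cls`
#'   (as from [detect_recording()]); must cover the layout channels.
#' @param layout the [mea_layout()].
#' @param transform `affine2d` mapping layout um to image um.
#' @param field analysis field `c(xmin, xmax, ymin, ymax)` in image um;
#'   defaults to the transformed electrode hull padded by half a pitch.
#' @param dn_markers marker columns that must all be positive.
#' @param min_diam_um minimum soma diameter, um.
#' @param grid_n grid resolution per axis for area integration.
#' @return data.frame per class: `cls`, `n_electrodes`, `region_area_mm2`,
#'   `n_cells`, `density_per_mm2`.
#' @export
density_by_class <- function(cells, activity, layout,
                             transform = affine_identity(), field = NULL,
                             dn_markers = c("PS6", "NEUN"),
                             min_diam_um = 25, grid_n = 400L) {
  stopifnot(inherits(layout, "mea_layout"), inherits(transform, "affine2d"))
  if (is.null(activity) || nrow(activity) == 0L) {
    stop_input("`activity` must cover the layout channels")
  }
  pos <- electrode_positions(layout)
  m <- merge(pos, activity[, c("channel", "cls")], by = "channel")
  if (nrow(m) < layout$n_channels) {
    stop_input("`activity` must cover the layout channels")
  }
  m <- m[m$cls != "DEFECTIVE" & !(m$channel %in% layout$defective), ,
         drop = FALSE]
  if (nrow(m) == 0L) stop_input("no usable (non-defective) electrodes")
  epos <- apply_affine(transform, cbind(m$x_um, m$y_um))

  if (is.null(field)) {
    pad_x <- layout$pitch_h_um / 2
    pad_y <- layout$pitch_v_um / 2
    field <- c(min(epos[, 1]) - pad_x, max(epos[, 1]) + pad_x,
               min(epos[, 2]) - pad_y, max(epos[, 2]) + pad_y)
  }
  chk_num(field, "field", len = 4L)

  nearest_of <- function(px, py) {
    # nearest usable electrode for each query point, chunked
    out <- integer(length(px))
    chunk <- 50000L
    for (i0 in seq(1L, length(px), by = chunk)) {
      ii <- i0:min(length(px), i0 + chunk - 1L)
      d2 <- outer(px[ii]^2 + py[ii]^2, rowSums(epos^2), "+") -
        2 * (cbind(px[ii], py[ii]) %*% t(epos))
      out[ii] <- max.col(-d2, ties.method = "first")
    }
    out
  }

  gx <- seq(field[1], field[2], length.out = grid_n)
  gy <- seq(field[3], field[4], length.out = grid_n)
  gpts <- expand.grid(x = gx, y = gy)
  g_owner <- m$cls[nearest_of(gpts$x, gpts$y)]
  field_area_mm2 <- (field[2] - field[1]) * (field[4] - field[3]) / 1e6
  area_by_cls <- table(g_owner) / length(g_owner) * field_area_mm2

  qual <- rep(TRUE, nrow(cells))
  for (mk in dn_markers) {
    if (!mk %in% names(cells)) stop_input(sprintf("missing marker `%s`", mk))
    qual <- qual & cells[[mk]] == 1
  }
  qual <- qual & cells$diam_um > min_diam_um &
    cells$x_um >= field[1] & cells$x_um <= field[2] &
    cells$y_um >= field[3] & cells$y_um <= field[4]
  cq <- cells[qual, , drop = FALSE]
  c_owner <- if (nrow(cq)) m$cls[nearest_of(cq$x_um, cq$y_um)] else character(0)

  classes <- sort(unique(m$cls))
  res <- data.frame(
    cls = classes,
    n_electrodes = as.integer(table(factor(m$cls, classes))),
    region_area_mm2 = as.numeric(area_by_cls[classes]),
    n_cells = as.integer(table(factor(c_owner, classes))))
  res$region_area_mm2[is.na(res$region_area_mm2)] <- 0
  res$density_per_mm2 <- ifelse(res$region_area_mm2 > 0,
                                res$n_cells / res$region_area_mm2, NA_real_)
  res
}
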