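# Marker panel probabilities: P(marker+ | SAbGal+ cytomegalic cell).
default_colabel_probs <- function() {
  c(P53 = 0.92, P16 = 0.85, SMI311 = 0.88, VIM = 0.95, PS6 = 0.89,
    NEUN = 0.98, P21 = 0.81, HMGB1_LOSS = 0.92, LAMINB1_LOSS = 0.84)
}

#' Configuration for synthetic histology cell maps
#'
#' Defines a 2-D tissue field with a dysmorphic-neuron (DN) core zone, a
#' lower-density surround zone, a balloon-cell (BC) band at the gray-white
#' boundary, and normal-sized cells everywhere. Default DN densities follow
#' the recorded core/surround contrast (53.6 vs 11.7 cells/mm2). Senescence
#' co-label probabilities are conditional on SAbGal positivity.
#'
#' @param seed RNG seed.
#' @param field_w_mm,field_h_mm field size, mm.
#' @param um_per_px image resolution, um per pixel.
#' @param core_rect_mm,surround_rect_mm zone rectangles `c(x0, y0, x1, y1)`
#'   in mm; the surround zone is `surround_rect_mm` minus `core_rect_mm`.
#'   Defaults carve the left part of the field.
#' @param dn_density_core_mm2,dn_density_surround_mm2 DN densities, mm^-2.
#' @param bc_band_mm balloon-cell strip `c(y0, y1)` in mm (gray-white
#'   boundary); `NULL` disables BCs.
#' @param bc_density_mm2 BC density inside the band, mm^-2.
#' @param normal_density_mm2 density of normal-sized neurons, mm^-2.
#' @param sabgal_prob probability that a cytomegalic (DN/BC) cell is
#'   SAbGal-positive.
#' @param dn_diam_um,bc_diam_um,normal_diam_um soma-diameter `c(mean, sd)`
#'   in um; cytomegalic cells are clamped above 25 um, normal cells below.
#' @param colabel_probs named probability vector, P(marker+ | SAbGal+).
#' @return an object of class `cell_sim_config`.
#' @export
cell_sim_config <- function(seed, field_w_mm = 2, field_h_mm = 1.5,
                            um_per_px = 2, core_rect_mm = NULL,
                            surround_rect_mm = NULL,
                            dn_density_core_mm2 = 53.6,
                            dn_density_surround_mm2 = 11.7,
                            bc_band_mm = NULL, bc_density_mm2 = 15,
                            normal_density_mm2 = 50, sabgal_prob = 0.9,
                            dn_diam_um = c(32, 3), bc_diam_um = c(32, 4),
                            normal_diam_um = c(12, 2),
                            colabel_probs = default_colabel_probs()) {
  chk_num(seed, "seed")
  chk_num(field_w_mm, "field_w_mm", lo = 1e-9)
  chk_num(field_h_mm, "field_h_mm", lo = 1e-9)
  chk_num(um_per_px, "um_per_px", lo = 1e-9)
  chk_num(dn_density_core_mm2, "dn_density_core_mm2", lo = 0)
  chk_num(dn_density_surround_mm2, "dn_density_surround_mm2", lo = 0)
  chk_num(bc_density_mm2, "bc_density_mm2", lo = 0)
  chk_num(normal_density_mm2, "normal_density_mm2", lo = 0)
  chk_num(sabgal_prob, "sabgal_prob", lo = 0, hi = 1)
  if (!is.numeric(colabel_probs) || is.null(names(colabel_probs)) ||
      any(colabel_probs < 0) || any(colabel_probs > 1)) {
    stop_input("`colabel_probs` must be a named vector of probabilities")
  }
  core_rect_mm <- core_rect_mm %||%
    c(0.1 * field_w_mm, 0.1 * field_h_mm, 0.5 * field_w_mm, 0.6 * field_h_mm)
  surround_rect_mm <- surround_rect_mm %||%
    c(0, 0, 0.7 * field_w_mm, 0.8 * field_h_mm)
  structure(list(seed = seed, field_w_mm = field_w_mm,
                 field_h_mm = field_h_mm, um_per_px = um_per_px,
                 core_rect_mm = core_rect_mm,
                 surround_rect_mm = surround_rect_mm,
                 dn_density_core_mm2 = dn_density_core_mm2,
                 dn_density_surround_mm2 = dn_density_surround_mm2,
                 bc_band_mm = bc_band_mm, bc_density_mm2 = bc_density_mm2,
                 normal_density_mm2 = normal_density_mm2,
                 sabgal_prob = sabgal_prob, dn_diam_um = dn_diam_um,
                 bc_diam_um = bc_diam_um, normal_diam_um = normal_diam_um,
                 colabel_probs = colabel_probs),
            class = "cell_sim_config")
}

rect_area_mm2 <- function(r) max(0, r[3] - r[1]) * max(0, r[4] - r[2])

in_rect <- function(x, y, r) x >= r[1] & x <= r[3] & y >= r[2] & y <= r[4]

# Homogeneous Poisson point placement inside a rectangle (mm coordinates).
poisson_points <- function(rect, density_mm2) {
  n <- stats::rpois(1L, density_mm2 * rect_area_mm2(rect))
  data.frame(x_mm = stats::runif(n, rect[1], rect[3]),
             y_mm = stats::runif(n, rect[2], rect[4]))
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Generate a synthetic cell map (and optionally a histology image)
#'
#' Places cells by homogeneous Poisson processes per zone. Dysmorphic
#' neurons (pS6+/NeuN+, soma > 25 um) fill the core and surround zones at
#' their configured densities; balloon cells (pS6+/NeuN-) fill the
#' gray-white band; normal-sized neurons (pS6-/NeuN+) cover the whole
#' field. Cytomegalic cells are SAbGal-positive with probability
#' `sabgal_prob`, and each SAbGal+ cytomegalic cell draws the senescence
#' panel markers independently at `colabel_probs`. The type-defining
#' markers pS6 and NeuN are set by cell type (see the package vignette);
#' their panel probabilities are exercised by [gen_colabel_panel()].
#'
#' @param cfg a [cell_sim_config()].
#' @param image logical; also rasterize a multi-channel image.
#' @param channels marker channels to rasterize when `image = TRUE`.
#' @return list with `cells` (data.frame: `x_um`, `y_um`, `diam_um`,
#'   `type` in DN/BC/NORMAL, `zone`, and one 0/1 column per marker) and
#'   `image` (array y-by-x-by-channel with attribute `um_per_px`, or
#'   `NULL`).
#' @export
gen_cell_map <- function(cfg, image = FALSE,
                         channels = c("SABGAL", "PS6", "NEUN")) {
  stopifnot(inherits(cfg, "cell_sim_config"))
  with_seed(cfg$seed, {
    field <- c(0, 0, cfg$field_w_mm, cfg$field_h_mm)

    make_cells <- function(pts, zone, type, diam, lo, hi) {
      n <- nrow(pts)
      data.frame(x_mm = pts$x_mm, y_mm = pts$y_mm,
                 zone = rep(zone, n), type = rep(type, n),
                 diam_um = clamp(stats::rnorm(n, diam[1], diam[2]), lo, hi))
    }

    # DN cores: Poisson in core rect; surround zone by thinning rejection
    dn_core <- make_cells(poisson_points(cfg$core_rect_mm,
                                         cfg$dn_density_core_mm2),
                          "core", "DN", cfg$dn_diam_um, 25.5, 60)
    sur <- poisson_points(cfg$surround_rect_mm, cfg$dn_density_surround_mm2)
    sur <- sur[!in_rect(sur$x_mm, sur$y_mm, cfg$core_rect_mm), , drop = FALSE]
    dn_sur <- make_cells(sur, "surround", "DN", cfg$dn_diam_um, 25.5, 60)

    bc <- NULL
    if (!is.null(cfg$bc_band_mm)) {
      band <- c(0, cfg$bc_band_mm[1], cfg$field_w_mm, cfg$bc_band_mm[2])
      bc <- make_cells(poisson_points(band, cfg$bc_density_mm2),
                       "bc_band", "BC", cfg$bc_diam_um, 25.5, 60)
    }

    nn <- make_cells(poisson_points(field, cfg$normal_density_mm2),
                     "background", "NORMAL", cfg$normal_diam_um, 6, 20)

    cells <- rbind(dn_core, dn_sur, bc, nn)
    n <- nrow(cells)
    cells$PS6 <- as.integer(cells$type %in% c("DN", "BC"))
    cells$NEUN <- as.integer(cells$type %in% c("DN", "NORMAL"))
    cells$SABGAL <- integer(n)
    cyto <- cells$type %in% c("DN", "BC")
    cells$SABGAL[cyto] <- stats::rbinom(sum(cyto), 1L, cfg$sabgal_prob)
    panel <- setdiff(names(cfg$colabel_probs), c("PS6", "NEUN"))
    for (mk in panel) {
      v <- integer(n)
      pos <- cells$SABGAL == 1L
      v[pos] <- stats::rbinom(sum(pos), 1L, cfg$colabel_probs[[mk]])
      cells[[mk]] <- v
    }
    cells$x_um <- cells$x_mm * 1000
    cells$y_um <- cells$y_mm * 1000
    cells <- cells[, c("x_um", "y_um", "diam_um", "type", "zone", "PS6",
                       "NEUN", "SABGAL", panel)]
    rownames(cells) <- NULL

    img <- if (isTRUE(image)) render_cell_image(cells, cfg, channels)
           else NULL
    list(cells = cells, image = img)
  })
}

# Rasterize marker channels: each positive cell becomes a bright disk on a
# dim noisy background. Intensities are arbitrary fluorescence units in
# [0, ~1].
render_cell_image <- function(cells, cfg, channels) {
  nx <- max(2L, round(cfg$field_w_mm * 1000 / cfg$um_per_px))
  ny <- max(2L, round(cfg$field_h_mm * 1000 / cfg$um_per_px))
  img <- array(0, dim = c(ny, nx, length(channels)),
               dimnames = list(NULL, NULL, channels))
  for (k in seq_along(channels)) {
    ch <- channels[k]
    plane <- matrix(0.1 + stats::rnorm(ny * nx, 0, 0.03), ny, nx)
    pos <- if (ch %in% names(cells)) which(cells[[ch]] == 1L) else integer(0)
    for (i in pos) {
      cx <- cells$x_um[i] / cfg$um_per_px
      cy <- cells$y_um[i] / cfg$um_per_px
      r <- cells$diam_um[i] / 2 / cfg$um_per_px
      xs <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r))
      ys <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r))
      if (!length(xs) || !length(ys)) next
      d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
      disk <- d2 <= r^2
      sub <- plane[ys, xs, drop = FALSE]
      sub[disk] <- pmax(sub[disk], 0.8 + stats::rnorm(1L, 0, 0.05))
      plane[ys, xs] <- sub
    }
    img[, , k] <- plane
  }
  attr(img, "um_per_px") <- cfg$um_per_px
  img
}

#' Generate a synthetic senescence co-label panel
#'
#' Simulates `n` SAbGal-positive cytomegalic cells whose panel markers are
#' independent Bernoulli draws at the given conditional probabilities --
#' the direct generative model behind reported co-label percentages
#' (fraction of SAbGal+ cells also positive for each marker).
#'
#' @param seed RNG seed.
#' @param n number of SAbGal+ cells.
#' @param probs named probability vector, P(marker+ | SAbGal+).
#' @return data.frame with `SABGAL` (all 1) and one 0/1 column per marker.
#' @export
gen_colabel_panel <- function(seed, n, probs = default_colabel_probs()) {
  chk_num(n, "n", lo = 1)
  with_seed(seed, {
    out <- data.frame(SABGAL = rep(1L, n))
    for (mk in names(probs)) {
      out[[mk]] <- stats::rbinom(n, 1L, probs[[mk]])
    }
    out
  })
}
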