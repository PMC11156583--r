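test_that("the area gate keeps only objects larger than 25 px2", {
  img <- matrix(0, 60, 60)
  img[10 + (0:4), 10 + (0:3)] <- 1   # 20 px2 blob: discarded
  img[40 + (0:5), 40 + (0:4)] <- 1   # 30 px2 blob: kept
  sp <- segmentation_params("fixed", 0.5, um_per_px = 2)
  cells <- segment_cells(img, sp)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$area_px2, 30)
  expect_equal(cells$area_um2, 30 * 4)
  expect_equal(cells$diam_um, 2 * sqrt(120 / pi))
})

test_that("blank and degenerate images behave as specified", {
  sp <- segmentation_params("fixed", 0.5, um_per_px = 2)
  expect_equal(nrow(segment_cells(matrix(0.05, 40, 40), sp)), 0)
  expect_error(segment_cells(matrix(numeric(0), 0, 0), sp), "non-empty")
  expect_error(segment_cells(matrix(1, 4, 4),
                             segmentation_params("fixed", 0.5)), "um-per-px")
  expect_error(segmentation_params("fixed"), "threshold_value")
})

test_that("connected components use 8-connectivity", {
  img <- matrix(0, 30, 30)
  # two 18-px blocks touching only at a corner: one object under
  # 8-connectivity
  img[5:10, 5:7] <- 1
  img[11:16, 8:10] <- 1
  sp <- segmentation_params("fixed", 0.5, min_area_px2 = 0, um_per_px = 1)
  expect_equal(nrow(segment_cells(img, sp)), 1)
})

test_that("watershed splits touching objects; off they merge", {
  img <- matrix(0, 80, 80)
  for (ctr in list(c(30, 35), c(30, 55))) {
    d2 <- outer((1:80 - ctr[1])^2, (1:80 - ctr[2])^2, "+")
    img[d2 <= 11^2] <- 1
  }
  on <- segment_cells(img, segmentation_params("fixed", 0.5,
                                               watershed = TRUE,
                                               um_per_px = 2))
  off <- segment_cells(img, segmentation_params("fixed", 0.5,
                                                um_per_px = 2))
  expect_equal(nrow(on), 2)
  expect_equal(nrow(off), 1)
})

test_that("marker positivity is called from per-channel Otsu cuts", {
  base <- matrix(0.05, 60, 60)
  base[10:20, 10:20] <- 0.9
  base[40:50, 40:50] <- 0.9
  marker <- matrix(0.05, 60, 60)
  marker[10:20, 10:20] <- 0.8   # only the first object is marker-positive
  sp <- segmentation_params("fixed", 0.5, um_per_px = 2)
  cells <- segment_cells(base, sp, marker_images = list(MK = marker))
  expect_equal(nrow(cells), 2)
  expect_equal(sort(cells$MK), c(0, 1))
})

test_that("Otsu thresholding segments a bimodal synthetic image", {
  cfg <- uniform_cell_cfg(seed = 5, density_mm2 = 30)
  cm <- gen_cell_map(cfg, image = TRUE, channels = "PS6")
  sp <- segmentation_params("otsu", um_per_px = 2, watershed = TRUE)
  det <- segment_cells(cm$image[, , 1], sp)
  expect_gt(nrow(det), 0)
  expect_lt(abs(nrow(det) - nrow(cm$cells)), 0.15 * nrow(cm$cells) + 3)
})

test_that("raising the area gate never increases the object count", {
  cfg <- uniform_cell_cfg(seed = 6, density_mm2 = 40)
  cm <- gen_cell_map(cfg, image = TRUE, channels = "PS6")
  counts <- sapply(c(0, 25, 100, 200, 400), function(a) {
    sp <- segmentation_params("otsu", min_area_px2 = a, um_per_px = 2)
    nrow(segment_cells(cm$image[, , 1], sp))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("equivalent diameter scales linearly with the pixel size", {
  img <- matrix(0, 40, 40)
  img[10:20, 10:20] <- 1
  d1 <- segment_cells(img, segmentation_params("fixed", 0.5,
                                               um_per_px = 1))$diam_um
  d3 <- segment_cells(img, segmentation_params("fixed", 0.5,
                                               um_per_px = 3))$diam_um
  expect_equal(d3, 3 * d1)
})

test_that("co-label fractions and intervals match closed forms", {
  cells <- data.frame(SABGAL = rep(1, 50),
                      P53 = c(rep(1, 46), rep(0, 4)))
  cf <- colabel_fraction(cells, "SABGAL", "P53")
  expect_equal(cf$fraction, 0.92)
  expect_equal(cf$n_ref, 50)
  expect_equal(cf$n_double, 46)
  expect_equal(cf$ci95, binom.test(46, 50)$conf.int[1:2], tolerance = 1e-12)
  expect_lt(cf$ci95[1], 0.92)
  expect_gt(cf$ci95[2], 0.92)
  none <- data.frame(SABGAL = rep(0, 10), P53 = rep(1, 10))
  expect_error(colabel_fraction(none, "SABGAL", "P53"), "undefined")
  expect_error(colabel_fraction(cells, "SABGAL", "NOPE"), "missing")
})

test_that("heterozygous VAF doubles into mutant-cell fraction", {
  expect_equal(mutant_cell_fraction(0.5)$cell_fraction, 1.0)
  expect_equal(mutant_cell_fraction(0.42)$cell_fraction, 0.84)
  expect_equal(mutant_cell_fraction(0.055)$cell_fraction, 0.11)
  expect_warning(res <- mutant_cell_fraction(0.6), "heterozygous")
  expect_equal(res$cell_fraction, 1.0)
  expect_false(res$heterozygous_consistent)
  expect_error(mutant_cell_fraction(1.2), "0, 1")
  expect_error(mutant_cell_fraction(-0.1), "0, 1")
})

test_that("cell density is count over area", {
  expect_equal(cell_density(data.frame(x = 1:8), 0.5), 16)
  expect_equal(cell_density(data.frame(x = numeric(0)), 0.5), 0)
  expect_equal(cell_density(12, 2), 6)
  expect_error(cell_density(data.frame(x = 1), 0), "positive")
})

test_that("image-based counting recovers a known density", {
  n_tot <- 0; a_tot <- 0
  for (seed in 1:10) {
    cfg <- uniform_cell_cfg(seed = seed, density_mm2 = 50)
    cm <- gen_cell_map(cfg, image = TRUE, channels = "PS6")
    sp <- segmentation_params("otsu", um_per_px = 2, watershed = TRUE)
    n_tot <- n_tot + nrow(segment_cells(cm$image[, , 1], sp))
    a_tot <- a_tot + 1.5
  }
  lo <- qpois(0.025, 50 * a_tot) / a_tot
  hi <- qpois(0.975, 50 * a_tot) / a_tot
  expect_gte(n_tot / a_tot, lo)
  expect_lte(n_tot / a_tot, hi)
})
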