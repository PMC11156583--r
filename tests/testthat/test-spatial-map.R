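test_that("electrode positions form the configured grid", {
  pos <- electrode_positions(mea_layout())
  expect_equal(nrow(pos), 120)
  # same-row neighbours are one horizontal pitch apart
  p1 <- pos[pos$row == 1 & pos$col == 1, ]
  p2 <- pos[pos$row == 1 & pos$col == 2, ]
  expect_equal(sqrt((p1$x_um - p2$x_um)^2 + (p1$y_um - p2$y_um)^2), 1500)
  # same-column neighbours one vertical pitch apart
  p3 <- pos[pos$row == 2 & pos$col == 1, ]
  expect_equal(sqrt((p1$x_um - p3$x_um)^2 + (p1$y_um - p3$y_um)^2), 1000)
  expect_equal(unname(unlist(
    electrode_positions(mea_layout(1, 1))[, c("x_um", "y_um")])), c(0, 0))
})

test_that("affine fit recovers constructed transforms exactly", {
  # identity
  src <- cbind(c(0, 1000, 0, 700), c(0, 0, 800, 900))
  tf0 <- fit_affine(src, src)
  expect_equal(tf0$A, diag(2), tolerance = 1e-12)
  expect_equal(tf0$b, c(0, 0), tolerance = 1e-9)
  expect_lt(tf0$rms_residual_um, 1e-9)
  # rotation 30 deg, scale 1.2, shift
  th <- 30 * pi / 180
  A <- 1.2 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- c(250, -120)
  set.seed(8)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    repeat {
      pts <- cbind(runif(n, 0, 2000), runif(n, 0, 2000))
      if (qr(cbind(pts, 1))$rank == 3) break
    }
    dst <- t(A %*% t(pts)) + rep(b, each = n)
    tf <- fit_affine(pts, dst)
    expect_equal(tf$A, A, tolerance = 1e-9)
    expect_equal(tf$b, b, tolerance = 1e-6)
    expect_lt(tf$rms_residual_um, 1e-9)
    expect_equal(apply_affine(tf, pts), dst, tolerance = 1e-9)
  }
})

test_that("degenerate landmark sets are rejected", {
  expect_error(fit_affine(cbind(0:1, 0:1), cbind(0:1, 0:1)),
               "underdetermined")
  col <- cbind(c(0, 1, 2), c(0, 1, 2))
  expect_error(fit_affine(col, col), "collinear")
})

test_that("density arithmetic on a single known region", {
  lay <- mea_layout(1, 1)
  act <- data.frame(channel = 1, cls = "IILD_MUA")
  # 12 qualifying cells in a 0.5 mm2 field -> 24 per mm2
  cells <- data.frame(x_um = runif(12, 0, 1000), y_um = runif(12, 0, 500),
                      diam_um = 30, PS6 = 1, NEUN = 1)
  d <- density_by_class(cells, act, lay, field = c(0, 1000, 0, 500))
  expect_equal(d$region_area_mm2, 0.5, tolerance = 1e-9)
  expect_equal(d$n_cells, 12)
  expect_equal(d$density_per_mm2, 24)
  # empty region -> density 0
  d0 <- density_by_class(cells[0, ], act, lay, field = c(0, 1000, 0, 500))
  expect_equal(d0$n_cells, 0)
  expect_equal(d0$density_per_mm2, 0)
  expect_error(density_by_class(cells, act[0, ], lay,
                                field = c(0, 1000, 0, 500)), "activity")
})

test_that("only pS6+/NeuN+ cells above 25 um count as dysmorphic neurons", {
  lay <- mea_layout(1, 1)
  act <- data.frame(channel = 1, cls = "IILD_MUA")
  cells <- data.frame(
    x_um = c(100, 200, 300, 400), y_um = c(100, 100, 100, 100),
    diam_um = c(30, 30, 30, 20),
    PS6 =  c(1, 0, 1, 1),
    NEUN = c(1, 1, 0, 1))
  d <- density_by_class(cells, act, lay, field = c(0, 1000, 0, 1000))
  expect_equal(d$n_cells, 1)  # the small and the single-positive cells drop
})

test_that("class regions partition the field: no double counting", {
  cfg <- small_mea_cfg(seed = 1, duration_s = 5)
  act <- zone_activity(cfg)
  set.seed(31)
  n <- 500
  cells <- data.frame(x_um = runif(n, -500, 4500),
                      y_um = runif(n, -500, 3500),
                      diam_um = runif(n, 20, 40),
                      PS6 = rbinom(n, 1, 0.7), NEUN = rbinom(n, 1, 0.7))
  field <- c(-500, 4500, -500, 3500)
  d <- density_by_class(cells, act, cfg$layout, field = field)
  qualifying <- sum(cells$PS6 == 1 & cells$NEUN == 1 & cells$diam_um > 25)
  expect_equal(sum(d$n_cells), qualifying)
  expect_equal(sum(d$region_area_mm2), 5 * 4, tolerance = 1e-9)
})

test_that("density is invariant to the image pixel scale", {
  # the same physical cells rasterized at two resolutions give one density
  counts <- sapply(c(2, 4), function(upp) {
    cfg <- uniform_cell_cfg(seed = 9, density_mm2 = 40)
    cfg$um_per_px <- upp
    cm <- gen_cell_map(cfg, image = TRUE, channels = "PS6")
    sp <- segmentation_params("otsu", um_per_px = upp, watershed = TRUE,
                              min_area_px2 = 25 / (upp / 2)^2)
    nrow(segment_cells(cm$image[, , 1], sp))
  })
  expect_lt(abs(counts[1] - counts[2]) / counts[1], 0.05)
})
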