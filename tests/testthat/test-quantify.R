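test_that("to_contrast_map applies the conversion elementwise", {
  m <- shift_map(matrix(5.066, 3, 4), pixel_um = 2, origin_um = c(1, 1))
  cm <- to_contrast_map(m)
  expect_true(all(cm$values == 0))
  expect_identical(cm$pixel_um, m$pixel_um)
  expect_identical(cm$origin_um, m$origin_um)
  one <- to_contrast_map(shift_map(matrix(5.3193, 1, 1), 1))
  expect_equal(one$values[1, 1], 0.05, tolerance = 1e-10)
})

test_that("roi_mean averages pixel centres in a half-open rectangle", {
  cmap <- toy_contrast_map(matrix(0.04, 5, 5))
  expect_equal(roi_mean(cmap, rect_roi(0, 0, 10, 10)), 0.04)

  m22 <- toy_contrast_map(matrix(c(0.01, 0.03, 0.02, 0.04), 2, 2))
  expect_equal(roi_mean(m22, rect_roi(0, 0, 4, 4)), 0.025)

  set.seed(31)
  cmap <- toy_contrast_map(matrix(runif(64, 0, 0.08), 8, 8))
  # full-map ROI equals the grid mean exactly
  expect_identical(roi_mean(cmap, rect_roi(0, 0, 16, 16)),
                   mean(cmap$values))
  # half-map and interior ROIs agree with exhaustive enumeration
  for (roi in list(rect_roi(0, 0, 8, 16), rect_roi(3, 5, 7, 6))) {
    expect_equal(roi_mean(cmap, roi), oracle_roi_mean(cmap, roi))
  }
  expect_error(roi_mean(cmap, rect_roi(10, 10, 10, 10)), "outside")
})

test_that("mask_means quantifies cells and ECM with absence flags", {
  regions <- lapply(c("medium", "epidermis", "interstitial", "ecm",
                      "chondrocyte"),
                    function(l) region_spec(l,
                      c(medium = 0.006, epidermis = 0.04,
                        interstitial = 0.03, ecm = 0.06,
                        chondrocyte = 0.045)[[l]], 0))
  ph <- render_digit_phantom(phantom_spec(regions = regions, seed = 2))
  mm <- mask_means(to_contrast_map(ph$map), ph$mask)
  expect_true(mm$has_cells && mm$has_ecm)
  expect_equal(nrow(mm$cells), 13)
  expect_true(all(abs(mm$cells$mean - 0.045) < 1e-12))
  expect_equal(mm$ecm_mean, 0.06, tolerance = 1e-12)
  # weighted reconstruction of the whole-map mean from mask classes
  cm <- to_contrast_map(ph$map)
  cls <- split(as.vector(cm$values), as.vector(ph$mask$labels))
  w <- lengths(cls)
  expect_equal(sum(vapply(cls, mean, 0) * w) / sum(w), mean(cm$values))

  # no chondrocytes: ECM mean only, cells flagged absent
  bud <- development_series(45)[[1]]
  ph2 <- render_digit_phantom(bud)
  mm2 <- mask_means(to_contrast_map(ph2$map), ph2$mask)
  expect_false(mm2$has_cells)
  expect_false(mm2$has_ecm)
  expect_equal(nrow(mm2$cells), 0L)
  expect_true(is.na(mm2$ecm_mean))
})

test_that("transversal profiles average five single-pixel lines", {
  # constant map -> constant profile
  cmap <- toy_contrast_map(matrix(0.05, 20, 40))
  prof <- transversal_profiles(cmap, anchor_um = 20)
  expect_true(all(prof$values == 0.05))
  expect_equal(length(prof$positions), 20)
  expect_equal(attr(prof, "realized_spacing_um"), 4)  # 5 um -> 2 px @ 2 um

  # map varying only along the transversal (y) axis: profile = 1D function
  f <- seq(0.01, 0.06, length.out = 20)
  cmap <- toy_contrast_map(matrix(rep(f, 40), 20, 40))
  prof <- transversal_profiles(cmap, anchor_um = 10)
  expect_equal(prof$values, f)

  # linear gradient along x: profile value = mean over the 5 line columns,
  # verified by brute-force pixel extraction
  g <- matrix(rep(seq(0.01, 0.06, length.out = 40), each = 20), 20, 40)
  cmap <- toy_contrast_map(g)
  prof <- transversal_profiles(cmap, anchor_um = 11)
  cols <- attr(prof, "line_coords_um")
  idx <- match(cols, (seq_len(40) - 0.5) * 2)
  brute <- rowMeans(g[, idx])
  expect_equal(prof$values, brute)

  expect_error(transversal_profiles(cmap, anchor_um = 75), "exceed")
})

test_that("normalize_profile maps edges to +/-100 per the threshold rule", {
  pos <- seq(0, 200, by = 10)
  val <- ifelse(pos >= 40 & pos <= 160, 0.05, 0.001)
  prof <- line_profile(pos, val)
  np <- normalize_profile(prof)
  expect_true(np$normalized)
  expect_equal(min(np$positions), -100)
  expect_equal(max(np$positions), 100)
  # the linear map: 100 um -> 0 %, 160 um -> +100 %, 130 um -> +50 %
  kept <- pos[pos >= 40 & pos <= 160]
  expect_equal(np$positions, (kept - 100) / 60 * 100)
  expect_equal(np$positions[kept == 100], 0)
  expect_equal(np$positions[kept == 130], 50)
  expect_equal(np$values, val[pos >= 40 & pos <= 160])

  # symmetric profile stays symmetric about 0
  sym <- line_profile(seq(-50, 50, 5), 0.05 - (seq(-50, 50, 5) / 1000)^2)
  ns <- normalize_profile(sym)
  expect_equal(ns$positions, -rev(ns$positions))
  expect_equal(ns$values, rev(ns$values))

  # interior sub-threshold dip does not move the edges
  dip <- val
  dip[pos == 100] <- 0.001
  ndip <- normalize_profile(line_profile(pos, dip))
  above <- which(dip >= 0.006)
  expect_equal(range(ndip$positions), c(-100, 100))
  expect_equal(length(ndip$positions), max(above) - min(above) + 1)

  # idempotence and translation invariance
  expect_equal(normalize_profile(np)$positions, np$positions)
  shifted <- line_profile(pos + 37.5, val)
  expect_equal(normalize_profile(shifted)$positions, np$positions)
  expect_equal(normalize_profile(shifted)$values, np$values)

  expect_error(normalize_profile(line_profile(pos, rep(0.001, length(pos)))),
               "no structure")
})

test_that("digit_length_ratio normalizes each digit to its day 0", {
  df <- data.frame(digit = rep(c("amp", "con"), each = 3),
                   timepoint = rep(c(0, 15, 30), 2),
                   length_um = c(100, 40, 80, 100, 106, 112))
  r <- digit_length_ratio(df)
  expect_equal(r$ratio[r$digit == "amp"], c(1.0, 0.4, 0.8))
  # constant growth factor g gives ratio g at each t
  expect_equal(r$ratio[r$digit == "con"], c(1.0, 1.06, 1.12))
  expect_true(all(r$ratio[r$timepoint == 0] == 1))
  expect_error(digit_length_ratio(df[df$timepoint != 0, ]), "day-0")
})
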