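test_that("phantom rendering is a pure function of (spec, seed)", {
  a <- render_digit_phantom(mature_digit_spec(seed = 5))
  b <- render_digit_phantom(mature_digit_spec(seed = 5))
  expect_identical(a$map$values, b$map$values)
  expect_identical(a$mask$labels, b$mask$labels)
  c <- render_digit_phantom(mature_digit_spec(seed = 6))
  expect_false(identical(a$map$values, c$map$values))
})

test_that("label masks partition the grid and realize the geometry", {
  spec <- mature_digit_spec(seed = 9)
  ph <- render_digit_phantom(spec)
  expect_true(all(ph$mask$labels %in% TISSUE_LABELS))
  expect_equal(dim(ph$mask$labels), dim(ph$map$values))
  # all five mature-digit tissues present
  expect_setequal(unique(as.vector(ph$mask$labels)),
                  c("medium", "epidermis", "interstitial", "ecm",
                    "chondrocyte"))
  # layer areas: medium 4 um + epidermis 6 um margins on an 80 um height
  # at 2 um pixels -> 2 and 3 pixel rows per side
  counts <- table(ph$mask$labels)
  expect_equal(unname(counts[["medium"]]), 2 * 2 * 74)
  expect_equal(unname(counts[["epidermis"]]), 2 * 3 * 74)
  expect_equal(unname(counts[["interstitial"]]), 2 * 3 * 74)
  # requested number of distinct cells realized
  expect_equal(max(ph$mask$cell_ids), spec$cell_count)
})

test_that("degenerate specs render flat maps", {
  regions <- lapply(c("medium", "epidermis", "interstitial", "ecm",
                      "chondrocyte"),
                    function(l) region_spec(l, 0.03, 0))
  spec <- phantom_spec(regions = regions, seed = 4)
  ph <- render_digit_phantom(spec)
  expect_equal(diff(range(ph$map$values)), 0)
  expect_equal(unique(as.vector(ph$map$values)),
               contrast_to_shift(0.03))
})

test_that("mask-based region means recover specified means within 3 SE", {
  spec <- mature_digit_spec(seed = 21)
  ph <- render_digit_phantom(spec)
  cm <- to_contrast_map(ph$map)
  for (lab in c("ecm", "chondrocyte", "epidermis", "interstitial",
                "medium")) {
    sel <- ph$mask$labels == lab
    n <- sum(sel)
    r <- spec$regions[[lab]]
    expect_lt(abs(mean(cm$values[sel]) - r$mean_contrast),
              3 * r$sd_contrast / sqrt(n) + 1e-12)
  }
  # mature digit: ECM stiffer than the cells it embeds
  mm <- mask_means(cm, ph$mask)
  expect_gt(mm$ecm_mean, mean(mm$cells$mean))
})

test_that("cell placement failure names the constraint", {
  expect_error(
    render_digit_phantom(phantom_spec(cell_count = 60,
                                      cell_radii_um = c(10, 8))),
    "cells")
})

test_that("collagenase series degrades the ECM monotonically", {
  base <- mature_digit_spec(seed = 2)
  expect_identical(collagenase_series(base, times_min = 0)[[1]]$regions,
                   base$regions)
  ser <- collagenase_series(base)
  ecm <- vapply(ser, function(s) s$regions$ecm$mean_contrast, 0)
  expect_true(all(diff(ecm) < 0))
  # cells stiffen and thin out at 45 min
  expect_gt(ser$`45min`$regions$chondrocyte$mean_contrast,
            ser$`0min`$regions$chondrocyte$mean_contrast)
  expect_lt(ser$`45min`$cell_count, ser$`0min`$cell_count)
  # expected whole-map means strictly decreasing (area-weighted)
  em <- vapply(ser, expected_map_mean, 0)
  expect_true(all(diff(em) < 0))
  expect_warning(collagenase_series(base, ecm_means = c(0.04, 0.05, 0.06)),
                 "not strictly decreasing")
})

test_that("development series is ordered and staged correctly", {
  expect_error(development_series(c(45, 48)), "unknown developmental stage")
  expect_length(development_series(49), 1L)
  ser <- development_series()
  # condensing cartilage core stiffens strictly with stage
  core_mean <- vapply(ser, function(s) {
    r <- s$regions
    if (!is.null(r$ecm)) (r$ecm$mean_contrast + r$chondrocyte$mean_contrast) / 2
    else r$interstitial$mean_contrast
  }, 0)
  expect_true(all(diff(core_mean) > 0))
  # epidermis thickens, never thins
  expect_true(all(diff(vapply(ser, `[[`, 0, "epidermis_um")) >= 0))
  # bud has no cartilage; digit at 53 has a joint, 49 does not
  expect_false("ecm" %in% names(ser$st45$regions))
  expect_null(ser$st49$joint)
  expect_false(is.null(ser$st53$joint))
  lab53 <- render_digit_phantom(ser$st53)$mask$labels
  expect_true("joint" %in% lab53)
  # developing digits: chondrocytes stiffer than immature ECM
  for (s in ser[c("st49", "st51", "st53")])
    expect_gt(s$regions$chondrocyte$mean_contrast,
              s$regions$ecm$mean_contrast)
})

test_that("regeneration series dips then recovers, lengths normalized", {
  ser <- regeneration_series(seed = 8)
  cart <- vapply(ser$specs, function(s)
    (s$regions$ecm$mean_contrast + s$regions$chondrocyte$mean_contrast) / 2,
    0)
  expect_lt(cart[["15dpa"]], cart[["30dpa"]])
  expect_lt(cart[["30dpa"]], cart[["0dpa"]])
  # mature at day 0; dedifferentiated (ECM = cells) at 15 dpa
  expect_gt(ser$specs$`0dpa`$regions$ecm$mean_contrast,
            ser$specs$`0dpa`$regions$chondrocyte$mean_contrast)
  expect_equal(ser$specs$`15dpa`$regions$ecm$mean_contrast,
               ser$specs$`15dpa`$regions$chondrocyte$mean_contrast)
  L <- ser$length_model(4, seed = 8)
  expect_true(all(L$ratio[L$dpa == 0] == 1))
  amp <- sapply(split(L$ratio[L$digit == "amputated"],
                      L$dpa[L$digit == "amputated"]), mean)
  expect_true(all(diff(amp[c("0", "15", "30")][-1]) > 0) || amp[["15"]] < amp[["30"]])
  expect_true(all(L$ratio[L$dpa == 30 & L$digit == "amputated"] <
                    L$ratio[L$dpa == 30 & L$digit == "contralateral"]))
})

test_that("cohort sampling is seeded and additive", {
  sp0 <- cohort_spec(animal_sd = 0, residual_sd = 0, seed = 3)
  co <- sample_cohort(sp0)
  m <- cohort_to_matrix(co)
  for (j in seq_along(sp0$conditions))
    expect_true(all(m[, j] == sp0$condition_effects[j]))
  sp <- cohort_spec(seed = 12)
  expect_identical(sample_cohort(sp), sample_cohort(sp))
  # default collagenase design: complete concordance, Friedman chi2 = 10
  f <- friedman_rank_test(cohort_to_matrix(sample_cohort(sp)))
  expect_equal(f$statistic, 10)
})
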