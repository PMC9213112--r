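concordant_5x3 <- function() {
  matrix(c(9, 6, 3), 5, 3, byrow = TRUE,
         dimnames = list(NULL, c("0min", "30min", "45min"))) +
    matrix(rep(seq(0, 0.4, 0.1), 3), 5, 3)
}

# within-subject ranks: col A always 3; col B = 1,1,1,2; col C = 2,2,2,1
rank_12_5_7_4x3 <- function() {
  matrix(c(3, 1, 2,
           3, 1, 2,
           3, 1, 2,
           3, 2, 1), 4, 3, byrow = TRUE,
         dimnames = list(NULL, c("0dpa", "15dpa", "30dpa")))
}

test_that("midrank averages ties and sums to n(n+1)/2", {
  expect_equal(midrank(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(midrank(c(5, 5, 1)), c(2.5, 2.5, 1))
  set.seed(5)
  for (i in 1:20) {
    v <- sample(1:4, 6, replace = TRUE)
    expect_equal(sum(midrank(v)), 21)
  }
})

test_that("Friedman statistic matches independent oracles", {
  # explicit-loop oracle on random continuous tables
  set.seed(99)
  for (i in 1:200) {
    N <- sample(3:8, 1); k <- sample(2:5, 1)
    tab <- matrix(rnorm(N * k), N, k)
    f <- friedman_rank_test(tab, posthoc = FALSE)
    expect_equal(f$statistic, oracle_friedman_chi2(tab))
    # base-R implementation as a second, independent oracle
    expect_equal(f$statistic,
                 unname(stats::friedman.test(tab)$statistic))
    expect_equal(f$p_value, unname(stats::friedman.test(tab)$p.value))
  }
})

test_that("Friedman is rank-invariant and bounded by concordance", {
  set.seed(7)
  for (i in 1:25) {
    tab <- matrix(rnorm(12), 4, 3)
    f1 <- friedman_rank_test(tab, posthoc = FALSE)$statistic
    f2 <- friedman_rank_test(exp(3 * tab), posthoc = FALSE)$statistic
    expect_identical(f1, f2)
    N <- nrow(tab); k <- ncol(tab)
    expect_lte(f1, N * (k - 1) + 1e-12)
  }
  # equality iff complete concordance; W = 1 there
  f <- friedman_rank_test(concordant_5x3())
  expect_equal(f$statistic, 5 * 2)
  expect_equal(f$effect_size$value, 1)
  # full ties: chi2 = 0, W = 0
  f0 <- friedman_rank_test(matrix(1, 4, 3), posthoc = FALSE)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$effect_size$value, 0)
  expect_error(friedman_rank_test(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)),
               "complete")
})

test_that("chi-squared upper tail has the df = 2 closed form", {
  expect_equal(chisq_upper_tail(0, 2), 1)
  expect_equal(chisq_upper_tail(0, 5), 1)
  set.seed(3)
  x <- runif(100, 0, 30)
  expect_equal(chisq_upper_tail(x, 2), exp(-x / 2), tolerance = 1e-12)
})

test_that("Kendall's W and eta-squared follow their formulas", {
  expect_equal(kendalls_w(10, 5, 3), 1)
  expect_equal(kendalls_w(6.5, 4, 3), 0.8125)
  expect_equal(round(kendalls_w(6.5, 4, 3), 2), 0.81)
  expect_equal(kendalls_w(0, 7, 4), 0)
  expect_equal(kw_eta_squared(15.21273, 5, 23), 0.62, tolerance = 0.005)
  expect_equal(kw_eta_squared(4, 5, 23), 0)
  expect_gt(kw_eta_squared(10, 5, 23), kw_eta_squared(5, 5, 23))
})

test_that("Dunn's Friedman post hoc reproduces printed adjusted p-values", {
  ph <- dunn_friedman_posthoc(concordant_5x3())
  extreme <- ph[ph$pair_i == "0min" & ph$pair_j == "45min", ]
  expect_equal(extreme$z, 2 / sqrt(12 / 30))
  expect_equal(extreme$p_adjusted, 0.0047, tolerance = 1e-3)

  ph2 <- dunn_friedman_posthoc(rank_12_5_7_4x3())
  extreme2 <- ph2[ph2$pair_i == "0dpa" & ph2$pair_j == "15dpa", ]
  expect_equal(extreme2$z, 1.75 / sqrt(0.5))
  expect_equal(extreme2$p_adjusted, 0.03998, tolerance = 2e-5 / 0.03998)

  # identical conditions: every adjusted p is 1
  same <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)
  expect_true(all(dunn_friedman_posthoc(same)$p_adjusted == 1))
  # adjusted >= raw, all within [0, 1]
  expect_true(all(ph2$p_adjusted >= ph2$p))
  expect_true(all(ph2$p >= 0 & ph2$p_adjusted <= 1))
})

test_that("Kruskal-Wallis matches base R with and without ties", {
  # two fully separated groups of two: printed formula gives 2.4
  kw <- kruskal_wallis_test(list(c(1, 2), c(3, 4)), posthoc = FALSE)
  expect_equal(kw$statistic, 2.4)
  expect_equal(kw$statistic,
               unname(stats::kruskal.test(list(c(1, 2), c(3, 4)))$statistic))
  set.seed(17)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    gs <- lapply(seq_len(k), function(j)
      sample(1:6, sample(3:7, 1), replace = TRUE))  # heavy ties
    if (length(unique(unlist(gs))) < 2) next
    kw <- kruskal_wallis_test(gs, posthoc = FALSE)
    ref <- stats::kruskal.test(gs)
    expect_equal(kw$statistic, unname(ref$statistic))
    expect_equal(kw$p_value, unname(ref$p.value))
  }
  # all observations equal -> H = 0
  expect_equal(kruskal_wallis_test(list(c(2, 2), c(2, 2, 2)),
                                   posthoc = FALSE)$statistic, 0)
})

test_that("Dunn's Kruskal-Wallis post hoc follows the z formula", {
  gs <- list(a = c(1, 2, 3, 4), b = c(5, 6, 7, 8))
  ph <- dunn_kw_posthoc(gs)
  # brute-force evaluation: rank means 2.5 vs 6.5, var term N(N+1)/12
  z_expect <- abs(2.5 - 6.5) / sqrt((8 * 9 / 12) * (1 / 4 + 1 / 4))
  expect_equal(ph$z, z_expect)
  # identical groups: p = 1
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_true(all(dunn_kw_posthoc(same)$p_adjusted == 1))
  # a larger monotone shift increases z for the extreme pair
  z1 <- dunn_kw_posthoc(list(1:4, 1:4 + 2, 1:4 + 4))
  z2 <- dunn_kw_posthoc(list(1:4, 1:4 + 4, 1:4 + 8))
  expect_gte(z2$z[2], z1$z[2])
})

test_that("exact Mann-Whitney agrees with enumeration and base R", {
  for (nx in 2:6) {
    for (ny in 2:6) {
      set.seed(nx * 10 + ny)
      x <- rnorm(nx); y <- rnorm(ny, 1)
      mw <- mann_whitney_exact(x, y)
      expect_equal(mw$statistic, oracle_mw_u(x, y))
      expect_equal(mw$p_value, oracle_mw_p(x, y))
      ref <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(mw$p_value, unname(ref$p.value))
    }
  }
  # identical samples: U = n^2/2, p capped at 1
  mw <- mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw$statistic, 4.5)
  expect_equal(mw$p_value, 1)
  expect_equal(mw$z, 0)
  # rank invariance under monotone transforms
  set.seed(23)
  x <- rnorm(5); y <- rnorm(4)
  expect_equal(mann_whitney_exact(x, y)$p_value,
               mann_whitney_exact(exp(x), exp(y))$p_value)
  expect_error(mann_whitney_exact(numeric(0), 1:3), "non-empty")
})

test_that("large-sample Mann-Whitney falls back to the normal Z", {
  set.seed(4)
  x <- rnorm(15); y <- rnorm(15, 0.5)
  mw <- mann_whitney_exact(x, y)
  expect_false(mw$exact)
  expect_equal(mw$p_value, min(1, 2 * pnorm(-abs(mw$z))))
})

test_that("Student's t-test matches the pooled-variance formula", {
  t0 <- students_t_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  tt <- students_t_two_sample(c(0, 1), c(10, 11))
  ref <- stats::t.test(c(0, 1), c(10, 11), var.equal = TRUE)
  expect_equal(tt$statistic, unname(ref$statistic))
  expect_equal(tt$p_value, ref$p.value)
  expect_equal(tt$df, 2)
  sw <- students_t_two_sample(c(10, 11), c(0, 1))
  expect_equal(sw$statistic, -tt$statistic)
  expect_equal(sw$p_value, tt$p_value)
  expect_error(students_t_two_sample(c(1, 1), c(1, 1)), "degenerate")
})

test_that("Chen-Shapiro QH is affine-invariant and calibrated", {
  set.seed(61)
  x <- rnorm(30)
  expect_equal(chen_shapiro_qh(3 * x + 7), chen_shapiro_qh(x),
               tolerance = 1e-12)
  # large normal sample sits near the Monte-Carlo null median
  set.seed(62)
  big <- rnorm(500)
  cs <- chen_shapiro(big)
  expect_false(cs$reject)
  expect_lt(abs(cs$qh - 1), 0.05)
  # two-point degenerate-heavy sample lands in the rejection tail
  bad <- c(rep(0, 12), rep(1, 12)) + rnorm(24, 0, 1e-6)
  expect_true(chen_shapiro(bad)$reject)
  expect_error(chen_shapiro_qh(c(1, 2, 3)), "n >= 4")
  expect_error(chen_shapiro_qh(rep(2, 10)), "zero-variance")
})

test_that("analysis_policy routes designs per the small-sample rule", {
  rm5x3 <- concordant_5x3()
  pol <- analysis_policy(rm5x3)
  expect_equal(pol$test, "friedman_rank_test")
  expect_match(pol$reason, "<= 30")
  pol2 <- analysis_policy(list(rnorm(4), rnorm(4)))
  expect_equal(pol2$test, "mann_whitney_exact")
  pol3 <- analysis_policy(list(rnorm(12), rnorm(12), rnorm(11)))
  expect_equal(pol3$test, "kruskal_wallis_test")
  # n = 40, normality passes: parametric branch
  set.seed(77)
  pol4 <- analysis_policy(list(rnorm(20), rnorm(20)))
  expect_equal(pol4$test, "students_t_two_sample")
  expect_match(pol4$reason, "parametric")
})

test_that("Friedman chi-square approximation has documented type-I error", {
  # property of the approximation at the collagenase design size
  # (N_A = 5, k = 3): the discrete exact null makes the nominal 5% level
  # conservative; the documented band is [0.02, 0.06]
  set.seed(314)
  n_sim <- 10000L
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    rej[i] <- friedman_rank_test(matrix(rnorm(15), 5, 3),
                                 posthoc = FALSE)$p_value < 0.05
  }
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.06)
})

test_that("test results serialize to JSON with all fields", {
  f <- friedman_rank_test(concordant_5x3())
  p <- withr::local_tempfile(fileext = ".json")
  write_test_json(f, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$statistic, 10)
  expect_equal(back$effect_size$value, 1)
  expect_equal(nrow(back$posthoc), 3)
})
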