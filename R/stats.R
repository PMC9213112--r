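#' Result container for the statistics suite
#'
#' Every test in the suite returns a `brillouin_test` object carrying the
#' statistic, its degrees of freedom, the p-value, the associated effect
#' size and any post hoc pair results, so reports can be serialized as JSON
#' without loss.
#'
#' @param statistic_name Name of the test statistic (e.g. `"chi-squared"`).
#' @param statistic Value of the statistic.
#' @param df Degrees of freedom (`NA` when not applicable).
#' @param p_value Two-sided p-value in \[0, 1\].
#' @param effect_size Named list `list(name =, value =)` or `NULL`.
#' @param posthoc `data.frame` of pairwise results or `NULL`.
#' @param method Human-readable method string.
#' @param n Named list of sample sizes.
#' @return An object of class `brillouin_test`.
#' @keywords internal
new_test_result <- function(statistic_name, statistic, df, p_value,
                            effect_size = NULL, posthoc = NULL,
                            method = statistic_name, n = list()) {
  stopifnot(p_value >= 0, p_value <= 1)
  if (!is.null(posthoc) && nrow(posthoc)) {
    stopifnot(all(posthoc$p_adjusted >= posthoc$p - 1e-15),
              all(posthoc$p_adjusted <= 1))
  }
  structure(list(statistic_name = statistic_name,
                 statistic = statistic, df = df, p_value = p_value,
                 effect_size = effect_size, posthoc = posthoc,
                 method = method, n = n),
            class = "brillouin_test")
}

#' @export
print.brillouin_test <- function(x, digits = 5, ...) {
  cat("\n\t", x$method, "\n\n")
  cat(sprintf("%s = %s", x$statistic_name,
              format(x$statistic, digits = digits)))
  if (!is.na(x$df)) cat(sprintf(", df = %g", x$df))
  cat(sprintf(", p = %s\n", format(x$p_value, digits = digits)))
  if (!is.null(x$effect_size))
    cat(sprintf("effect size %s = %s\n", x$effect_size$name,
                format(x$effect_size$value, digits = digits)))
  if (!is.null(x$posthoc) && nrow(x$posthoc)) {
    cat("post hoc (Dunn, Bonferroni):\n")
    print(x$posthoc, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Midranks
#'
#' Ranks with ties resolved by averaging (midranks), the rank basis used by
#' every nonparametric test in the suite. Ranks always sum to
#' \eqn{n(n+1)/2}.
#'
#' @param values Numeric vector.
#' @return Numeric vector of midranks.
#' @export
midrank <- function(values) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  rank(values, ties.method = "average")
}

#' Upper tail of the chi-squared distribution
#'
#' Survival function \eqn{P(X \ge x)} for \eqn{X \sim \chi^2_{df}}; the
#' p-value backend for the Friedman and Kruskal-Wallis tests. For
#' `df = 2` it equals \eqn{e^{-x/2}} exactly.
#'
#' @param x Statistic value, `x >= 0`.
#' @param df Degrees of freedom, positive.
#' @return Upper-tail probability.
#' @export
chisq_upper_tail <- function(x, df) {
  stopifnot(is.numeric(x), all(x >= 0), df > 0)
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

.as_rm_matrix <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("repeated-measures table must be complete and numeric",
         call. = FALSE)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  m
}

#' Friedman rank test for repeated measures
#'
#' Nonparametric one-way ANOVA for complete repeated-measures designs:
#' values are midranked within each subject and the statistic
#' \deqn{\chi^2 = \frac{12}{N k (k+1)} \sum_j R_j^2 - 3 N (k+1)}
#' (with \eqn{N} subjects, \eqn{k} conditions, \eqn{R_j} the rank sum of
#' condition \eqn{j}) is referred to the chi-squared distribution with
#' \eqn{k-1} degrees of freedom. The chi-squared approximation (rather than
#' an exact permutation null) is deliberate: it is the small-sample
#' convention of the original analyses this suite reproduces. Kendall's W
#' is attached as effect size.
#'
#' @param table Numeric matrix or data.frame, subjects in rows, conditions
#'   in columns; no missing cells.
#' @param posthoc If `TRUE` (default), attach Dunn's post hoc pairwise
#'   comparisons with Bonferroni adjustment.
#' @return A `brillouin_test` with `statistic_name = "chi-squared"`,
#'   `df = k - 1`, Kendall's W effect size and (optionally) post hoc table.
#' @seealso [kendalls_w()], [dunn_friedman_posthoc()]
#' @examples
#' # complete concordance, 5 subjects x 3 conditions: chi2 = 10, W = 1
#' tab <- matrix(c(3, 2, 1), 5, 3, byrow = TRUE) + stats::rnorm(15, 0, 1e-3)
#' tab <- t(apply(matrix(seq_len(15), 5, 3), 1, function(i) c(3, 2, 1)))
#' friedman_rank_test(tab)
#' @export
friedman_rank_test <- function(table, posthoc = TRUE) {
  m <- .as_rm_matrix(table)
  N <- nrow(m); k <- ncol(m)
  ranks <- t(apply(m, 1L, midrank))
  Rj <- colSums(ranks)
  chi2 <- 12 / (N * k * (k + 1)) * sum(Rj^2) - 3 * N * (k + 1)
  chi2 <- max(chi2, 0)
  p <- chisq_upper_tail(chi2, df = k - 1L)
  W <- kendalls_w(chi2, N_A = N, k = k)
  ph <- if (posthoc) dunn_friedman_posthoc(m) else NULL
  new_test_result("chi-squared", chi2, df = k - 1L, p_value = p,
                  effect_size = list(name = "Kendall's W", value = W),
                  posthoc = ph,
                  method = "Friedman rank ANOVA for repeated measures",
                  n = list(N_A = N, k = k))
}

#' Kendall's W effect size for the Friedman test
#'
#' \eqn{W = \chi^2 / (N_A (k - 1))}, the coefficient of concordance
#' recovered from the Friedman statistic; \eqn{W \in [0, 1]} with
#' \eqn{W = 1} iff all subjects rank the conditions identically.
#'
#' @param chi2 Friedman chi-squared statistic.
#' @param N_A Number of subjects (animals).
#' @param k Number of conditions.
#' @return Kendall's W.
#' @export
kendalls_w <- function(chi2, N_A, k) {
  stopifnot(chi2 >= 0, N_A >= 2, k >= 2)
  chi2 / (N_A * (k - 1))
}

#' Dunn's post hoc test after a Friedman test
#'
#' For each condition pair \eqn{(i, j)} compares mean within-subject ranks:
#' \deqn{z = |\bar R_i - \bar R_j| / \sqrt{k (k+1) / (6 N_A)},}
#' two-sided normal p-value, Bonferroni-multiplied by the number of pairs
#' \eqn{k(k-1)/2} and capped at 1. Pairs are reported in condition order.
#'
#' @inheritParams friedman_rank_test
#' @return `data.frame` with columns `pair_i`, `pair_j`, `z`, `p`,
#'   `p_adjusted`.
#' @export
dunn_friedman_posthoc <- function(table) {
  m <- .as_rm_matrix(table)
  N <- nrow(m); k <- ncol(m)
  cond <- colnames(m)
  if (is.null(cond)) cond <- as.character(seq_len(k))
  ranks <- t(apply(m, 1L, midrank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * N))
  n_pairs <- k * (k - 1) / 2
  out <- do.call(rbind, lapply(seq_len(k - 1L), function(i) {
    do.call(rbind, lapply(seq.int(i + 1L, k), function(j) {
      z <- abs(rbar[i] - rbar[j]) / se
      p <- 2 * stats::pnorm(-z)
      data.frame(pair_i = cond[i], pair_j = cond[j], z = z, p = p,
                 p_adjusted = min(1, p * n_pairs),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

.as_group_list <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  lapply(groups, function(g) {
    if (!is.numeric(g) || length(g) < 1L || any(!is.finite(g)))
      stop("each group must be a non-empty finite numeric vector",
           call. = FALSE)
    g
  })
}

# tie-correction term sum(t^3 - t) over tied groups of the pooled sample
.tie_term <- function(pooled) {
  t <- table(pooled)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank test for independent groups
#'
#' Pooled midranks across \eqn{k} independent groups;
#' \deqn{H = \left[\frac{12}{N(N+1)} \sum_i R_i^2/n_i - 3(N+1)\right] \Big/
#'   \left[1 - \sum (t^3 - t) / (N^3 - N)\right]}
#' with the standard tie-correction divisor; p from the chi-squared upper
#' tail with \eqn{k-1} degrees of freedom. The rank eta-squared effect size
#' is attached.
#'
#' @param groups List of \eqn{k \ge 2} numeric vectors (independent
#'   samples). Names, if present, label the post hoc pairs.
#' @param posthoc Attach Dunn's pairwise comparisons (default `TRUE`).
#' @return A `brillouin_test` with statistic `H`, `df = k - 1`, eta-squared
#'   effect size.
#' @seealso [kw_eta_squared()], [dunn_kw_posthoc()]
#' @export
kruskal_wallis_test <- function(groups, posthoc = TRUE) {
  gs <- .as_group_list(groups)
  k <- length(gs)
  n <- lengths(gs)
  N <- sum(n)
  pooled <- unlist(gs, use.names = FALSE)
  r <- midrank(pooled)
  Ri <- vapply(split(r, rep(seq_len(k), n)), sum, numeric(1))
  H <- 12 / (N * (N + 1)) * sum(Ri^2 / n) - 3 * (N + 1)
  corr <- 1 - .tie_term(pooled) / (N^3 - N)
  if (corr <= 0) {
    # every pooled observation tied: uncorrected H is exactly 0
    if (abs(H) > 1e-12)
      stop("degenerate ties leave H undefined", call. = FALSE)
    H <- 0
  } else {
    H <- max(H / corr, 0)
  }
  p <- chisq_upper_tail(H, df = k - 1L)
  eta2 <- kw_eta_squared(H, k = k, N = N)
  ph <- if (posthoc) dunn_kw_posthoc(gs) else NULL
  new_test_result("H", H, df = k - 1L, p_value = p,
                  effect_size = list(name = "eta-squared", value = eta2),
                  posthoc = ph,
                  method = "Kruskal-Wallis rank ANOVA for independent samples",
                  n = list(N = N, k = k, n_i = as.list(n)))
}

#' Rank eta-squared effect size for the Kruskal-Wallis test
#'
#' \eqn{\eta^2 = (H - k + 1) / (N - k)}. Can be slightly negative when
#' \eqn{H < k - 1} (small-sample noise below the null expectation); it is
#' reported as computed, not clipped.
#'
#' @param H Kruskal-Wallis statistic.
#' @param k Number of groups.
#' @param N Total number of observations.
#' @return Eta-squared.
#' @export
kw_eta_squared <- function(H, k, N) {
  stopifnot(H >= 0, k >= 2, N > k)
  (H - k + 1) / (N - k)
}

#' Dunn's post hoc test after a Kruskal-Wallis test
#'
#' For groups \eqn{(i, j)}:
#' \deqn{z = |\bar R_i - \bar R_j| \Big/ \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum(t^3 - t)}{12 (N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#' with pooled midranks and tie correction; two-sided normal p, Bonferroni
#' over all \eqn{k(k-1)/2} pairs.
#'
#' @inheritParams kruskal_wallis_test
#' @return `data.frame` with columns `pair_i`, `pair_j`, `z`, `p`,
#'   `p_adjusted`.
#' @export
dunn_kw_posthoc <- function(groups) {
  gs <- .as_group_list(groups)
  k <- length(gs)
  n <- lengths(gs)
  N <- sum(n)
  nm <- names(gs)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  pooled <- unlist(gs, use.names = FALSE)
  r <- midrank(pooled)
  rbar <- vapply(split(r, rep(seq_len(k), n)), mean, numeric(1))
  var_term <- N * (N + 1) / 12 - .tie_term(pooled) / (12 * (N - 1))
  n_pairs <- k * (k - 1) / 2
  out <- do.call(rbind, lapply(seq_len(k - 1L), function(i) {
    do.call(rbind, lapply(seq.int(i + 1L, k), function(j) {
      se <- sqrt(var_term * (1 / n[i] + 1 / n[j]))
      z <- abs(rbar[i] - rbar[j]) / se
      p <- 2 * stats::pnorm(-z)
      data.frame(pair_i = nm[i], pair_j = nm[j], z = z, p = p,
                 p_adjusted = min(1, p * n_pairs),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Exact Mann-Whitney U test
#'
#' Two-sample rank test reporting \eqn{U = \min(U_x, U_y)} from midranks, an
#' exact two-sided p-value by complete enumeration of all
#' \eqn{\binom{n_x + n_y}{n_x}} group labelings (the one-sided tail
#' probability \eqn{P(U \le U_{obs})} doubled and capped at 1), and the
#' continuity-corrected standardized score
#' \deqn{Z = \frac{U - n_x n_y / 2 \pm 0.5}{\sqrt{n_x n_y (n_x + n_y + 1)/12}}}
#' with the 0.5 correction applied toward the mean. Enumeration is used up
#' to \eqn{n_x + n_y \le 20}; beyond that the normal approximation on the
#' same Z is reported. The effect size \eqn{r = |Z|/\sqrt{N}} is attached
#' with \eqn{N = n_x + n_y}.
#'
#' @param x,y Non-empty numeric samples.
#' @return A `brillouin_test` with statistic `U`, `df = NA`, `Z` stored in
#'   `$z`, and effect size `r`.
#' @export
mann_whitney_exact <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("samples must be finite", call. = FALSE)
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  r <- midrank(pooled)
  Ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  Uy <- nx * ny - Ux
  U <- min(Ux, Uy)
  mu <- nx * ny / 2
  sigma <- sqrt(nx * ny * (N + 1) / 12)
  cc <- if (U < mu) 0.5 else if (U > mu) -0.5 else 0
  Z <- (U - mu + cc) / sigma
  exact <- N <= 20L
  if (exact) {
    # complete enumeration of group labelings: null distribution of the
    # x-group statistic U_x; two-sided p doubles the lower tail at
    # U = min(U_x, U_y) (the U_x null is symmetric about n_x n_y / 2)
    combos <- utils::combn(N, nx)
    us <- apply(combos, 2L, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
    p <- min(1, 2 * mean(us <= U + 1e-12))
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(Z)))
  }
  res <- new_test_result("U", U, df = NA_real_, p_value = p,
                         effect_size = list(name = "r",
                                            value = effect_size_r(Z, N)),
                         method = if (exact)
                           "Exact Mann-Whitney U test (full enumeration)"
                         else
                           "Mann-Whitney U test (normal approximation)",
                         n = list(n_x = nx, n_y = ny, N = N))
  res$z <- Z
  res$exact <- exact
  res
}

#' Effect size r for the Mann-Whitney test
#'
#' \eqn{r = |Z| / \sqrt{N}} with \eqn{N} the total observation count across
#' both groups. Reported at full precision.
#'
#' @param Z Standardized test statistic.
#' @param N Total number of observations.
#' @return Effect size `r >= 0`.
#' @export
effect_size_r <- function(Z, N) {
  stopifnot(is.finite(Z), N >= 1)
  abs(Z) / sqrt(N)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classic pooled-variance two-sided t-test with
#' \eqn{df = n_x + n_y - 2}; the parametric branch used when sample sizes
#' permit a normality assessment that does not reject.
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @return A `brillouin_test` with statistic `t`.
#' @export
students_t_two_sample <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 2L, length(y) >= 2L,
            all(is.finite(x)), all(is.finite(y)))
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 <= 0)
    stop("degenerate input: pooled variance is zero", call. = FALSE)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * stats::pt(-abs(t), df = df)
  new_test_result("t", t, df = df, p_value = p,
                  method = "Two-sample Student's t-test (pooled variance)",
                  n = list(n_x = nx, n_y = ny))
}

# Monte-Carlo null quantile cache for the Chen-Shapiro statistic.
# 1e4 standard-normal samples per n, fixed seed; location-scale invariance
# of QH makes the standard normal the full null.
.cs_cache <- new.env(parent = emptyenv())
.cs_null_sample <- function(n, n_sim = 10000L, seed = 20220078L) {
  key <- sprintf("n%d_s%d_k%d", n, n_sim, seed)
  if (!is.null(.cs_cache[[key]])) return(.cs_cache[[key]])
  qh <- withr_local_seed(seed, {
    vapply(seq_len(n_sim),
           function(i) chen_shapiro_qh(stats::rnorm(n)), numeric(1))
  })
  .cs_cache[[key]] <- qh
  qh
}

# evaluate `code` under a temporary RNG seed, restoring global RNG state
withr_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Chen-Shapiro statistic QH
#'
#' Normality statistic based on normalized spacings of the order statistics:
#' \deqn{QH = \frac{1}{(n-1) s} \sum_{i=1}^{n-1}
#'   \frac{x_{(i+1)} - x_{(i)}}{M_{i+1} - M_i},}
#' where \eqn{M_i = \Phi^{-1}((i - 3/8)/(n + 1/4))} are Blom plotting
#' positions and \eqn{s} the sample standard deviation. QH is
#' location-scale invariant and close to 1 for normal samples; departures
#' from normality shrink it.
#'
#' @param x Numeric sample, `n >= 4`, non-degenerate.
#' @return The QH statistic.
#' @export
chen_shapiro_qh <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  if (n < 4L) stop("Chen-Shapiro requires n >= 4", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance sample", call. = FALSE)
  xs <- sort(x)
  i <- seq_len(n)
  M <- stats::qnorm((i - 3 / 8) / (n + 1 / 4))
  sum(diff(xs) / diff(M)) / ((n - 1) * s)
}

#' Chen-Shapiro normality test
#'
#' Computes [chen_shapiro_qh()] and rejects normality when QH falls below
#' the `alpha` quantile of its Monte-Carlo null distribution (10^4
#' standard-normal samples of the same size, fixed internal seed 20220078,
#' cached per sample size within the session).
#'
#' @param x Numeric sample, `n >= 4`.
#' @param alpha Significance level (default 0.05).
#' @return List with `qh`, `critical` (the lower alpha null quantile),
#'   `reject` flag, `n` and `alpha`.
#' @export
chen_shapiro <- function(x, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  qh <- chen_shapiro_qh(x)
  null_qh <- .cs_null_sample(length(x))
  crit <- stats::quantile(null_qh, probs = alpha, names = FALSE,
                          type = 7)
  list(qh = qh, critical = crit, reject = qh < crit, n = length(x),
       alpha = alpha)
}

#' Choose the analysis branch for a dataset
#'
#' Encodes the suite's decision rule: with small samples
#' (\eqn{n \le 30}) or when the Chen-Shapiro screen rejects normality,
#' analysis proceeds nonparametrically — Friedman for complete
#' repeated-measures tables, Mann-Whitney for two independent groups,
#' Kruskal-Wallis for three or more. Otherwise the parametric t-test branch
#' is chosen (two-group case). The returned descriptor records the decision
#' and its reason.
#'
#' @param data Either a numeric matrix/data.frame (interpreted as a
#'   complete repeated-measures table, subjects x conditions) or a list of
#'   numeric vectors (independent groups).
#' @param alpha Significance level for the normality screen.
#' @return List with `design`, `test`, `reason`, `n`.
#' @export
analysis_policy <- function(data, alpha = 0.05) {
  if (is.matrix(data) || is.data.frame(data)) {
    m <- .as_rm_matrix(data)
    n <- length(m)
    design <- "repeated_measures"
    values <- as.vector(m)
  } else {
    gs <- .as_group_list(data)
    n <- sum(lengths(gs))
    design <- if (length(gs) == 2L) "two_independent_groups"
              else "independent_groups"
    values <- unlist(gs, use.names = FALSE)
  }
  small <- n <= 30L
  normal_reject <- if (!small && length(values) >= 4L)
    chen_shapiro(values, alpha = alpha)$reject else NA
  nonparametric <- small || isTRUE(normal_reject)
  test <- if (nonparametric) {
    switch(design,
           repeated_measures = "friedman_rank_test",
           two_independent_groups = "mann_whitney_exact",
           independent_groups = "kruskal_wallis_test")
  } else {
    # parametric branch exists only for two-sample comparisons; designs
    # with >= 3 groups stay on ranks (no parametric ANOVA in this suite)
    switch(design,
           repeated_measures = "students_t_two_sample",
           two_independent_groups = "students_t_two_sample",
           independent_groups = "kruskal_wallis_test")
  }
  reason <- if (small)
    sprintf("n = %d <= 30: normality not assessable, nonparametric branch", n)
  else if (isTRUE(normal_reject))
    "Chen-Shapiro rejected normality: nonparametric branch"
  else if (design == "independent_groups")
    "n > 30 and normality not rejected, but >= 3 groups: rank ANOVA"
  else
    "n > 30 and normality not rejected: parametric branch"
  list(design = design, test = test, reason = reason, n = n)
}

#' Serialize a test result as JSON
#'
#' @param result A `brillouin_test`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_test_json <- function(result, path) {
  stopifnot(inherits(result, "brillouin_test"))
  out <- unclass(result)
  out$df <- if (is.na(out$df)) NULL else out$df
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
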