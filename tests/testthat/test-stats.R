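# Independent oracles used below: a sort-based quantile computation, the
# rank-sum closed form of the Kruskal-Wallis H statistic, brute-force
# concordant/discordant pair counting for Kendall's tau, and ANOVA mean
# squares from lm() for the ICC.

kw_h_oracle <- function(groups) {
  v <- unlist(groups); r <- rank(v)
  n <- length(v)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(v)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

tau_b_oracle <- function(x, y) {
  n <- length(x); C <- D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  tie_term <- function(v) { t <- table(v); sum(t * (t - 1) / 2) }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tie_term(x)) * (n0 - tie_term(y)))
}

test_that("median and quartiles match a sort-based oracle", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)),
               c(median = 3, q1 = 2, q3 = 4))
  expect_equal(median_iqr(7), c(median = 7, q1 = 7, q3 = 7))
  expect_error(median_iqr(numeric(0)), "empty")
  set.seed(41)
  for (i in 1:20) {
    v <- rnorm(sample(1:60, 1))
    got <- median_iqr(v)
    s <- sort(v)
    expect_equal(unname(got["median"]), median(s))
    expect_equal(unname(got[c("q1", "q3")]),
                 unname(quantile(s, c(0.25, 0.75), type = 7)))
  }
})

test_that("KS test handles identical and disjoint samples", {
  eq <- ks_two_sample(1:8, 1:8)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  dis <- ks_two_sample(1:8, 101:110)
  expect_equal(dis$statistic, 1)
  expect_lt(dis$p, 0.01)
  expect_error(ks_two_sample(1, 1:5), "n >= 2")
})

test_that("Kruskal-Wallis H equals the rank closed form", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(6, 7, 8, 9, 10),
            c = c(11, 12, 13, 14, 15))
  out <- kruskal_wallis_pairwise(g)
  expect_equal(out$statistic, 12.5)       # hand computation
  expect_equal(out$statistic, kw_h_oracle(g))
  set.seed(43)
  for (i in 1:10) {
    g2 <- list(x = sample(20, 6, TRUE), y = sample(20, 8, TRUE),
               z = sample(20, 5, TRUE))
    expect_equal(kruskal_wallis_pairwise(g2)$statistic, kw_h_oracle(g2))
  }
})

test_that("pairwise comparisons are Bonferroni-adjusted and capped", {
  g <- list(a = c(1, 1, 2, 2), b = c(1, 1, 2, 2), c = c(1, 2, 1, 2))
  out <- kruskal_wallis_pairwise(g)
  for (pw in out$pairwise) {
    expect_equal(pw$adjusted_p, min(1, pw$p * 3))
    expect_lte(pw$adjusted_p, 1)
  }
  # all values identical: overall and pairwise p = 1
  same <- kruskal_wallis_pairwise(list(a = c(3, 3), b = c(3, 3),
                                       c = c(3, 3)))
  expect_equal(same$p, 1)
  expect_true(all(vapply(same$pairwise, `[[`, numeric(1),
                         "adjusted_p") == 1))
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 4, 7), 2))$p, 1)
  # [[5,0],[0,5]]: 2/choose(10,5) = 2/252
  p <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p
  expect_equal(p, 2 / 252)
  # symmetry under transposition
  tab <- matrix(c(7, 2, 3, 9), 2)
  expect_equal(fisher_exact_2x2(tab)$p, fisher_exact_2x2(t(tab))$p)
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 1), 2)),
               "non-negative")
})

test_that("Kendall tau matches brute-force pair counting", {
  expect_equal(kendall_tau_ci(1:6, 2 * (1:6), n_boot = 50)$tau, 1)
  expect_equal(kendall_tau_ci(1:6, rev(1:6), n_boot = 50)$tau, -1)
  set.seed(47)
  for (i in 1:10) {
    x <- sample(8, 10, TRUE); y <- sample(8, 10, TRUE)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
    expect_equal(kendall_tau_ci(x, y, n_boot = 10)$tau, tau_b_oracle(x, y))
  }
  # constant input: tau undefined, reported missing
  expect_true(is.na(kendall_tau_ci(rep(1, 5), 1:5)$tau))
})

test_that("bootstrap CI is seeded, reproducible and contains tau", {
  set.seed(53)
  x <- rnorm(15); y <- x + rnorm(15)
  a <- kendall_tau_ci(x, y, n_boot = 500, seed = 7)
  b <- kendall_tau_ci(x, y, n_boot = 500, seed = 7)
  expect_identical(a, b)
  expect_lte(a$ci_lower, a$tau)
  expect_gte(a$ci_upper, a$tau)
  c2 <- kendall_tau_ci(x, y, n_boot = 500, seed = 8)
  expect_false(identical(a$ci_lower, c2$ci_lower))
})

test_that("ICC matches the ANOVA mean-squares oracle", {
  a <- c(4, 5, 6, 8, 7, 3); b <- c(5, 6, 7, 9, 9, 4)
  # frozen from the lm()-based ANOVA oracle on this 6-subject table
  expect_equal(icc_two_observers(a, b)$icc, 0.83516484, tolerance = 1e-7)
  expect_equal(icc_two_observers(a, b, form = "ICC3")$icc, 0.97854077,
               tolerance = 1e-7)
  df <- data.frame(y = c(a, b), subj = factor(rep(1:6, 2)),
                   obs = factor(rep(1:2, each = 6)))
  av <- anova(lm(y ~ subj + obs, df))
  msr <- av["subj", "Mean Sq"]; msc <- av["obs", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  expect_equal(icc_two_observers(a, b)$icc,
               (msr - mse) / (msr + mse + 2 * (msc - mse) / 6))
  expect_equal(icc_two_observers(a, a)$icc, 1)
})

test_that("uncorrelated noisy ratings give near-zero ICC", {
  set.seed(59)
  vals <- vapply(1:100, function(i) {
    a <- rnorm(10)
    icc_two_observers(a, rnorm(10, sd = 10))$icc
  }, numeric(1))
  expect_lt(mean(vals), 0.2)
})

test_that("reported p-values always lie in the unit interval", {
  set.seed(61)
  for (i in 1:25) {
    g <- list(a = rnorm(5), b = rnorm(7), c = rnorm(4))
    kw <- kruskal_wallis_pairwise(g)
    ps <- c(kw$p, vapply(kw$pairwise, `[[`, numeric(1), "p"),
            vapply(kw$pairwise, `[[`, numeric(1), "adjusted_p"),
            ks_two_sample(g$a, g$b)$p)
    expect_true(all(ps >= 0 & ps <= 1))
  }
})
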