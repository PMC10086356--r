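#' Median and interquartile range
#'
#' Cohort variables are non-Gaussian, so they are summarized as median
#' (IQR). Quartiles use the standard linear-interpolation definition
#' (`stats::quantile` type 7).
#'
#' @param values numeric vector, n >= 1, NAs removed.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @examples
#' median_iqr(c(1, 2, 3, 4, 5))
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("median_iqr: empty input")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

new_group_comparison <- function(test, groups, statistic, p, adjusted_p = NA,
                                 method = NA_character_, n = NULL) {
  structure(list(test = test, groups = groups, statistic = statistic,
                 p = p, adjusted_p = adjusted_p,
                 adjustment_method = method, n = n),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$test, " (",
      paste(x$groups, collapse = " vs "), ")\n", sep = "")
  cat(sprintf("  statistic = %.4g, p = %.4g", x$statistic, x$p))
  if (!all(is.na(x$adjusted_p)))
    cat(sprintf(", adjusted p = %.4g (%s)", x$adjusted_p,
                x$adjustment_method))
  cat("\n")
  if (!is.null(x$pairwise)) {
    for (pw in x$pairwise)
      cat(sprintf("  %s vs %s: p = %.4g, adjusted = %.4g\n",
                  pw$groups[1], pw$groups[2], pw$p, pw$adjusted_p))
  }
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided test for a distribution difference between two groups of a
#' non-Gaussian variable. Exact p-values are used when both samples are
#' small enough for `stats::ks.test`'s exact path (no ties, n*m < 10^4),
#' otherwise the asymptotic distribution.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param group_names labels for the output.
#' @return A `group_comparison` with the D statistic.
#' @export
ks_two_sample <- function(a, b, group_names = c("a", "b")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("ks_two_sample: need n >= 2 per group")
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  new_group_comparison("kolmogorov_smirnov", group_names,
                       unname(kt$statistic), kt$p.value,
                       n = c(length(a), length(b)))
}

#' Kruskal-Wallis test with Bonferroni-adjusted pairwise comparisons
#'
#' Overall tie-corrected H test across all groups, followed by all
#' pairwise two-group rank tests with Bonferroni adjustment by the number
#' of pairs; adjusted p-values are capped at 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return A `group_comparison` with fields `statistic` (H), `p`, and
#'   `pairwise` (list of pairwise `group_comparison`s with `adjusted_p`).
#' @examples
#' kruskal_wallis_pairwise(list(a = 1:5, b = 2:6, c = c(9, 9, 10, 12)))
#' @export
kruskal_wallis_pairwise <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("kruskal_wallis_pairwise: each group needs n >= 2")
  all_v <- unlist(groups, use.names = FALSE)
  if (length(unique(all_v)) == 1L) {
    # degenerate: all observations identical
    overall <- new_group_comparison("kruskal_wallis", names(groups), 0, 1)
  } else {
    kt <- stats::kruskal.test(groups)
    overall <- new_group_comparison("kruskal_wallis", names(groups),
                                    unname(kt$statistic), kt$p.value)
  }
  pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  n_pairs <- length(pairs)
  pw <- lapply(pairs, function(pr) {
    va <- groups[[pr[1]]]; vb <- groups[[pr[2]]]
    if (length(unique(c(va, vb))) == 1L) {
      raw <- 1
      stat <- 0
    } else {
      kt <- stats::kruskal.test(list(va, vb))
      raw <- kt$p.value; stat <- unname(kt$statistic)
    }
    new_group_comparison("kruskal_wallis_pairwise", pr, stat, raw,
                         adjusted_p = min(1, raw * n_pairs),
                         method = "bonferroni",
                         n = c(length(va), length(vb)))
  })
  overall$pairwise <- pw
  overall$n <- vapply(groups, length, integer(1))
  overall
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided hypergeometric test for a difference in a binary variable
#' between two groups.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param group_names labels for the output.
#' @return A `group_comparison` (statistic = odds ratio estimate).
#' @export
fisher_exact_2x2 <- function(tab, group_names = c("a", "b")) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("fisher_exact_2x2: need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("fisher_exact_2x2: entries must be non-negative integers")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  new_group_comparison("fisher_exact", group_names,
                       unname(ft$estimate), ft$p.value, n = rowSums(tab))
}

#' Kendall's tau with bootstrap confidence interval
#'
#' Tie-corrected tau-b with a seeded percentile-bootstrap CI (resampling
#' pairs) and the p-value from the standard tau null (exact for small n
#' without ties, normal approximation otherwise) — the rank correlation of
#' choice for small groups.
#'
#' @param x,y paired numeric vectors, n >= 3 after NA removal.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return List of class `correlation_result`: `tau`, `ci_lower`,
#'   `ci_upper`, `p`, `n`, `ci_method`. `tau` is `NA` when either vector
#'   is constant.
#' @export
kendall_tau_ci <- function(x, y, n_boot = 2000L, conf = 0.95, seed = 1L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("kendall_tau_ci: need n >= 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    out <- list(tau = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                p = NA_real_, n = n, ci_method = "bootstrap_percentile")
    class(out) <- "correlation_result"
    return(out)
  }
  tau <- stats::cor(x, y, method = "kendall")
  p <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))$p.value
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  taus <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(x[idx])) == 1L || length(unique(y[idx])) == 1L)
      return(NA_real_)
    stats::cor(x[idx], y[idx], method = "kendall")
  }, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  ci <- stats::quantile(taus, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  out <- list(tau = tau, ci_lower = ci[1], ci_upper = ci[2], p = p, n = n,
              ci_method = "bootstrap_percentile")
  class(out) <- "correlation_result"
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> Kendall tau = %.3f (CI %.3f-%.3f), p = %.4g, n = %d\n",
              x$tau, x$ci_lower, x$ci_upper, x$p, x$n))
  invisible(x)
}

#' Two-observer intraclass correlation coefficient
#'
#' Agreement between two observers rating the same subjects, as a two-way
#' random-effects, absolute-agreement, single-measures ICC (ICC(2,1));
#' the consistency form ICC(3,1) is available via `form`. Computed from
#' the ANOVA mean squares of the subject x observer table. Identical
#' rating vectors (zero total variance) give ICC = 1 by convention.
#'
#' @param ratings_a,ratings_b paired numeric ratings, n >= 3.
#' @param form `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency).
#' @param conf confidence level of the F-based interval.
#' @return List: `icc`, `ci_lower`, `ci_upper`, `form`, `n`.
#' @export
icc_two_observers <- function(ratings_a, ratings_b,
                              form = c("ICC2", "ICC3"), conf = 0.95) {
  form <- match.arg(form)
  ok <- stats::complete.cases(ratings_a, ratings_b)
  a <- ratings_a[ok]; b <- ratings_b[ok]
  n <- length(a)
  if (n < 3L) stop("icc_two_observers: need n >= 3 paired ratings")
  k <- 2L
  m <- cbind(a, b)
  if (stats::var(as.vector(m)) == 0)
    return(list(icc = 1, ci_lower = 1, ci_upper = 1, form = form, n = n))
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)            # between-subjects
  msc <- ss_cols / (k - 1)            # between-observers
  mse <- ss_err / ((n - 1) * (k - 1)) # residual
  icc <- if (form == "ICC2") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  # F-based interval (Shrout & Fleiss) on the consistency form; reported
  # for both forms as an approximation when msc differs little from mse
  f <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  fl <- f / stats::qf(1 - (1 - conf) / 2, df1, df2)
  fu <- f * stats::qf(1 - (1 - conf) / 2, df2, df1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  list(icc = icc, ci_lower = ci[1], ci_upper = ci[2], form = form, n = n)
}
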