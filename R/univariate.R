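# Univariate case-control statistics: chi-square on contingency counts,
# summary-statistic Z, t / Mann-Whitney with a deterministic normality gate,
# Spearman rank correlation, and Benjamini-Hochberg adjustment.

test_result <- function(method, statistic, p, df = NA_real_,
                        estimate = NA_real_) {
  stopifnot(is.finite(statistic), p >= 0, p <= 1)
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p = unname(p),
                 estimate = unname(estimate)),
            class = "lp_test")
}

#' @export
print.lp_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g\n", x$method, x$statistic,
              if (is.finite(x$df)) sprintf(" (df = %.3g)", x$df) else "",
              x$p))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Classical Pearson chi-square of independence on an r x c table of
#' counts, without continuity correction (the convention under which the
#' published baseline-table statistics reproduce exactly).
#'
#' @param counts matrix of non-negative integer counts (rows = exposure
#'   levels, columns = groups).
#' @return An `lp_test` with `method = "pearson_chi2"`, the chi-square
#'   statistic, `df = (r-1)(c-1)` and the upper-tail p-value.
#' @examples
#' pearson_chi_square(is_baseline_counts()$gender)  # 0.135
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) <= 0) stop("grand total must be > 0")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: a row or column margin is zero")
  # the small-expected-count warning concerns the p approximation only;
  # the statistic itself is exact
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ct$expected <= 0))
    stop("degenerate table: an expected count is zero")
  test_result("pearson_chi2", ct$statistic, ct$p.value, df = ct$parameter)
}

#' Two-sample Z test from printed summary statistics
#'
#' The unpooled normal-theory Z comparing two group means from their
#' printed mean/SD/n summaries, `Z = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)`,
#' with a two-sided normal p-value. This is how baseline continuous
#' variables reported only as "mean +/- SD" are compared.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return An `lp_test` with `method = "z_summary"`.
#' @examples
#' z_from_summary(64.53, 10.26, 251, 62.95, 8.79, 251)  # Z ~ 1.853
#' @export
z_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 <= 0 || s2 <= 0) stop("SDs must be > 0")
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  z <- (m1 - m2) / sqrt(s1^2 / n1 + s2^2 / n2)
  test_result("z_summary", z, 2 * stats::pnorm(-abs(z)))
}

#' Two-sample t test
#'
#' Pooled (Student) or Welch two-sample t with two-sided p-value.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param welch use the Welch unequal-variance form (default `FALSE`,
#'   i.e. pooled, matching the study's "independent-sample t-test").
#' @return An `lp_test` with `method` `"student_t"` or `"welch_t"`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("degenerate: zero variance in both samples")
  tt <- stats::t.test(x, y, var.equal = !welch)
  test_result(if (welch) "welch_t" else "student_t",
              tt$statistic, tt$p.value, df = tt$parameter,
              estimate = mean(x) - mean(y))
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank ties and the tie-corrected normal
#' approximation, two-sided. The statistic reported is U on the `x` side
#' (number of (x, y) pairs with x > y, ties counting 1/2).
#'
#' @param x,y numeric samples, each non-empty.
#' @return An `lp_test` with `method = "mann_whitney"`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("each sample must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    stop("degenerate: all values identical across both samples")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  test_result("mann_whitney", wt$statistic, wt$p.value)
}

sample_skewness <- function(x) {
  n <- length(x); m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

sample_excess_kurtosis <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^4) / s^4 - 3
}

#' Deterministic normality gate
#'
#' Routes a variable to the t test (`"normal"`) or Mann-Whitney
#' (`"non_normal"`) by the moment rule |skewness| < 1 and
#' |excess kurtosis| < 1. Deterministic and dependency-free; samples with
#' n < 8 or zero variance fall back to `"non_normal"` with a warning.
#'
#' @param x numeric sample.
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_gate <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 8) {
    warning("n < 8: falling back to non_normal")
    return("non_normal")
  }
  if (stats::var(x) == 0) return("non_normal")
  if (abs(sample_skewness(x)) < 1 && abs(sample_excess_kurtosis(x)) < 1)
    "normal" else "non_normal"
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (monotone, order-preserving);
#' a validated wrapper around [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Spearman rank correlation test
#'
#' Midrank-based rank correlation with the t approximation
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` on n - 2 df, two-sided.
#'
#' @param x,y numeric vectors of equal length, n >= 4, finite.
#' @return An `lp_test` with `method = "spearman"` and `estimate = rs`.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need n >= 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("degenerate: zero rank variance")
  rs <- stats::cor(rx, ry)
  if (abs(rs) >= 1)
    return(test_result("spearman", rs, 0, df = n - 2, estimate = rs))
  tstat <- rs * sqrt((n - 2) / (1 - rs^2))
  test_result("spearman", rs, 2 * stats::pt(-abs(tstat), df = n - 2),
              df = n - 2, estimate = rs)
}

#' Univariate screen of a metadata table
#'
#' Runs the appropriate two-group comparison for every clinical variable
#' in a metadata data frame: chi-square for categorical (gender and
#' comorbidity flags), and t or Mann-Whitney for continuous variables as
#' chosen by [normality_gate()] per variable.
#'
#' @param metadata data frame as from [read_metadata()] /
#'   [simulate_covariates()].
#' @return Data frame with columns `variable`, `method`, `statistic`,
#'   `p`, `q` (BH over the continuous/categorical tests jointly).
#' @export
univariate_screen <- function(metadata) {
  grp <- metadata$group
  if (is.null(grp)) stop("metadata must have a group column")
  rows <- list()
  cat_vars <- c("gender", "t2d", "hypertension", "obesity")
  for (v in cat_vars) {
    x <- metadata[[v]]
    if (is.null(x) || all(is.na(x))) next
    tab <- table(x, grp)
    if (nrow(tab) < 2) next
    r <- pearson_chi_square(unclass(tab))
    rows[[v]] <- data.frame(variable = v, method = r$method,
                            statistic = r$statistic, p = r$p)
  }
  num_vars <- c("age", "tc", "tg", "ldl_c", "hdl_c")
  for (v in num_vars) {
    x <- metadata[[v]]
    if (is.null(x) || all(is.na(x))) next
    xc <- x[grp == "case"]; xk <- x[grp == "control"]
    gate <- tryCatch(normality_gate(x[is.finite(x)]),
                     warning = function(w) "non_normal")
    r <- if (gate == "normal") two_sample_t(xc, xk)
         else mann_whitney(xc, xk)
    rows[[v]] <- data.frame(variable = v, method = r$method,
                            statistic = r$statistic, p = r$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out
}
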