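#' Paired test-retest measurements
#'
#' Aligns the two acquisitions of every eye for one (algorithm, layer,
#' metric) stratum of a measurement table.
#'
#' @param measurements A [measure_cohort()] data frame.
#' @param algorithm,layer Stratum selectors.
#' @param metric `"vd"` or `"vsd"`.
#' @return A `paired_measurements` data frame with columns `eye`, `m1`,
#'   `m2` and attributes `algorithm`, `layer`, `metric`.
#' @export
paired_measurements <- function(measurements, algorithm, layer,
                                metric = c("vd", "vsd")) {
  metric <- match.arg(metric)
  sub <- measurements[measurements$algorithm == algorithm &
                        measurements$layer == layer, ]
  if (nrow(sub) == 0L) stop("no rows for ", algorithm, "/", layer)
  w <- stats::reshape(sub[, c("eye", "acquisition", metric)],
                      direction = "wide", idvar = "eye",
                      timevar = "acquisition")
  out <- data.frame(eye = w$eye, m1 = w[[2L]], m2 = w[[3L]])
  if (anyNA(out)) stop("incomplete acquisition pairs for ", algorithm, "/", layer)
  structure(out, class = c("paired_measurements", "data.frame"),
            algorithm = algorithm, layer = layer, metric = metric)
}

#' Relative test-retest difference
#'
#' The absolute difference between the two acquisitions normalized by the
#' pair mean: `|m2 - m1| / ((m1 + m2)/2)`. A pair of two zeros is defined
#' as 0. The pair-mean denominator (symmetric in the two acquisitions) is
#' the package's recorded choice; `denominator = "first"` normalizes by the
#' first measurement instead.
#'
#' @param m1,m2 Numeric vectors of paired measurements (non-negative).
#' @param denominator `"pair_mean"` (default) or `"first"`.
#' @return Vector of relative differences.
#' @export
relative_difference <- function(m1, m2, denominator = c("pair_mean", "first")) {
  denominator <- match.arg(denominator)
  stopifnot(length(m1) == length(m2))
  den <- if (denominator == "pair_mean") (m1 + m2) / 2 else m1
  if (any(den < 0 | (den == 0 & abs(m2 - m1) > 0)))
    stop("relative difference undefined: non-positive denominator with unequal pair")
  out <- numeric(length(m1))
  nz <- den > 0
  out[nz] <- abs(m2[nz] - m1[nz]) / den[nz]
  out
}

#' Repeatability coefficient
#'
#' \deqn{RC = 1.96 \sqrt{\sum_i (m_{2i} - m_{1i})^2 / n}}
#' the half-width of the interval expected to contain 95% of test-retest
#' differences; 0 iff every pair is identical.
#'
#' @param pm A [paired_measurements()] frame, or anything with `m1`/`m2`
#'   columns.
#' @return The repeatability coefficient (same units as the measurements).
#' @export
repeatability_coefficient <- function(pm) {
  stopifnot(nrow(pm) >= 1L)
  1.96 * sqrt(sum((pm$m2 - pm$m1)^2) / nrow(pm))
}

#' Single-measures intraclass correlation with 95% CI
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC —
#' ICC(A,1) in the McGraw & Wong nomenclature — computed from the mean
#' squares of the two-way (eye x acquisition) decomposition, with the
#' F-distribution 95% confidence interval. Values can be negative when the
#' within-eye disagreement exceeds the between-eye spread.
#'
#' @param pm A [paired_measurements()] frame (n >= 3 pairs).
#' @param alpha CI significance level (0.05 for a 95% interval).
#' @return An `icc_result` list: `icc`, `ci_low`, `ci_high`, `model`,
#'   `degenerate` (TRUE when all values are identical and the ICC is
#'   undefined).
#' @export
icc_single <- function(pm, alpha = 0.05) {
  n <- nrow(pm)
  stopifnot(n >= 3L)
  k <- 2L
  y <- cbind(pm$m1, pm$m2)
  if (max(y) == min(y)) {
    return(structure(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          model = "two-way random, absolute agreement, single measures (ICC(A,1))",
                          degenerate = TRUE), class = "icc_result"))
  }
  grand <- mean(y)
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # McGraw & Wong F-based interval for ICC(A,1)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, ci_low = lo, ci_high = hi,
                 model = "two-way random, absolute agreement, single measures (ICC(A,1))",
                 degenerate = FALSE), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$degenerate) cat("<icc_result> undefined (zero total variance)\n")
  else cat(sprintf("<icc_result> ICC = %.3f [%.3f-%.3f], %s\n",
                   x$icc, x$ci_low, x$ci_high, x$model))
  invisible(x)
}

stat_test_result <- function(test, statistic, p, p_c = NA_real_, note = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 p = unname(min(1, p)), p_c = p_c, note = note),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("<stat_test_result> %s: statistic = %.4g, p = %.4g%s\n",
              x$test, x$statistic, x$p,
              if (is.na(x$p_c)) "" else sprintf(", p_c = %.4g", x$p_c)))
  invisible(x)
}

#' Friedman rank test across algorithms
#'
#' Rank-based omnibus comparison of related samples (eyes x algorithms)
#' with average-rank tie handling and the chi-square approximation.
#'
#' @param matrix Numeric matrix, rows = eyes (blocks), columns = algorithms.
#' @return A `stat_test_result`.
#' @export
friedman_test <- function(matrix) {
  m <- as.matrix(matrix)
  stopifnot(nrow(m) >= 2L, ncol(m) >= 2L)
  ft <- stats::friedman.test(m)
  if (is.nan(ft$statistic)) {  # all ranks tied within every block
    return(stat_test_result("Friedman", 0, 1))
  }
  stat_test_result("Friedman", ft$statistic, ft$p.value)
}

#' Pairwise Wilcoxon signed-rank post-hoc tests
#'
#' Every pair of algorithm columns is compared with the two-sided Wilcoxon
#' signed-rank test and the whole family is Holm-Bonferroni corrected; the
#' corrected values are reported as `p_c`. A pair with all-zero differences
#' yields p = 1.
#'
#' @inheritParams friedman_test
#' @return A data frame: `a`, `b`, `statistic`, `p`, `p_c`.
#' @export
pairwise_posthoc <- function(matrix) {
  m <- as.matrix(matrix)
  stopifnot(ncol(m) >= 2L)
  algs <- colnames(m)
  if (is.null(algs)) algs <- paste0("col", seq_len(ncol(m)))
  pairs <- utils::combn(ncol(m), 2L)
  res <- apply(pairs, 2L, function(ij) {
    d <- m[, ij[1L]] - m[, ij[2L]]
    if (all(d == 0)) return(c(statistic = 0, p = 1))
    wt <- suppressWarnings(stats::wilcox.test(m[, ij[1L]], m[, ij[2L]],
                                              paired = TRUE, exact = FALSE,
                                              correct = TRUE))
    c(statistic = unname(wt$statistic), p = wt$p.value)
  })
  out <- data.frame(a = algs[pairs[1L, ]], b = algs[pairs[2L, ]],
                    statistic = res["statistic", ], p = res["p", ])
  out$p_c <- holm_bonferroni(out$p)
  out
}

#' Mann-Whitney U test (two independent groups)
#'
#' Exact two-sided test when both groups have at most 8 untied
#' observations, the normal approximation with tie correction otherwise.
#'
#' @param group_a,group_b Numeric vectors.
#' @return A `stat_test_result` whose statistic is the U of `group_a`.
#' @export
mann_whitney <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- length(group_a) <= 8L && length(group_b) <= 8L && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                            correct = TRUE))
  stat_test_result("Mann-Whitney U", wt$statistic, wt$p.value,
                   note = if (exact) "exact" else "normal approximation")
}

#' Kruskal-Wallis test (k independent groups)
#'
#' @param groups List of numeric vectors.
#' @return A `stat_test_result` (H statistic with tie correction,
#'   chi-square p-value).
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2L)
  kt <- stats::kruskal.test(groups)
  if (is.nan(kt$statistic)) {  # every observation tied
    return(stat_test_result("Kruskal-Wallis", 0, 1))
  }
  stat_test_result("Kruskal-Wallis", kt$statistic, kt$p.value)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending, multiplies the i-th by (m - i + 1),
#' enforces monotonicity, caps at 1, and returns the corrected values in
#' the original order.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Corrected p-values, same order as the input.
#' @export
holm_bonferroni <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "holm")
}

#' Age-adjusted regression of relative test-retest differences
#'
#' Ordinary least squares of the relative difference on age plus one 0/1
#' indicator per binarization approach with no separate intercept (the
#' indicators span it), mirroring a design with "seven binary variables for
#' the respective algorithm"; the equivalent reference-level
#' (intercept + k-1 dummies) parameterization is available.
#'
#' @param table Data frame with columns `rel_diff`, `age`, `algorithm`.
#' @param indicators Optional pre-built 0/1 indicator matrix replacing the
#'   factor expansion of `algorithm` (used to audit the design); must have
#'   full column rank together with `age`.
#' @param parameterization `"indicators"` (default, no intercept) or
#'   `"dummy_intercept"`.
#' @return A `regression_result` list: `coefficients`, `p_values`, `fit`.
#' @export
age_adjusted_regression <- function(table, indicators = NULL,
                                    parameterization = c("indicators", "dummy_intercept")) {
  parameterization <- match.arg(parameterization)
  stopifnot(nrow(table) >= 9L,
            all(c("rel_diff", "age", "algorithm") %in% names(table)))
  if (is.null(indicators)) {
    f <- factor(table$algorithm)
    indicators <- stats::model.matrix(~ 0 + f)
    colnames(indicators) <- levels(f)
  }
  x <- cbind(age = table$age, indicators)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):ncol(x)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  fit <- if (parameterization == "indicators") {
    stats::lm(table$rel_diff ~ 0 + x)
  } else {
    stats::lm(table$rel_diff ~ table$age + factor(table$algorithm))
  }
  sm <- summary(fit)
  coefs <- stats::coef(fit)
  names(coefs) <- sub("^x", "", names(coefs))
  pv <- sm$coefficients[, "Pr(>|t|)"]
  names(pv) <- names(coefs)
  structure(list(coefficients = coefs, p_values = pv, fit = fit,
                 parameterization = parameterization),
            class = "regression_result")
}

#' Correlation of a metric with age
#'
#' @param values,ages Numeric vectors (per-eye metric means and ages).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `stat_test_result` whose statistic is the correlation r.
#' @export
age_metric_correlation <- function(values, ages, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ct <- suppressWarnings(stats::cor.test(ages, values, method = method))
  stat_test_result(paste0(method, " correlation"), ct$estimate, ct$p.value)
}

#' Friedman power simulation
#'
#' Monte-Carlo power of the Friedman test: in each replicate one value per
#' (eye, algorithm) cell is drawn from an independent normal with the given
#' per-algorithm mean and SD, and the fraction of replicates rejecting at
#' `alpha` is returned. With equal means this estimates the type-I error
#' (about `alpha`); the default 10000 replicates match the study-style
#' post-hoc power analysis.
#'
#' @param group_means,group_sds Per-algorithm means and SDs.
#' @param n_eyes Number of eyes (blocks) per replicate.
#' @param reps Number of simulation replicates.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return Estimated power (rejection fraction).
#' @export
friedman_power_simulation <- function(group_means, group_sds, n_eyes,
                                      reps = 10000L, alpha = 0.05, seed = 1L) {
  k <- length(group_means)
  stopifnot(k >= 2L, length(group_sds) == k, n_eyes >= 2L, reps >= 1L)
  set.seed(seed)
  rejections <- 0L
  for (r in seq_len(reps)) {
    m <- matrix(stats::rnorm(n_eyes * k, mean = rep(group_means, each = n_eyes),
                             sd = rep(group_sds, each = n_eyes)),
                nrow = n_eyes)
    if (friedman_test(m)$p < alpha) rejections <- rejections + 1L
  }
  rejections / reps
}
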