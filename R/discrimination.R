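#' Age-adjusted logistic probabilities
#'
#' Maximum-likelihood logistic regression of health status on one vessel
#' metric plus age (with intercept); the fitted probabilities feed the ROC
#' analysis, so discrimination is assessed after age adjustment. When
#' complete or quasi-complete separation is detected the fit is repeated
#' with a small L2 (ridge) penalty and flagged.
#'
#' @param metric_values Per-eye metric values (e.g. mean VD of a layer).
#' @param ages Per-eye ages.
#' @param labels Binary outcome: 0/1, logical, or a 2-level factor
#'   (second level = pathology).
#' @param ridge Ridge penalty used on detected separation.
#' @return A `logistic_fit` list: `probabilities`, `coefficients`
#'   (intercept, metric, age), `separation` flag.
#' @export
logistic_probability <- function(metric_values, ages, labels, ridge = 1e-4) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  n <- length(y)
  stopifnot(length(metric_values) == n, length(ages) == n, n >= 6L,
            all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  df <- data.frame(y = y, metric = metric_values, age = ages)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ metric + age, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || !fit$converged) {
    x <- cbind(metric = metric_values, age = ages)
    # penalize on the standardized scale so metrics of any magnitude
    # (VD ~ 1e-2, VSD ~ 1e-8) are shrunk comparably; glmnet warns below 8
    # observations per class but the penalized fit is still defined
    gfit <- suppressWarnings(
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = ridge, standardize = TRUE, thresh = 1e-12))
    probs <- as.numeric(stats::predict(gfit, newx = x, type = "response"))
    coefs <- as.numeric(stats::coef(gfit))
    names(coefs) <- c("(Intercept)", "metric", "age")
  } else {
    probs <- unname(stats::fitted(fit))
    coefs <- stats::coef(fit)
    coefs[is.na(coefs)] <- 0  # aliased (e.g. constant) predictors drop out
  }
  structure(list(probabilities = probs, coefficients = coefs,
                 separation = separated, labels = y),
            class = "logistic_fit")
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' ROC over all distinct probability cutpoints (ties grouped, so tied
#' scores contribute diagonal segments and count 1/2 toward the AUC); the
#' trapezoidal AUC equals the normalized tie-aware Mann-Whitney statistic
#' of the probabilities.
#'
#' @param probabilities Per-eye scores (higher = more likely pathology).
#' @param labels Binary outcome, as in [logistic_probability()].
#' @return A `roc_result`: `auc`, `curve` (data frame `fpr`, `tpr`, from
#'   (0,0) to (1,1)), `n_pos`, `n_neg`, plus the scores and labels for
#'   paired comparison.
#' @export
roc_curve <- function(probabilities, labels) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  stopifnot(length(probabilities) == length(y), all(y %in% c(0L, 1L)))
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(probabilities, decreasing = TRUE)
  ps <- probabilities[ord]; ys <- y[ord]
  grp <- cumsum(!duplicated(ps))
  tp <- c(0, cumsum(tapply(ys, grp, sum)))
  fp <- c(0, cumsum(tapply(1L - ys, grp, sum)))
  curve <- data.frame(fpr = fp / n_neg, tpr = tp / n_pos)
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg,
                 probabilities = probabilities, labels = y),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d pathology vs %d healthy)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Hanley-McNeil 95% confidence interval for an AUC
#'
#' Nonparametric standard error via the exponential approximation
#' (\eqn{Q_1 = A/(2-A)}, \eqn{Q_2 = 2A^2/(1+A)}), normal-theory interval
#' truncated to \[0, 1\]. A degenerate AUC of exactly 0 or 1 collapses the
#' interval to the bound and is flagged.
#'
#' @param roc A [roc_curve()] result.
#' @param alpha Significance level (0.05 for a 95% interval).
#' @return List `ci_low`, `ci_high`, `se`, `degenerate`.
#' @export
auc_confidence_interval <- function(roc, alpha = 0.05) {
  stopifnot(inherits(roc, "roc_result"), roc$n_pos >= 2L, roc$n_neg >= 2L)
  a <- roc$auc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (roc$n_pos - 1) * (q1 - a^2) +
                (roc$n_neg - 1) * (q2 - a^2)) / (roc$n_pos * roc$n_neg))
  z <- stats::qnorm(1 - alpha / 2)
  list(ci_low = max(0, a - z * se), ci_high = min(1, a + z * se), se = se,
       degenerate = a %in% c(0, 1))
}

#' Paired DeLong comparison of two AUCs
#'
#' Compares the AUCs of two scores computed on the same eyes and labels,
#' accounting for the correlation between the paired probability vectors.
#'
#' @param roc_a,roc_b [roc_curve()] results sharing eyes and labels.
#' @return A `stat_test_result` (DeLong Z statistic, two-sided p). The
#'   statistic is antisymmetric in the argument order.
#' @export
compare_auc <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  if (!identical(roc_a$labels, roc_b$labels))
    stop("the two ROC results must be computed on the same eyes and labels")
  if (identical(roc_a$probabilities, roc_b$probabilities))
    return(stat_test_result("DeLong paired AUC", 0, 1))
  ra <- pROC::roc(roc_a$labels, roc_a$probabilities, quiet = TRUE,
                  direction = "<", levels = c(0, 1))
  rb <- pROC::roc(roc_b$labels, roc_b$probabilities, quiet = TRUE,
                  direction = "<", levels = c(0, 1))
  # pROC warns below 8 observations per class; the test is still defined
  tt <- suppressWarnings(pROC::roc.test(ra, rb, method = "delong",
                                        paired = TRUE))
  stat_test_result("DeLong paired AUC", tt$statistic, tt$p.value)
}

#' Full age-adjusted discrimination analysis of one stratum
#'
#' Convenience wrapper: logistic fit on (metric, age), ROC of the fitted
#' probabilities, AUC with Hanley-McNeil CI.
#'
#' @inheritParams logistic_probability
#' @return A `roc_result` with added elements `ci_low`, `ci_high`,
#'   `separation`, `model_coefficients`.
#' @export
discriminate <- function(metric_values, ages, labels, ridge = 1e-4) {
  fit <- logistic_probability(metric_values, ages, labels, ridge = ridge)
  roc <- roc_curve(fit$probabilities, fit$labels)
  ci <- auc_confidence_interval(roc)
  roc$ci_low <- ci$ci_low
  roc$ci_high <- ci$ci_high
  roc$separation <- fit$separation
  roc$model_coefficients <- fit$coefficients
  roc
}
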