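test_that("relative difference is symmetric, zero-safe, and pair-mean normalized", {
  expect_equal(relative_difference(0.2, 0.2), 0)
  expect_equal(relative_difference(0.2, 0.1), 0.1 / 0.15)
  expect_equal(relative_difference(0.1, 0.2), relative_difference(0.2, 0.1))
  expect_equal(relative_difference(0, 0), 0)
  expect_equal(relative_difference(0.2, 0.1, denominator = "first"), 0.5)
  expect_error(relative_difference(-0.2, 0.1), "denominator")
})

test_that("repeatability coefficient follows the printed formula", {
  pm <- data.frame(m1 = c(1, 2, 3), m2 = c(1, 2, 3))
  expect_equal(repeatability_coefficient(pm), 0)
  expect_equal(repeatability_coefficient(data.frame(m1 = 0, m2 = 1)), 1.96)
  # n cancels for identical pairs
  expect_equal(repeatability_coefficient(data.frame(m1 = rep(0, 4), m2 = rep(1, 4))),
               1.96)
  expect_error(repeatability_coefficient(data.frame(m1 = numeric(), m2 = numeric())))
})

test_that("RC and relative differences match brute-force oracles on random data", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    m1 <- runif(n, 0.01, 1)
    m2 <- m1 + rnorm(n, 0, 0.1)
    expect_equal(repeatability_coefficient(data.frame(m1 = m1, m2 = m2)),
                 oracle_rc(m1, m2), tolerance = 1e-12)
    expect_equal(relative_difference(m1, abs(m2)), oracle_rel_diff(m1, abs(m2)),
                 tolerance = 1e-12)
  }
})

test_that("ICC(A,1) is exact for perfect agreement and matches the ANOVA oracle", {
  perfect <- data.frame(m1 = c(1, 2, 3), m2 = c(1, 2, 3))
  expect_equal(icc_single(perfect)$icc, 1)

  # permuted second measurement destroys agreement: near zero or negative
  set.seed(72)
  v <- rnorm(12)
  shuffled <- data.frame(m1 = v, m2 = v[c(7:12, 1:6)])
  res <- icc_single(shuffled)
  expect_lt(res$icc, 0.4)
  expect_equal(res$icc, oracle_icc_a1(shuffled$m1, shuffled$m2), tolerance = 1e-10)

  for (i in 1:50) {
    n <- sample(4:30, 1)
    m1 <- rnorm(n)
    m2 <- 0.8 * m1 + rnorm(n, 0, 0.5)
    got <- icc_single(data.frame(m1 = m1, m2 = m2))
    expect_equal(got$icc, oracle_icc_a1(m1, m2), tolerance = 1e-10)
    expect_lte(got$ci_low, got$icc)
    expect_gte(got$ci_high, got$icc)
  }

  degen <- icc_single(data.frame(m1 = rep(2, 5), m2 = rep(2, 5)))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$icc))
})

test_that("ICC recovers a known variance ratio on simulated paired data", {
  set.seed(73)
  sigma_b <- 1; sigma_w <- 0.5
  target <- sigma_b^2 / (sigma_b^2 + sigma_w^2)
  n <- 200
  iccs <- replicate(10, {
    subj <- rnorm(n, sd = sigma_b)
    icc_single(data.frame(m1 = subj + rnorm(n, sd = sigma_w),
                          m2 = subj + rnorm(n, sd = sigma_w)))$icc
  })
  expect_lt(abs(mean(iccs) - target), 0.03)
})

test_that("friedman test handles ties, strong orderings, and permutation nulls", {
  same <- matrix(rep(c(1, 2, 3), each = 8), nrow = 8)
  same[, 2] <- same[, 1]; same[, 3] <- same[, 1]
  res <- friedman_test(same)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)

  # identical column order in every row: statistic 2n at k = 3
  set.seed(74)
  base <- matrix(runif(30), 10, 3)
  ordered <- t(apply(base, 1, sort))
  res2 <- friedman_test(ordered)
  expect_equal(res2$statistic, 20, tolerance = 1e-12)
  expect_lt(res2$p, 0.01)

  # exact permutation null on a 4x3 matrix: the chi-square p is within the
  # coarse resolution of the 6^4 = 1296-arrangement exact distribution
  set.seed(75)
  m <- matrix(rnorm(12), 4, 3)
  obs <- friedman_test(m)$statistic
  perms <- as.matrix(expand.grid(1:6, 1:6, 1:6, 1:6))
  all_orders <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  stats <- apply(perms, 1, function(idx) {
    pm <- m
    for (r in 1:4) pm[r, ] <- pm[r, all_orders[idx[r], ]]
    friedman_test(pm)$statistic
  })
  exact_p <- mean(stats >= obs - 1e-12)
  expect_lt(abs(friedman_test(m)$p - exact_p), 0.12)
})

test_that("post-hoc battery runs all pairs with Holm correction", {
  set.seed(76)
  m <- matrix(runif(26 * 7), 26, 7,
              dimnames = list(NULL, BINARIZATION_ALGORITHMS))
  ph <- pairwise_posthoc(m)
  expect_equal(nrow(ph), choose(7, 2))
  expect_true(all(ph$p_c >= ph$p))
  expect_true(all(ph$p_c <= 1))
  # a duplicated column pair yields p = 1
  m2 <- cbind(a = m[, 1], b = m[, 1], c = m[, 2])
  ph2 <- pairwise_posthoc(m2)
  expect_equal(ph2$p[ph2$a == "a" & ph2$b == "b"], 1)
})

test_that("mann-whitney switches between exact and approximate correctly", {
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  res <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p, 0.1)  # exact two-sided at U = 0, 3 vs 3
  expect_match(res$note, "exact")
  # U_A + U_B = n_A * n_B
  set.seed(77)
  a <- rnorm(6); b <- rnorm(7)
  ua <- mann_whitney(a, b)$statistic
  ub <- mann_whitney(b, a)$statistic
  expect_equal(ua + ub, 42)
  big <- mann_whitney(rnorm(20), rnorm(20))
  expect_match(big$note, "approximation")
})

test_that("kruskal-wallis agrees with two-sample behaviour and detects separation", {
  set.seed(78)
  a <- rnorm(10); b <- rnorm(10) + 0.4
  kw <- kruskal_wallis(list(a, b))
  mw <- mann_whitney(a, b)
  expect_lt(abs(kw$p - mw$p), 0.05)
  expect_equal(kruskal_wallis(list(rep(1, 5), rep(1, 5)))$statistic, 0)
  sep <- kruskal_wallis(list(rnorm(5), rnorm(5) + 10, rnorm(5) + 20))
  expect_lt(sep$p, 0.01)
})

test_that("holm correction matches its hand-coded step-down oracle", {
  expect_equal(holm_bonferroni(0.03), 0.03)
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_bonferroni(c(0.5, 0.5, 0.5)), c(1, 1, 1))
  set.seed(79)
  for (i in 1:50) {
    p <- runif(sample(2:20, 1))
    got <- holm_bonferroni(p)
    expect_equal(got, oracle_holm(p), tolerance = 1e-12)
    expect_true(all(got >= p))
    expect_true(all(diff(got[order(p)]) >= -1e-12))
  }
})

test_that("the age-adjusted regression recovers known coefficients", {
  set.seed(80)
  n <- 500
  algs <- sample(BINARIZATION_ALGORITHMS, n, replace = TRUE)
  ages <- runif(n, 20, 80)
  # age effect zero, manual indicator effect +0.6
  y <- 0.1 + 0.6 * (algs == "Manual") + rnorm(n, 0, 0.2)
  tab <- data.frame(rel_diff = y, age = ages, algorithm = algs)
  fit <- age_adjusted_regression(tab)
  expect_length(fit$coefficients, 8)  # age + 7 indicators
  se_age <- sqrt(diag(vcov(fit$fit)))[1]
  expect_lt(abs(fit$coefficients["age"]), 2.5 * se_age)
  expect_lt(abs((fit$coefficients["Manual"] + fit$coefficients["age"] * 0) -
                  (0.1 + 0.6)), 0.08)
  expect_lt(abs((fit$coefficients["Manual"] - fit$coefficients["Otsu"]) - 0.6),
            0.08)
  expect_lt(fit$p_values["Manual"], 1e-4)

  dup <- stats::model.matrix(~ 0 + factor(algs))
  colnames(dup) <- levels(factor(algs))
  expect_error(age_adjusted_regression(tab, indicators = cbind(dup, Manual2 = dup[, "Manual"])),
               "collinear")
})

test_that("friedman power simulation is calibrated and saturates", {
  # zero effect: rejection rate ~ alpha
  p0 <- friedman_power_simulation(rep(0, 4), rep(1, 4), n_eyes = 10,
                                  reps = 400, seed = 81)
  expect_lt(abs(p0 - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.02)
  # huge separation: power ~ 1
  p1 <- friedman_power_simulation(c(0, 5, 10), rep(0.5, 3), n_eyes = 6,
                                  reps = 200, seed = 82)
  expect_gt(p1, 0.95)
  # monotone in the number of eyes
  pw <- sapply(c(4, 6, 10), function(n)
    friedman_power_simulation(c(0, 0.8, 1.6), rep(1, 3), n_eyes = n,
                              reps = 400, seed = 83))
  expect_true(all(diff(pw) >= -0.05))
  expect_gt(pw[3], pw[1])
})
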