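# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and naive formulas, used to pin the optimized
# implementations.

oracle_between_class_variance <- function(h, T) {
  g <- 0:255
  n0 <- 0; n1 <- 0; s0 <- 0; s1 <- 0
  for (i in 1:256) {
    if (g[i] <= T) { n0 <- n0 + h[i]; s0 <- s0 + g[i] * h[i] }
    else { n1 <- n1 + h[i]; s1 <- s1 + g[i] * h[i] }
  }
  if (n0 == 0 || n1 == 0) return(-Inf)
  n0 * n1 * (s0 / n0 - s1 / n1)^2
}

oracle_otsu <- function(h) {
  crit <- sapply(0:255, function(T) oracle_between_class_variance(h, T))
  (0:255)[which.max(crit)]
}

oracle_percentile <- function(h, p = 0.5) {
  total <- sum(h)
  lv <- (0:255)[h > 0]
  best_T <- NA; best <- Inf
  for (T in min(lv):max(lv)) {
    d <- abs(sum(h[1:(T + 1)]) / total - p)
    if (d < best) { best <- d; best_T <- T }
  }
  best_T
}

oracle_huang_fuzziness <- function(h, T) {
  g <- 0:255
  gmin <- min(g[h > 0]); gmax <- max(g[h > 0])
  C <- gmax - gmin
  n0 <- sum(h[g <= T]); n1 <- sum(h[g > T])
  if (n0 == 0 || n1 == 0) return(Inf)
  m0 <- sum(g[g <= T] * h[g <= T]) / n0
  m1 <- sum(g[g > T] * h[g > T]) / n1
  total <- 0
  for (i in 1:256) {
    if (h[i] == 0) next
    m <- if (g[i] <= T) m0 else m1
    mu <- 1 / (1 + abs(g[i] - m) / C)
    s <- if (mu <= 0 || mu >= 1) 0 else -mu * log(mu) - (1 - mu) * log(1 - mu)
    total <- total + h[i] * s
  }
  total
}

oracle_huang <- function(h) {
  gmin <- min((0:255)[h > 0]); gmax <- max((0:255)[h > 0])
  cand <- gmin:(gmax - 1)
  crit <- sapply(cand, function(T) oracle_huang_fuzziness(h, T))
  cand[which.min(crit)]
}

oracle_li_criterion <- function(h, T) {
  g <- 0:255
  n0 <- sum(h[g <= T]); n1 <- sum(h[g > T])
  if (n0 == 0 || n1 == 0) return(Inf)
  s0 <- sum(g[g <= T] * h[g <= T]); s1 <- sum(g[g > T] * h[g > T])
  t0 <- if (s0 > 0) -s0 * log(s0 / n0) else 0
  t1 <- if (s1 > 0) -s1 * log(s1 / n1) else 0
  t0 + t1
}

oracle_li <- function(h) {
  crit <- sapply(0:255, function(T) oracle_li_criterion(h, T))
  (0:255)[which.min(crit)]
}

# final selection step of the moment-preserving method: grey level whose
# cumulative fraction is nearest the target background fraction
oracle_p0_selection <- function(h, p0) {
  total <- sum(h)
  lv <- (0:255)[h > 0]
  best_T <- NA; best <- Inf
  for (T in min(lv):max(lv)) {
    d <- abs(sum(h[1:(T + 1)]) / total - p0)
    if (d < best) { best <- d; best_T <- T }
  }
  best_T
}

oracle_rc <- function(m1, m2) {
  acc <- 0
  for (i in seq_along(m1)) acc <- acc + (m2[i] - m1[i])^2
  1.96 * sqrt(acc / length(m1))
}

oracle_rel_diff <- function(m1, m2) {
  out <- numeric(length(m1))
  for (i in seq_along(m1)) {
    den <- (m1[i] + m2[i]) / 2
    out[i] <- if (den == 0) 0 else abs(m2[i] - m1[i]) / den
  }
  out
}

oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- (m - i + 1) * p[ord[i]]
    running <- max(running, val)
    adj[ord[i]] <- min(1, running)
  }
  adj
}

oracle_vd <- function(grid, squared = TRUE) {
  nw <- 0
  for (v in as.vector(grid)) if (v) nw <- nw + 1
  f <- nw / length(grid)
  if (squared) f^2 else f
}

oracle_vsd <- function(grid) {
  nw <- 0
  for (v in as.vector(grid)) if (v) nw <- nw + 1
  nw / length(grid)^2
}

# ICC(A,1) from an ANOVA table fitted by aov(), independent of the
# direct-sums implementation
oracle_icc_a1 <- function(m1, m2) {
  n <- length(m1)
  d <- data.frame(y = c(m1, m2),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = d))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# 8-connected component count by iterative flood fill
count_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  ncomp <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    ncomp <- ncomp + 1L
    stack <- list(c(r, c))
    lab[r, c] <- ncomp
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- cur[1] + dr; cc <- cur[2] + dc
        if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- ncomp
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  ncomp
}

# tie-aware rank-statistic AUC: P(score_pos > score_neg) + 0.5 P(equal),
# by explicit pair enumeration
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  }
  tot / (length(pos) * length(neg))
}

# random-histogram generators: smooth bimodal mixtures (the shape OCTA
# grey-level histograms take) and rough random-support histograms
rand_hist_smooth <- function() {
  mu <- sort(sample(30:220, 2))
  sd <- runif(2, 8, 30)
  w <- runif(1, 0.2, 0.8)
  x <- c(rnorm(round(5000 * w), mu[1], sd[1]),
         rnorm(round(5000 * (1 - w)), mu[2], sd[2]))
  tabulate(pmin(255, pmax(0, round(x))) + 1, 256)
}

rand_hist_rough <- function() {
  h <- integer(256)
  sup <- sample(0:255, sample(10:80, 1))
  h[sup + 1] <- sample(1:100, length(sup), replace = TRUE)
  h
}

# independent Tsai moment solution: background fraction p0 of the bilevel
# image preserving the first three grey moments (NA when degenerate)
oracle_tsai_p0 <- function(h) {
  g <- 0:255
  n <- sum(h)
  m1 <- sum(g * h) / n; m2 <- sum(g^2 * h) / n; m3 <- sum(g^3 * h) / n
  cd <- m2 - m1^2
  if (cd <= 0) return(NA_real_)
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) return(NA_real_)
  z0 <- (-c1 - sqrt(disc)) / 2
  z1 <- (-c1 + sqrt(disc)) / 2
  if (z1 <= z0) return(NA_real_)
  p0 <- (z1 - m1) / (z1 - z0)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) return(NA_real_)
  p0
}
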