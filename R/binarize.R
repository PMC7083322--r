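#' The seven supported binarization approaches
#'
#' One manual approach (maximum grey value inside the foveal avascular zone)
#' and six automated global histogram algorithms, named as in the Fiji /
#' ImageJ auto-threshold menu.
#' @export
BINARIZATION_ALGORITHMS <- c("Manual", "Huang", "Li", "Otsu",
                             "Moments", "Mean", "Percentile")

GREY_LEVELS <- 0:255

#' 256-bin grey-level histogram
#'
#' All automated thresholding algorithms operate on the 256-bin grey-level
#' histogram of an 8-bit image, never on the pixel grid itself.
#'
#' @param image A [grey_image()] or integer pixel matrix in \[0, 255\].
#' @return An integer vector of length 256 (class `histogram256`);
#'   element `g + 1` counts the pixels with grey value `g`.
#' @export
grey_histogram <- function(image) {
  px <- as_pixel_matrix(image)
  counts <- tabulate(as.integer(px) + 1L, nbins = 256L)
  structure(counts, class = "histogram256")
}

as_histogram256 <- function(hist) {
  if (inherits(hist, "histogram256")) return(unclass(hist))
  h <- as.integer(hist)
  if (length(h) != 256L || any(h < 0L)) stop("expected a 256-bin histogram of non-negative counts")
  h
}

#' Threshold result
#'
#' @param algorithm One of [BINARIZATION_ALGORITHMS].
#' @param threshold Integer grey level in \[0, 255\]: pixels strictly greater
#'   than `threshold` are classified as vessel (white).
#' @param degenerate `TRUE` when a degenerate input (e.g. a single-level
#'   histogram) forced a fallback path.
#' @return A `threshold_result` list.
#' @export
threshold_result <- function(algorithm, threshold, degenerate = FALSE) {
  stopifnot(algorithm %in% BINARIZATION_ALGORITHMS,
            threshold >= 0, threshold <= 255)
  structure(list(algorithm = algorithm, threshold = as.integer(threshold),
                 degenerate = isTRUE(degenerate)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %s: T = %d%s\n", x$algorithm, x$threshold,
              if (x$degenerate) " (degenerate input)" else ""))
  invisible(x)
}

as_threshold_value <- function(t) {
  if (inherits(t, "threshold_result")) t$threshold else as.integer(t)
}

populated_range <- function(h) range(GREY_LEVELS[h > 0L])

#' Mean threshold
#'
#' The threshold is the mean grey level of the image, floored to an integer.
#'
#' @param hist A [grey_histogram()].
#' @return A [threshold_result()].
#' @export
threshold_mean <- function(hist) {
  h <- as_histogram256(hist)
  total <- sum(h)
  stopifnot(total >= 1)
  threshold_result("Mean", floor(sum(GREY_LEVELS * as.numeric(h)) / total))
}

#' Percentile threshold
#'
#' Returns the grey level whose cumulative histogram fraction is closest to
#' the target percentile `p` (default 0.5, the reference-software default);
#' ties resolve to the lower grey level.
#'
#' @inheritParams threshold_mean
#' @param p Target cumulative fraction, strictly between 0 and 1.
#' @export
threshold_percentile <- function(hist, p = 0.5) {
  h <- as_histogram256(hist)
  stopifnot(p > 0, p < 1, sum(h) >= 1)
  pr <- populated_range(h)
  cand <- pr[1]:pr[2]  # candidate levels span the populated range
  cumfrac <- cumsum(h)[cand + 1L] / sum(h)
  threshold_result("Percentile", cand[which.min(abs(cumfrac - p))])
}

#' Otsu threshold
#'
#' Maximizes the between-class variance
#' \eqn{\omega_0\omega_1(\mu_0-\mu_1)^2} over all splits with a non-empty
#' background (grey \eqn{\le T}) and foreground (grey \eqn{> T}) class;
#' ties resolve to the lowest grey level.
#'
#' @inheritParams threshold_mean
#' @export
threshold_otsu <- function(hist) {
  h <- as_histogram256(hist)
  total <- sum(h)
  stopifnot(total >= 1)
  if (sum(h > 0L) < 2L)
    return(threshold_result("Otsu", populated_range(h)[1], degenerate = TRUE))
  cs <- cumsum(as.numeric(h))
  csg <- cumsum(GREY_LEVELS * as.numeric(h))
  valid <- cs > 0L & cs < total
  crit <- rep(-Inf, 256L)
  mu0 <- csg[valid] / cs[valid]
  mu1 <- (csg[256L] - csg[valid]) / (total - cs[valid])
  crit[valid] <- cs[valid] * (total - cs[valid]) * (mu0 - mu1)^2
  threshold_result("Otsu", GREY_LEVELS[which.max(crit)])
}

#' Moments threshold (moment-preserving)
#'
#' Tsai's moment-preserving method: the first three normalized grey moments
#' determine the two representative levels of an ideal bilevel image and the
#' background fraction \eqn{p_0}; the threshold is the grey level whose
#' cumulative fraction is nearest \eqn{p_0} (ties to the lower level). When
#' the moment equations have no valid real solution (e.g. a single-level
#' histogram) the method falls back to the mean threshold and flags the
#' result as degenerate.
#'
#' @inheritParams threshold_mean
#' @export
threshold_moments <- function(hist) {
  h <- as_histogram256(hist)
  total <- sum(h)
  stopifnot(total >= 1)
  fallback <- function() {
    t <- threshold_mean(h)
    threshold_result("Moments", t$threshold, degenerate = TRUE)
  }
  g <- as.numeric(GREY_LEVELS)
  m1 <- sum(g * h) / total
  m2 <- sum(g^2 * h) / total
  m3 <- sum(g^3 * h) / total
  cd <- m2 - m1^2
  if (cd <= 0) return(fallback())
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) return(fallback())
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  if (z1 <= z0) return(fallback())
  p0 <- (z1 - m1) / (z1 - z0)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) return(fallback())
  pr <- populated_range(h)
  cand <- pr[1]:pr[2]
  cumfrac <- cumsum(h)[cand + 1L] / total
  threshold_result("Moments", cand[which.min(abs(cumfrac - p0))])
}

# Shannon entropy term S(mu) = -mu ln mu - (1-mu) ln(1-mu), with S(0)=S(1)=0
shannon_fuzziness <- function(mu) {
  s <- numeric(length(mu))
  in01 <- mu > 0 & mu < 1
  m <- mu[in01]
  s[in01] <- -m * log(m) - (1 - m) * log(1 - m)
  s
}

huang_criterion <- function(h, T) {
  g <- GREY_LEVELS
  pr <- populated_range(h)
  C <- pr[2] - pr[1]
  cs <- cumsum(as.numeric(h))
  csg <- cumsum(g * as.numeric(h))
  total <- cs[256L]
  i <- T + 1L
  if (cs[i] == 0L || cs[i] == total) return(Inf)
  mu0 <- csg[i] / cs[i]
  mu1 <- (csg[256L] - csg[i]) / (total - cs[i])
  m <- ifelse(g <= T, mu0, mu1)
  membership <- 1 / (1 + abs(g - m) / C)
  sum(h * shannon_fuzziness(membership))
}

#' Huang threshold (fuzzy-set)
#'
#' Huang & Wang's fuzzy thresholding: each candidate threshold induces a
#' fuzzy membership \eqn{\mu_T(g) = 1/(1 + |g - m|/C)} toward the mean
#' \eqn{m} of the pixel's class, with \eqn{C} the populated grey-level
#' range; the returned threshold minimizes the Shannon-entropy fuzziness
#' \eqn{\sum_g c_g S(\mu_T(g))}. Ties resolve to the lowest grey level.
#'
#' @inheritParams threshold_mean
#' @export
threshold_huang <- function(hist) {
  h <- as_histogram256(hist)
  stopifnot(sum(h) >= 1)
  pr <- populated_range(h)
  if (pr[1] == pr[2])
    return(threshold_result("Huang", pr[1], degenerate = TRUE))
  cand <- pr[1]:(pr[2] - 1L)
  crit <- vapply(cand, function(T) huang_criterion(h, T), numeric(1))
  threshold_result("Huang", cand[which.min(crit)])
}

# Li cross-entropy criterion at integer threshold T (bg: g <= T, fg: g > T),
# with the 0*log(0) = 0 convention for an all-zero background class.
li_criterion <- function(h, T) {
  g <- GREY_LEVELS
  cs <- cumsum(as.numeric(h))
  csg <- cumsum(g * as.numeric(h))
  total <- cs[256L]
  i <- T + 1L
  if (cs[i] == 0L || cs[i] == total) return(Inf)
  s0 <- csg[i]
  s1 <- csg[256L] - s0
  m0 <- s0 / cs[i]
  m1 <- s1 / (total - cs[i])
  t0 <- if (s0 > 0) -s0 * log(m0) else 0
  t1 <- if (s1 > 0) -s1 * log(m1) else 0
  t0 + t1
}

#' Li threshold (minimum cross-entropy)
#'
#' Li & Tam's iterative minimum cross-entropy scheme: starting from the image
#' mean, each step recomputes the background/foreground class means
#' \eqn{\mu_0, \mu_1} at the current threshold and moves to
#' \eqn{(\mu_0 - \mu_1)/(\ln\mu_0 - \ln\mu_1)}, rounded to a grey level,
#' until the update is below 0.5 grey levels (iteration cap 100, flagged if
#' hit). Because the fixed point can sit a few grey levels off the true
#' criterion minimum on irregular histograms, the iteration is followed by
#' a sweep of the cross-entropy criterion over all valid grey levels and
#' the global minimizer is returned (ties to the lowest level), so the
#' result always attains the criterion optimum.
#'
#' @inheritParams threshold_mean
#' @export
threshold_li <- function(hist) {
  h <- as_histogram256(hist)
  total <- sum(h)
  stopifnot(total >= 1)
  pr <- populated_range(h)
  if (pr[1] == pr[2])
    return(threshold_result("Li", pr[1], degenerate = TRUE))
  g <- GREY_LEVELS
  cs <- cumsum(as.numeric(h))
  csg <- cumsum(g * as.numeric(h))
  stopifnot("Li threshold requires a positive grey mean" = csg[256L] > 0)
  t_cur <- floor(csg[256L] / total)
  converged <- FALSE
  for (k in seq_len(100L)) {
    i <- t_cur + 1L
    n0 <- cs[i]
    if (n0 == 0 || n0 == total) break
    m0 <- csg[i] / n0
    m1 <- (csg[256L] - csg[i]) / (total - n0)
    t_next <- if (m0 <= 0) {
      floor(m1 / 2)  # empty-mean background: bisect toward the foreground mean
    } else {
      as.integer(floor((m0 - m1) / (log(m0) - log(m1)) + 0.5))
    }
    t_next <- max(0L, min(255L, t_next))
    if (abs(t_next - t_cur) < 0.5) { converged <- TRUE; break }
    t_cur <- t_next
  }
  # global refinement: the returned level must attain the criterion optimum
  crit <- vapply(GREY_LEVELS, function(T) li_criterion(h, T), numeric(1))
  threshold_result("Li", GREY_LEVELS[which.min(crit)], degenerate = !converged)
}

#' Manual FAZ-based threshold
#'
#' The manual approach delineates the foveal avascular zone — a physiologic
#' vessel-free region — and uses the maximum grey value inside it as the
#' binarization threshold: any pixel brighter than the brightest avascular
#' background is taken to be vessel.
#'
#' @param image A [grey_image()] or pixel matrix.
#' @param faz Logical mask of the same dimensions, `TRUE` inside the FAZ.
#' @return A [threshold_result()] with algorithm `"Manual"`.
#' @export
threshold_manual_faz <- function(image, faz) {
  px <- as_pixel_matrix(image)
  if (!is.logical(faz) || !identical(dim(px), dim(faz)))
    stop("`faz` must be a logical mask matching the image dimensions")
  if (!any(faz)) stop("FAZ mask is empty")
  threshold_result("Manual", max(px[faz]))
}

#' Manual repeat-measurement protocol
#'
#' The manual threshold is measured twice; when the two measurements differ
#' by fewer than 5 grey levels their mean (rounded half up) is used, and when
#' they differ by 5 or more a third measurement is obtained and the median of
#' the three is used.
#'
#' @param t1,t2 The two threshold measurements (grey levels in \[0, 255\]).
#' @param t3_provider A zero-argument function returning the third
#'   measurement; only called when `|t1 - t2| >= 5`.
#' @return A [threshold_result()] with algorithm `"Manual"`.
#' @export
manual_threshold_protocol <- function(t1, t2, t3_provider = NULL) {
  t1 <- as_threshold_value(t1); t2 <- as_threshold_value(t2)
  stopifnot(t1 >= 0, t1 <= 255, t2 >= 0, t2 <= 255)
  if (abs(t1 - t2) < 5) {
    threshold_result("Manual", floor((t1 + t2) / 2 + 0.5))
  } else {
    if (is.null(t3_provider)) stop("measurements differ by >= 5; a third measurement is required")
    t3 <- as_threshold_value(t3_provider())
    threshold_result("Manual", stats::median(c(t1, t2, t3)))
  }
}

#' Transfer the superficial FAZ selection to the deep layer
#'
#' The FAZ is delineated on the superficial layer only; the same mask is
#' applied verbatim to the corresponding area of the deep-layer image to
#' obtain the deep manual threshold.
#'
#' @param faz_superficial Logical FAZ mask delineated on the superficial image.
#' @param deep_image The deep-layer [grey_image()].
#' @export
transfer_faz_to_deep <- function(faz_superficial, deep_image) {
  px <- as_pixel_matrix(deep_image)
  if (!identical(dim(px), dim(faz_superficial)))
    stop("FAZ mask dimensions do not match the deep image")
  threshold_manual_faz(deep_image, faz_superficial)
}

#' Automated threshold dispatcher
#'
#' @inheritParams threshold_mean
#' @param algorithm One of `"Huang"`, `"Li"`, `"Otsu"`, `"Moments"`,
#'   `"Mean"`, `"Percentile"`.
#' @param p Percentile target, used by the Percentile algorithm only.
#' @export
auto_threshold <- function(hist, algorithm, p = 0.5) {
  switch(algorithm,
         Huang = threshold_huang(hist),
         Li = threshold_li(hist),
         Otsu = threshold_otsu(hist),
         Moments = threshold_moments(hist),
         Mean = threshold_mean(hist),
         Percentile = threshold_percentile(hist, p = p),
         stop("unknown automated algorithm: ", algorithm))
}

#' Binarize an image at a threshold
#'
#' A pixel is classified as vessel (white) when its grey value is strictly
#' greater than the threshold, i.e. the threshold bounds the background
#' class.
#'
#' @param image A [grey_image()] or pixel matrix.
#' @param threshold A [threshold_result()] or integer grey level in \[0, 255\].
#' @return A [binary_image()].
#' @export
binarize <- function(image, threshold) {
  px <- as_pixel_matrix(image)
  t <- as_threshold_value(threshold)
  stopifnot(t >= 0, t <= 255)
  binary_image(px > t)
}
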