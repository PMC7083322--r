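# Small, fast fixtures generated in code.

# a scaled-down simulation config for unit tests: 192 px images keep every
# geometric feature (FAZ, branching net, speckle) while running in
# milliseconds
small_config <- function(...) {
  defaults <- list(image_size_px = 192L, n_segments = 320L, n_seeds = 14L,
                   n_healthy = 2L, n_pathology = 2L, rater_jitter_px = 1.5,
                   seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# library of 30 binary shapes exercising the skeletonizer: bars, diagonals,
# crosses, L shapes, rings, dilated random blobs, multi-component scenes
make_shape_library <- function(seed = 404) {
  set.seed(seed)
  shapes <- list()
  blank <- function() matrix(FALSE, 48, 48)
  # filled rectangles of assorted aspect ratios
  for (dims in list(c(20, 3), c(3, 20), c(12, 12), c(30, 5), c(7, 25))) {
    m <- blank()
    m[10:(9 + dims[1]), 8:(7 + dims[2])] <- TRUE
    shapes[[length(shapes) + 1]] <- m
  }
  # 1-px and thick diagonals
  for (w in c(0, 1, 2)) {
    m <- blank()
    for (i in 5:40) m[i, pmax(1, pmin(48, (i - w):(i + w)))] <- TRUE
    shapes[[length(shapes) + 1]] <- m
  }
  # crosses and L / T shapes
  for (arm in c(3, 5)) {
    m <- blank()
    m[20:(19 + arm), 5:44] <- TRUE
    m[5:44, 20:(19 + arm)] <- TRUE
    shapes[[length(shapes) + 1]] <- m
    l <- blank()
    l[10:40, 10:(9 + arm)] <- TRUE
    l[(41 - arm):40, 10:40] <- TRUE
    shapes[[length(shapes) + 1]] <- l
  }
  # rings (annuli) of different thickness: skeleton must stay one loop
  for (th in c(3, 5, 8)) {
    m <- blank()
    cx <- 24.5
    d <- sqrt(outer((1:48 - cx)^2, (1:48 - cx)^2, `+`))
    m[d >= 14 - th & d <= 14] <- TRUE
    shapes[[length(shapes) + 1]] <- m
  }
  # random blobs dilated to solid shapes
  for (k in 1:8) {
    m <- blank()
    pts <- cbind(sample(10:38, 14, replace = TRUE), sample(10:38, 14, replace = TRUE))
    m[pts] <- TRUE
    m <- EBImage::dilate(m * 1, EBImage::makeBrush(7, "disc")) > 0
    shapes[[length(shapes) + 1]] <- m
  }
  # multi-component scenes: separated bars and squares
  for (gap in c(4, 8, 12)) {
    m <- blank()
    m[5:9, 5:30] <- TRUE
    m[(10 + gap):(14 + gap), 5:30] <- TRUE
    m[30:40, 36:44] <- TRUE
    shapes[[length(shapes) + 1]] <- m
  }
  # sparse dots (single-pixel components survive thinning untouched)
  for (k in 1:4) {
    m <- blank()
    idx <- cbind(sample(seq(4, 44, by = 6), 5), sample(seq(4, 44, by = 6), 5))
    m[idx] <- TRUE
    shapes[[length(shapes) + 1]] <- m
  }
  stopifnot(length(shapes) >= 30)
  shapes[1:30]
}

# histogram from explicit level: count pairs, e.g. hist_of(c(`50` = 3, `60` = 1))
hist_of <- function(counts) {
  h <- integer(256)
  lv <- as.integer(names(counts))
  h[lv + 1L] <- as.integer(counts)
  h
}
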