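#' Simulation configuration for synthetic test-retest angiogram cohorts
#'
#' Defines the study conditions emulated by the generator: 3x3 mm macular
#' en-face angiograms with a central foveal avascular zone (FAZ), a branching
#' vessel network brighter than the speckle background, a deep-layer variant
#' with lower overall signal, capillary dropout for pathology eyes, and two
#' independent noise realizations per eye/layer forming a test-retest pair.
#'
#' @param image_size_px Image side length in pixels (square images).
#' @param mm_extent Physical scan extent in mm (3 x 3 mm macular scans).
#' @param n_healthy,n_pathology Numbers of healthy and pathology eyes.
#' @param dropout_fraction Fraction of vessel segments removed (peripheral,
#'   terminal-first) for pathology eyes; in \[0, 1).
#' @param vessel_intensity,background_intensity Mean grey values of vessel
#'   and background pixels before noise, in \[0, 255\].
#' @param deep_offset Additive grey offset applied to both intensities for
#'   the deep layer (negative: lower overall signal).
#' @param speckle_scale Strength of the multiplicative speckle in \[0, 1\]:
#'   each pixel is scaled by `1 + speckle_scale * (R - 1)` with `R` a
#'   mean-one Rayleigh variate; 0 gives a noiseless render.
#' @param speckle_grain_px Spatial correlation length (Gaussian sigma, in
#'   pixels) of the speckle field; OCT speckle has a grain size larger than
#'   one pixel, so supra-threshold noise forms small blobs rather than
#'   isolated pixels. 0 gives independent per-pixel noise. The field is
#'   renormalized after smoothing so `speckle_scale` keeps its marginal
#'   meaning.
#' @param rater_jitter_px SD (pixels) of the radial jitter applied to FAZ
#'   polygon vertices by the emulated manual rater.
#' @param age_range Two-element numeric, subject age range in years.
#' @param age_vd_slope Relative decline of the vessel-segment budget per
#'   year of age (0.004 = 0.4 %/year), producing the negative
#'   age-vessel-density correlation seen in macular OCTA.
#' @param faz_radius_mm Mean FAZ radius in mm.
#' @param faz_margin Scale factor of the capillary-free exclusion zone
#'   around the FAZ polygon: vessels terminate at `faz_margin` times the
#'   local FAZ radius, leaving the narrow perifoveal margin that a
#'   free-hand delineation occasionally overshoots into.
#' @param n_seeds Number of vessel sprouts started on the FAZ rim.
#' @param n_segments Target number of vessel segments for the youngest age.
#' @param branch_prob Per-segment probability of spawning a side branch.
#' @param seg_len_px Two-element range of segment lengths in pixels.
#' @param width_start,width_min,width_decay Branch width schedule in pixels.
#' @param cell_cap Maximum number of segment endpoints per 16x16-px cell:
#'   a coarse self-avoidance that keeps the network space-filling (real
#'   capillary beds rarely overlap in an en-face projection), so skeleton
#'   length stays proportional to total vessel length.
#' @param seed Master seed from which all per-eye seeds are derived.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(image_size_px = 1024L,
                       mm_extent = 3.0,
                       n_healthy = 11L,
                       n_pathology = 15L,
                       dropout_fraction = 0.25,
                       vessel_intensity = 140,
                       background_intensity = 60,
                       deep_offset = -25,
                       speckle_scale = 0.25,
                       speckle_grain_px = 1.2,
                       rater_jitter_px = 6,
                       age_range = c(20, 80),
                       age_vd_slope = 0.004,
                       faz_radius_mm = 0.3,
                       faz_margin = 1.10,
                       n_seeds = 42L,
                       n_segments = 4000L,
                       branch_prob = 0.45,
                       seg_len_px = c(8, 18),
                       width_start = 4,
                       width_min = 2,
                       width_decay = 0.9,
                       cell_cap = 2L,
                       seed = 1L) {
  cfg <- list(image_size_px = as.integer(image_size_px), mm_extent = mm_extent,
              n_healthy = as.integer(n_healthy),
              n_pathology = as.integer(n_pathology),
              dropout_fraction = dropout_fraction,
              vessel_intensity = vessel_intensity,
              background_intensity = background_intensity,
              deep_offset = deep_offset, speckle_scale = speckle_scale,
              speckle_grain_px = speckle_grain_px,
              rater_jitter_px = rater_jitter_px, age_range = age_range,
              age_vd_slope = age_vd_slope, faz_radius_mm = faz_radius_mm,
              faz_margin = faz_margin,
              n_seeds = as.integer(n_seeds), n_segments = as.integer(n_segments),
              branch_prob = branch_prob, seg_len_px = seg_len_px,
              width_start = width_start, width_min = width_min,
              width_decay = width_decay, cell_cap = as.integer(cell_cap),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (image_size_px < 16L) stop("image_size_px must be at least 16")
    if (dropout_fraction < 0 || dropout_fraction >= 1)
      stop("dropout_fraction must lie in [0, 1)")
    if (vessel_intensity <= background_intensity)
      stop("vessel_intensity must exceed background_intensity")
    greys <- c(vessel_intensity, background_intensity)
    if (any(greys < 0 | greys > 255)) stop("grey intensities must lie in [0, 255]")
    if (n_segments < 1L || n_seeds < 1L)
      stop("degenerate configuration: n_segments and n_seeds must be positive")
    if (speckle_scale < 0 || speckle_scale > 1) stop("speckle_scale must lie in [0, 1]")
    if (age_range[1] > age_range[2]) stop("age_range must be increasing")
    if (faz_margin < 1) stop("faz_margin must be at least 1")
  })
  invisible(cfg)
}

# mean-one Rayleigh variates: R = sqrt(-(4/pi) log U)
rayleigh_mean1 <- function(n) sqrt(-(4 / pi) * log(stats::runif(n)))

make_faz_polygon <- function(cfg) {
  size <- cfg$image_size_px
  r_px <- cfg$faz_radius_mm / cfg$mm_extent * size
  centre <- (size + 1) / 2
  nv <- 24L
  angles <- sort(stats::runif(nv, 0, 2 * pi))
  radii <- r_px * stats::runif(nv, 0.9, 1.1)
  cbind(x = centre + radii * cos(angles), y = centre + radii * sin(angles))
}

#' Grow a synthetic vessel tree
#'
#' Grows a stochastic branching network outward from the rim of a randomly
#' shaped FAZ: sprouts start on the rim pointing radially outward and extend
#' in jittered straight segments, occasionally branching with narrower
#' children, until the segment budget is exhausted or all tips have left the
#' field or would enter the FAZ. The FAZ interior stays vessel-free by
#' construction, and the rendered vessel mask (and hence the true vessel
#' fraction) is stored with the tree.
#'
#' @param config A [sim_config()].
#' @param rng_seed Integer seed; the same config and seed reproduce the
#'   identical tree.
#' @param n_segments Segment budget; defaults to `config$n_segments`
#'   (overridden per eye to encode the age effect).
#' @return A `vessel_tree`: list with `segments` (data frame `x0, y0, x1,
#'   y1, width, parent, terminal`), `centreline` (pixel coordinate matrix),
#'   `faz_polygon`, `vessel_mask`, `true_vessel_fraction`, `image_size`.
#' @export
generate_vessel_tree <- function(config, rng_seed, n_segments = config$n_segments) {
  validate_sim_config(config)
  if (n_segments < 1L) stop("degenerate configuration: segment budget must be positive")
  set.seed(rng_seed)
  size <- config$image_size_px
  faz <- make_faz_polygon(config)
  centre <- colMeans(faz)
  # vessels are kept outside an exclusion zone `faz_margin` times the local
  # FAZ radius, reproducing the capillary-free perifoveal margin
  excl <- sweep(sweep(faz, 2, centre) * config$faz_margin, 2, centre, `+`)
  excl_bnd <- rbind(excl, excl[1L, , drop = FALSE])

  # sprouts start just outside the local exclusion radius, pointing outward
  seed_ang <- stats::runif(config$n_seeds, 0, 2 * pi)
  vert_ang <- atan2(faz[, 2] - centre[2], faz[, 1] - centre[1])
  vert_r <- sqrt(rowSums(sweep(faz, 2, centre)^2))
  ord <- order(vert_ang)
  rad_fun <- stats::approxfun(c(vert_ang[ord], vert_ang[ord][1L] + 2 * pi),
                              c(vert_r[ord], vert_r[ord][1L]), rule = 2)
  wrap <- function(a) ((a + pi) %% (2 * pi)) - pi
  rim_r <- config$faz_margin * rad_fun(wrap(seed_ang)) * 1.03
  tips <- data.frame(x = centre[1] + rim_r * cos(seed_ang),
                     y = centre[2] + rim_r * sin(seed_ang),
                     angle = seed_ang + stats::rnorm(config$n_seeds, 0, 0.2),
                     width = config$width_start,
                     parent = NA_integer_)
  segs <- vector("list", 256L)
  n_seg <- 0L
  # coarse occupancy grid (16-px cells) enforcing spatial self-avoidance
  ncell <- ceiling(size / 16)
  occ <- matrix(0L, ncell, ncell)
  cell_of <- function(x, y) cbind(pmin(ncell, pmax(1, ceiling(y / 16))),
                                  pmin(ncell, pmax(1, ceiling(x / 16))))
  while (nrow(tips) > 0L && n_seg < n_segments) {
    nt <- nrow(tips)
    len <- stats::runif(nt, config$seg_len_px[1], config$seg_len_px[2])
    ang <- tips$angle + stats::rnorm(nt, 0, 0.35)
    x1 <- tips$x + len * cos(ang)
    y1 <- tips$y + len * sin(ang)
    inside_img <- x1 >= 2 & x1 <= size - 1 & y1 >= 2 & y1 <= size - 1
    in_excl <- mgcv::in.out(excl_bnd, cbind(x1, y1))
    keep <- which(inside_img & !in_excl)
    if (length(keep) > 0L) {
      # admit tips in cell-visit order until each target cell reaches its cap
      cells <- cell_of(x1[keep], y1[keep])
      admit <- logical(length(keep))
      for (j in seq_along(keep)) {
        if (occ[cells[j, 1L], cells[j, 2L]] < config$cell_cap) {
          admit[j] <- TRUE
          occ[cells[j, 1L], cells[j, 2L]] <- occ[cells[j, 1L], cells[j, 2L]] + 1L
        }
      }
      keep <- keep[admit]
    }
    if (length(keep) == 0L) break
    if (n_seg + length(keep) > n_segments) keep <- keep[seq_len(n_segments - n_seg)]
    new <- data.frame(x0 = tips$x[keep], y0 = tips$y[keep],
                      x1 = x1[keep], y1 = y1[keep],
                      width = tips$width[keep], parent = tips$parent[keep])
    idx <- n_seg + seq_len(nrow(new))
    n_seg <- n_seg + nrow(new)
    segs[[length(segs) + 1L]] <- new
    # every surviving tip continues; some spawn a narrower side branch
    cont <- data.frame(x = new$x1, y = new$y1, angle = ang[keep],
                       width = pmax(config$width_min, new$width * 0.985),
                       parent = idx)
    branch <- stats::runif(nrow(new)) < config$branch_prob
    if (any(branch)) {
      side <- sample(c(-1, 1), sum(branch), replace = TRUE)
      br <- data.frame(x = new$x1[branch], y = new$y1[branch],
                       angle = ang[keep][branch] + side * stats::runif(sum(branch), 0.35, 0.9),
                       width = pmax(config$width_min, new$width[branch] * config$width_decay),
                       parent = idx[branch])
      cont <- rbind(cont, br)
    }
    tips <- cont
  }
  segments <- do.call(rbind, Filter(Negate(is.null), segs))
  if (is.null(segments) || nrow(segments) == 0L)
    stop("degenerate configuration: no vessel segments could be grown")
  rownames(segments) <- NULL
  segments$terminal <- !(seq_len(nrow(segments)) %in% segments$parent)
  build_vessel_tree(segments, faz, config)
}

# rasterize centrelines, dilate per width bucket, cut out the FAZ interior
build_vessel_tree <- function(segments, faz_polygon, config) {
  size <- config$image_size_px
  faz_mask <- rasterize_polygon(faz_polygon, size, size)
  pts <- rasterize_segments(segments, size)
  keep <- !faz_mask[cbind(pts[, 2L], pts[, 1L])]
  centreline <- pts[keep, , drop = FALSE]

  mask <- matrix(FALSE, size, size)
  widths <- pmin(7L, pmax(1L, as.integer(round(segments$width[pts[, 3L]]))))
  for (w in sort(unique(widths))) {
    sel <- widths == w
    wm <- matrix(0L, size, size)
    wm[cbind(pts[sel, 2L], pts[sel, 1L])] <- 1L
    if (w > 1L) {
      brush <- EBImage::makeBrush(if (w %% 2L == 1L) w else w + 1L, shape = "disc")
      wm <- EBImage::dilate(wm, brush)
    }
    mask <- mask | (wm > 0)
  }
  mask[faz_mask] <- FALSE
  structure(list(segments = segments, centreline = centreline,
                 faz_polygon = faz_polygon, vessel_mask = mask,
                 true_vessel_fraction = sum(mask) / length(mask),
                 image_size = size,
                 mm_per_pixel = config$mm_extent / size),
            class = "vessel_tree")
}

# sample points densely along every segment; columns: x, y, segment index
rasterize_segments <- function(segments, size) {
  n <- nrow(segments)
  len <- sqrt((segments$x1 - segments$x0)^2 + (segments$y1 - segments$y0)^2)
  np <- pmax(2L, ceiling(len * 2))
  seg_idx <- rep.int(seq_len(n), np)
  t <- unlist(lapply(np, function(k) seq(0, 1, length.out = k)), use.names = FALSE)
  x <- round(segments$x0[seg_idx] + t * (segments$x1 - segments$x0)[seg_idx])
  y <- round(segments$y0[seg_idx] + t * (segments$y1 - segments$y0)[seg_idx])
  ok <- x >= 1 & x <= size & y >= 1 & y <= size
  cbind(x = as.integer(x[ok]), y = as.integer(y[ok]), seg = seg_idx[ok])
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d segments, %d centreline px, vessel fraction %.3f\n",
              nrow(x$segments), nrow(x$centreline), x$true_vessel_fraction))
  invisible(x)
}

#' Apply capillary dropout to a vessel tree
#'
#' Emulates impaired macular vasculature by pruning the network from the
#' periphery: terminal segments are removed one at a time (parents becoming
#' terminal as their children disappear) until the requested fraction of all
#' segments — rounded half up — has been removed. The true vessel fraction
#' strictly decreases for any positive dropout on a non-empty tree.
#'
#' @param tree A `vessel_tree`.
#' @param dropout_fraction Fraction of segments to remove, in \[0, 1).
#' @param rng_seed Integer seed selecting which terminals are pruned.
#' @param config The [sim_config()] used to build the tree (for re-rendering).
#' @return A `vessel_tree` with the pruned segment set and re-rendered mask.
#' @export
apply_pathology <- function(tree, dropout_fraction, rng_seed, config) {
  stopifnot(dropout_fraction >= 0, dropout_fraction < 1)
  if (dropout_fraction == 0) return(tree)
  set.seed(rng_seed)
  segs <- tree$segments
  n <- nrow(segs)
  n_remove <- floor(dropout_fraction * n + 0.5)
  if (n_remove == 0L) return(tree)
  n_children <- tabulate(segs$parent[!is.na(segs$parent)], nbins = n)
  alive <- rep(TRUE, n)
  for (i in seq_len(n_remove)) {
    terminals <- which(alive & n_children == 0L)
    if (length(terminals) == 0L) break
    victim <- terminals[sample.int(length(terminals), 1L)]
    alive[victim] <- FALSE
    p <- segs$parent[victim]
    if (!is.na(p)) n_children[p] <- n_children[p] - 1L
  }
  pruned <- segs[alive, , drop = FALSE]
  rownames(pruned) <- NULL
  old_idx <- which(alive)
  pruned$parent <- match(pruned$parent, old_idx)
  pruned$terminal <- !(seq_len(nrow(pruned)) %in% pruned$parent)
  build_vessel_tree(pruned, tree$faz_polygon, config)
}

#' Render an angiogram from a vessel tree
#'
#' Vessel pixels are rendered at `vessel_intensity`, background at
#' `background_intensity` (both shifted by `deep_offset` for the deep
#' layer), then multiplied pixel-wise by a mean-one Rayleigh speckle factor
#' blended at `speckle_scale`, and clipped to \[0, 255\]. Rendering twice
#' with different seeds yields the paired test-retest structure: an
#' identical underlying vessel mask under independent noise.
#'
#' @param tree A `vessel_tree`.
#' @param layer `"superficial"` or `"deep"`.
#' @param config A [sim_config()].
#' @param rng_seed Integer seed for the speckle realization.
#' @return A [grey_image()].
#' @export
render_angiogram <- function(tree, layer = c("superficial", "deep"),
                             config, rng_seed) {
  layer <- match.arg(layer)
  stopifnot(tree$image_size == config$image_size_px)
  set.seed(rng_seed)
  off <- if (layer == "deep") config$deep_offset else 0
  base <- matrix(config$background_intensity + off,
                 tree$image_size, tree$image_size)
  base[tree$vessel_mask] <- config$vessel_intensity + off
  s <- config$speckle_scale
  x <- 1
  if (s > 0) {
    x <- matrix(1 + s * (rayleigh_mean1(length(base)) - 1), nrow(base))
    if (config$speckle_grain_px > 0) {
      sd0 <- stats::sd(x)
      x <- EBImage::gblur(x, sigma = config$speckle_grain_px)
      # restore the marginal spread the smoothing removed
      x <- 1 + (x - mean(x)) * sd0 / stats::sd(x)
    }
  }
  px <- pmin(255, pmax(0, round(base * x)))
  grey_image(matrix(as.integer(px), nrow(base)), layer = layer,
             mm_per_pixel = config$mm_extent / config$image_size_px)
}

#' Simulate a manual rater's FAZ delineation
#'
#' Emulates free-hand delineation of the FAZ outer border: every polygon
#' vertex is displaced radially (relative to the polygon centroid) by
#' Gaussian jitter of SD `rater_jitter_px`, and the perturbed polygon is
#' rasterized to a mask. A perturbation yielding a self-intersecting or
#' collapsed polygon is redrawn (up to 25 retries). Zero jitter returns the
#' exact rasterization.
#'
#' @param faz_polygon Two-column vertex matrix (must be a simple polygon).
#' @param rater_jitter_px SD of the radial vertex jitter in pixels.
#' @param rng_seed Integer seed.
#' @param width,height Dimensions of the target mask.
#' @return A logical FAZ mask.
#' @export
simulate_manual_rater <- function(faz_polygon, rater_jitter_px, rng_seed,
                                  width, height) {
  if (!faz_polygon_is_simple(faz_polygon)) stop("FAZ polygon must be simple")
  if (rater_jitter_px == 0)
    return(rasterize_polygon(faz_polygon, width, height))
  set.seed(rng_seed)
  centre <- colMeans(faz_polygon)
  dx <- faz_polygon[, 1] - centre[1]
  dy <- faz_polygon[, 2] - centre[2]
  r <- sqrt(dx^2 + dy^2)
  for (try in seq_len(25L)) {
    r2 <- r + stats::rnorm(nrow(faz_polygon), 0, rater_jitter_px)
    if (any(r2 <= 1)) next
    poly <- cbind(centre[1] + dx / r * r2, centre[2] + dy / r * r2)
    if (faz_polygon_is_simple(poly))
      return(rasterize_polygon(poly, width, height))
  }
  stop("could not draw a simple jittered FAZ polygon in 25 attempts")
}

#' Generate a synthetic test-retest cohort
#'
#' Produces `n_healthy + n_pathology` eye records, each holding two
#' consecutive acquisitions of the superficial and deep layers (four images
#' per eye). Ages are drawn uniformly from `age_range` and scale the
#' vessel-segment budget down with age; pathology eyes additionally undergo
#' capillary dropout. All per-eye and per-image seeds are derived from the
#' master seed by a fixed counter scheme, so any cohort element is
#' reproducible in isolation.
#'
#' @param config A [sim_config()].
#' @return A list of `eye_record`s (class `octa_cohort`), each with
#'   `subject_id`, `eye`, `age`, `group`, `signal_strength`, `faz_polygon`,
#'   `true_vessel_fraction`, `tree`, and `images$<layer>[[acquisition]]`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  n_eyes <- config$n_healthy + config$n_pathology
  stopifnot(n_eyes >= 1L)
  set.seed(config$seed)
  # counter scheme: 6 seeds per eye (tree, pathology, 4 renders), drawn once
  seed_table <- matrix(sample.int(.Machine$integer.max, n_eyes * 6L),
                       nrow = n_eyes)
  ages <- stats::runif(n_eyes, config$age_range[1], config$age_range[2])
  groups <- c(rep("healthy", config$n_healthy),
              rep("pathology", config$n_pathology))
  signal <- sample(9:10, n_eyes, replace = TRUE)
  # two eyes per subject until the count is exhausted (15 subjects / 26 eyes
  # at the default sizes)
  subject <- ceiling(seq_len(n_eyes) / 2)
  eye_side <- rep(c("OD", "OS"), length.out = n_eyes)

  cohort <- vector("list", n_eyes)
  for (i in seq_len(n_eyes)) {
    budget <- max(1L, as.integer(round(
      config$n_segments * (1 - config$age_vd_slope * (ages[i] - config$age_range[1])))))
    tree <- generate_vessel_tree(config, rng_seed = seed_table[i, 1L],
                                 n_segments = budget)
    if (groups[i] == "pathology")
      tree <- apply_pathology(tree, config$dropout_fraction,
                              rng_seed = seed_table[i, 2L], config = config)
    images <- list(
      superficial = list(
        render_angiogram(tree, "superficial", config, seed_table[i, 3L]),
        render_angiogram(tree, "superficial", config, seed_table[i, 4L])),
      deep = list(
        render_angiogram(tree, "deep", config, seed_table[i, 5L]),
        render_angiogram(tree, "deep", config, seed_table[i, 6L])))
    cohort[[i]] <- structure(
      list(subject_id = sprintf("S%02d", subject[i]), eye = eye_side[i],
           eye_id = sprintf("E%02d", i), age = ages[i], group = groups[i],
           signal_strength = signal[i], faz_polygon = tree$faz_polygon,
           true_vessel_fraction = tree$true_vessel_fraction,
           seeds = c(tree = seed_table[i, 1L], pathology = seed_table[i, 2L],
                     supe1 = seed_table[i, 3L], supe2 = seed_table[i, 4L],
                     deep1 = seed_table[i, 5L], deep2 = seed_table[i, 6L]),
           tree = tree, images = images),
      class = "eye_record")
  }
  structure(cohort, class = "octa_cohort", config = config)
}

#' @export
print.octa_cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, character(1), "group")
  cat(sprintf("<octa_cohort> %d eyes (%d healthy, %d pathology), %d images\n",
              length(x), sum(groups == "healthy"), sum(groups == "pathology"),
              4L * length(x)))
  invisible(x)
}
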