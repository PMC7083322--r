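#' Measure one eye: thresholds, vessel density, skeleton density
#'
#' Runs every requested binarization approach on both acquisitions of both
#' layers of an eye record and computes the vessel density (VD) and vessel
#' skeleton density (VSD) of each binarized map: with all seven approaches
#' this yields 2 layers x 2 acquisitions x 7 algorithms = 28 rows per eye.
#'
#' The manual approach follows the clinical protocol: the FAZ is delineated
#' (twice, by the simulated rater) on the superficial image, the maximum
#' grey value inside the delineation is the threshold, the repeat protocol
#' combines the two measurements (third delineation when they differ by 5 or
#' more), and the superficial FAZ selection is transferred verbatim to the
#' deep-layer image.
#'
#' @param record An `eye_record` from [generate_cohort()] (or an equivalent
#'   list read back from disk).
#' @param algorithms Subset of [BINARIZATION_ALGORITHMS].
#' @param faz_masks Optional list of pre-drawn rater masks, one element per
#'   acquisition, each a list of 3 logical masks (third used only when the
#'   repeat protocol requires it). When `NULL` they are simulated from
#'   `record$faz_polygon` with `config$rater_jitter_px` and `rater_seed`.
#' @param config A [sim_config()]; required when `faz_masks` is `NULL` and
#'   `"Manual"` is among `algorithms`.
#' @param rater_seed Integer seed for the simulated rater.
#' @param vd_convention Vessel-density convention, see [vessel_density()].
#' @param percentile_p Target fraction of the Percentile algorithm.
#' @return A data frame with one row per (layer, acquisition, algorithm):
#'   `eye, subject_id, age, group, signal_strength, layer, acquisition,
#'   algorithm, threshold, vd, vsd, vd_convention`.
#' @export
measure_eye <- function(record, algorithms = BINARIZATION_ALGORITHMS,
                        faz_masks = NULL, config = NULL, rater_seed = NULL,
                        vd_convention = c("squared_fraction", "fraction"),
                        percentile_p = 0.5) {
  vd_convention <- match.arg(vd_convention)
  stopifnot(length(algorithms) >= 1L, all(algorithms %in% BINARIZATION_ALGORITHMS))
  for (layer in c("superficial", "deep")) {
    if (length(record$images[[layer]]) != 2L)
      stop(sprintf("eye %s: expected 2 acquisitions of the %s layer",
                   record$eye_id, layer))
  }
  manual <- "Manual" %in% algorithms
  if (manual && is.null(faz_masks)) {
    if (is.null(config) || is.null(rater_seed))
      stop("manual thresholding needs `faz_masks` or `config` + `rater_seed`")
    set.seed(rater_seed)
    mask_seeds <- matrix(sample.int(.Machine$integer.max, 6L), nrow = 2L)
    sz <- config$image_size_px
    faz_masks <- lapply(1:2, function(acq) {
      lapply(1:3, function(j) simulate_manual_rater(
        record$faz_polygon, config$rater_jitter_px, mask_seeds[acq, j], sz, sz))
    })
  }

  rows <- list()
  for (layer in c("superficial", "deep")) {
    for (acq in 1:2) {
      img <- record$images[[layer]][[acq]]
      hist <- grey_histogram(img)
      for (alg in algorithms) {
        tr <- if (alg == "Manual") {
          masks <- faz_masks[[acq]]
          measure_fn <- if (layer == "superficial") {
            function(m) threshold_manual_faz(img, m)
          } else {
            function(m) transfer_faz_to_deep(m, img)
          }
          manual_threshold_protocol(measure_fn(masks[[1L]]),
                                    measure_fn(masks[[2L]]),
                                    t3_provider = function() measure_fn(masks[[3L]]))
        } else {
          auto_threshold(hist, alg, p = percentile_p)
        }
        bin <- binarize(img, tr)
        skel <- skeletonize(bin)
        rows[[length(rows) + 1L]] <- data.frame(
          eye = record$eye_id, subject_id = record$subject_id,
          age = record$age, group = record$group,
          signal_strength = record$signal_strength,
          layer = layer, acquisition = acq, algorithm = alg,
          threshold = tr$threshold,
          vd = vessel_density(bin, vd_convention),
          vsd = vessel_skeleton_density(skel),
          vd_convention = vd_convention,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Measure a whole cohort
#'
#' @param cohort An `octa_cohort` from [generate_cohort()].
#' @param seed Master seed for the simulated manual rater; per-eye rater
#'   seeds are derived from it. Defaults to the cohort's own seed plus one,
#'   so measurement randomness is independent of generation randomness.
#' @inheritParams measure_eye
#' @return A data frame of stacked [measure_eye()] rows (26 eyes x 28 rows
#'   = 728 rows at the default study sizes).
#' @export
measure_cohort <- function(cohort, algorithms = BINARIZATION_ALGORITHMS,
                           vd_convention = c("squared_fraction", "fraction"),
                           percentile_p = 0.5, seed = NULL) {
  vd_convention <- match.arg(vd_convention)
  config <- attr(cohort, "config")
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(seed)
  rater_seeds <- sample.int(.Machine$integer.max, length(cohort))
  out <- lapply(seq_along(cohort), function(i) {
    measure_eye(cohort[[i]], algorithms = algorithms, config = config,
                rater_seed = rater_seeds[i], vd_convention = vd_convention,
                percentile_p = percentile_p)
  })
  do.call(rbind, out)
}
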