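#' Pipeline run configuration
#'
#' Bundles everything a full simulate-measure-compare run needs: the
#' simulation config, the algorithm list and analysis options, the
#' significance level, and the master seed.
#'
#' @param sim A [sim_config()].
#' @param algorithms Subset of [BINARIZATION_ALGORITHMS].
#' @param vd_convention See [vessel_density()].
#' @param percentile_p Percentile-algorithm target fraction.
#' @param rel_diff_denominator See [relative_difference()].
#' @param alpha Significance level.
#' @param power_reps Replicates for the Friedman power simulation.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       algorithms = BINARIZATION_ALGORITHMS,
                       vd_convention = c("squared_fraction", "fraction"),
                       percentile_p = 0.5,
                       rel_diff_denominator = c("pair_mean", "first"),
                       alpha = 0.05,
                       power_reps = 10000L) {
  vd_convention <- match.arg(vd_convention)
  rel_diff_denominator <- match.arg(rel_diff_denominator)
  stopifnot(alpha > 0, alpha < 1, length(algorithms) >= 1L,
            all(algorithms %in% BINARIZATION_ALGORITHMS))
  structure(list(sim = sim, algorithms = algorithms,
                 vd_convention = vd_convention, percentile_p = percentile_p,
                 rel_diff_denominator = rel_diff_denominator, alpha = alpha,
                 power_reps = as.integer(power_reps)),
            class = "run_config")
}

#' Simulate a cohort to disk
#'
#' Generates the synthetic cohort and writes one 8-bit greyscale PNG per
#' (eye, layer, acquisition), one FAZ polygon JSON per eye, the simulation
#' config as JSON, and a manifest CSV recording every seed used.
#'
#' @param config A [run_config()] (or bare [sim_config()]).
#' @param out_dir Output directory (created if absent).
#' @return The manifest data frame, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  sim <- if (inherits(config, "run_config")) config$sim else config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  cohort <- generate_cohort(sim)
  rows <- list()
  for (rec in cohort) {
    write_faz_json(rec$faz_polygon,
                   file.path(out_dir, sprintf("%s_faz.json", rec$eye_id)))
    for (layer in c("superficial", "deep")) {
      for (acq in 1:2) {
        fname <- sprintf("%s_%s_%d.png", rec$eye_id, layer, acq)
        write_grey_png(rec$images[[layer]][[acq]], file.path(out_dir, fname))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = rec$subject_id, eye = rec$eye, eye_id = rec$eye_id,
          age = rec$age, group = rec$group,
          signal_strength = rec$signal_strength,
          true_vessel_fraction = rec$true_vessel_fraction,
          layer = layer, acquisition = acq, file = fname,
          render_seed = rec$seeds[[paste0(substr(layer, 1, 4), acq)]],
          master_seed = sim$seed, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(sim), file.path(out_dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a simulated cohort back from disk
#'
#' @param dir Directory written by [run_simulate()].
#' @return An `octa_cohort` (without the vessel trees, which are not
#'   serialized; ground-truth vessel fractions come from the manifest).
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  cfg_list <- jsonlite::read_json(file.path(dir, "sim_config.json"),
                                  simplifyVector = TRUE)
  cfg_list$age_range <- as.numeric(cfg_list$age_range)
  cfg_list$seg_len_px <- as.numeric(cfg_list$seg_len_px)
  sim <- do.call(sim_config, cfg_list)
  missing <- manifest$file[!file.exists(file.path(dir, manifest$file))]
  if (length(missing) > 0L)
    stop("missing image files: ", paste(missing, collapse = ", "))
  records <- lapply(split(manifest, manifest$eye_id), function(m) {
    m <- m[order(m$layer, m$acquisition), ]
    images <- list(superficial = list(), deep = list())
    for (i in seq_len(nrow(m))) {
      img <- read_grey_png(file.path(dir, m$file[i]), layer = m$layer[i],
                           mm_per_pixel = sim$mm_extent / sim$image_size_px)
      images[[m$layer[i]]][[m$acquisition[i]]] <- img
    }
    structure(list(subject_id = m$subject_id[1L], eye = m$eye[1L],
                   eye_id = m$eye_id[1L], age = m$age[1L], group = m$group[1L],
                   signal_strength = m$signal_strength[1L],
                   faz_polygon = read_faz_json(
                     file.path(dir, sprintf("%s_faz.json", m$eye_id[1L]))),
                   true_vessel_fraction = m$true_vessel_fraction[1L],
                   images = images),
              class = "eye_record")
  })
  records <- records[order(names(records))]
  structure(unname(records), class = "octa_cohort", config = sim)
}

#' Measure a cohort directory to a CSV
#'
#' @param input_dir Directory written by [run_simulate()].
#' @param out_csv Output CSV path for the measurement table.
#' @param config A [run_config()].
#' @return The measurement data frame, invisibly.
#' @export
run_measure <- function(input_dir, out_csv, config = run_config()) {
  cohort <- read_cohort(input_dir)
  measurements <- measure_cohort(cohort, algorithms = config$algorithms,
                                 vd_convention = config$vd_convention,
                                 percentile_p = config$percentile_p)
  dir.create(dirname(out_csv), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(measurements, out_csv, row.names = FALSE)
  invisible(measurements)
}

#' Run the full statistical comparison
#'
#' Executes the whole battery on a measurement table: per-stratum relative
#' differences, ICC and RC; the Friedman omnibus test across algorithms
#' with Wilcoxon post-hoc pairs and Holm-Bonferroni correction; the
#' Mann-Whitney healthy-versus-pathology comparisons; the age-adjusted
#' regression of relative differences; the age correlation; age-adjusted
#' logistic ROC/AUC per stratum with paired DeLong comparisons of the
#' manual approach against each automated algorithm; and the Friedman power
#' simulation at 6 eyes.
#'
#' @param measurements A [measure_cohort()] data frame (or CSV path).
#' @param config A [run_config()].
#' @return An `octa_report` list with components `repeatability`,
#'   `friedman`, `posthoc`, `group_comparison`, `regression`,
#'   `age_correlation`, `roc`, `auc_comparisons`, `power`, `meta`.
#' @export
compare_measurements <- function(measurements, config = run_config()) {
  if (is.character(measurements))
    measurements <- utils::read.csv(measurements, stringsAsFactors = FALSE)
  algs <- intersect(BINARIZATION_ALGORITHMS, unique(measurements$algorithm))
  stopifnot(length(algs) >= 1L)
  if (any(table(measurements$eye, measurements$layer) %%
            (2L * length(algs)) != 0))
    stop("every eye needs 2 acquisitions per layer and algorithm")
  layers <- intersect(c("superficial", "deep"), unique(measurements$layer))
  metrics <- c("vd", "vsd")
  eye_meta <- unique(measurements[, c("eye", "subject_id", "age", "group")])
  eye_meta <- eye_meta[order(eye_meta$eye), ]
  labels <- as.integer(eye_meta$group == "pathology")

  rep_rows <- list(); rel_mats <- list(); fried <- list(); posthoc <- list()
  for (layer in layers) for (metric in metrics) {
    mat <- sapply(algs, function(a) {
      pm <- paired_measurements(measurements, a, layer, metric)
      pm <- pm[order(pm$eye), ]
      relative_difference(pm$m1, pm$m2,
                          denominator = config$rel_diff_denominator)
    })
    rownames(mat) <- sort(unique(measurements$eye))
    key <- paste(metric, layer, sep = ".")
    rel_mats[[key]] <- mat
    if (length(algs) >= 2L) {
      fried[[key]] <- friedman_test(mat)
      ph <- pairwise_posthoc(mat)
      ph$metric <- metric; ph$layer <- layer
      posthoc[[key]] <- ph
    }
    for (a in algs) {
      pm <- paired_measurements(measurements, a, layer, metric)
      icc <- icc_single(pm)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        metric = metric, layer = layer, algorithm = a,
        n = nrow(pm), mean_rel_diff = mean(mat[, a]),
        rc = repeatability_coefficient(pm),
        icc = icc$icc, icc_ci_low = icc$ci_low, icc_ci_high = icc$ci_high,
        stringsAsFactors = FALSE)
    }
  }
  repeatability <- do.call(rbind, rep_rows)

  # healthy vs pathology on per-eye means, and the age correlation
  group_rows <- list(); age_corr <- list()
  for (metric in metrics) {
    per_eye_all <- tapply(measurements[[metric]], measurements$eye, mean)
    per_eye_all <- per_eye_all[eye_meta$eye]
    age_corr[[metric]] <- age_metric_correlation(as.numeric(per_eye_all),
                                                 eye_meta$age)
    for (layer in layers) {
      sub <- measurements[measurements$layer == layer, ]
      per_eye <- tapply(sub[[metric]], sub$eye, mean)[eye_meta$eye]
      mw <- mann_whitney(per_eye[labels == 0L], per_eye[labels == 1L])
      group_rows[[length(group_rows) + 1L]] <- data.frame(
        metric = metric, layer = layer,
        mean_healthy = mean(per_eye[labels == 0L]),
        mean_pathology = mean(per_eye[labels == 1L]),
        u_statistic = mw$statistic, p = mw$p, stringsAsFactors = FALSE)
    }
  }
  group_comparison <- do.call(rbind, group_rows)

  # age-adjusted regression of relative differences, one model per metric
  regression <- list()
  if (length(algs) >= 2L) {
    for (metric in metrics) {
      tab <- do.call(rbind, lapply(layers, function(layer) {
        mat <- rel_mats[[paste(metric, layer, sep = ".")]]
        data.frame(rel_diff = as.vector(mat),
                   age = rep(eye_meta$age, times = ncol(mat)),
                   algorithm = rep(colnames(mat), each = nrow(mat)))
      }))
      regression[[metric]] <- age_adjusted_regression(tab)
    }
  }

  # age-adjusted discrimination per stratum + manual-vs-automated AUC tests
  roc_rows <- list(); rocs <- list(); auc_cmp <- list()
  # discrimination needs both classes and enough eyes for the logistic fit
  if (length(unique(labels)) == 2L && nrow(eye_meta) >= 6L) {
    for (layer in layers) for (metric in metrics) for (a in algs) {
      pm <- paired_measurements(measurements, a, layer, metric)
      pm <- pm[order(pm$eye), ]
      vals <- (pm$m1 + pm$m2) / 2
      d <- discriminate(vals, eye_meta$age, labels)
      rocs[[paste(metric, layer, a, sep = ".")]] <- d
      roc_rows[[length(roc_rows) + 1L]] <- data.frame(
        metric = metric, layer = layer, algorithm = a, auc = d$auc,
        ci_low = d$ci_low, ci_high = d$ci_high,
        separation = d$separation, stringsAsFactors = FALSE)
    }
    if ("Manual" %in% algs && length(algs) >= 2L) {
      for (layer in layers) for (metric in metrics) {
        man <- rocs[[paste(metric, layer, "Manual", sep = ".")]]
        cmp <- lapply(setdiff(algs, "Manual"), function(a) {
          tt <- compare_auc(man, rocs[[paste(metric, layer, a, sep = ".")]])
          data.frame(metric = metric, layer = layer, algorithm = a,
                     auc_manual = man$auc,
                     auc_auto = rocs[[paste(metric, layer, a, sep = ".")]]$auc,
                     z = tt$statistic, p = tt$p, stringsAsFactors = FALSE)
        })
        cmp <- do.call(rbind, cmp)
        cmp$p_c <- holm_bonferroni(cmp$p)
        auc_cmp[[paste(metric, layer, sep = ".")]] <- cmp
      }
    }
  }

  # Friedman power at 6 eyes, from this cohort's VD relative differences
  power <- NULL
  if (length(algs) >= 2L && "vd.superficial" %in% names(rel_mats)) {
    mat <- rel_mats[["vd.superficial"]]
    power <- friedman_power_simulation(colMeans(mat), apply(mat, 2, stats::sd),
                                       n_eyes = 6L, reps = config$power_reps,
                                       alpha = config$alpha,
                                       seed = config$sim$seed + 2L)
  }

  structure(list(
    repeatability = repeatability,
    relative_differences = rel_mats,
    friedman = fried,
    posthoc = if (length(posthoc)) do.call(rbind, unname(posthoc)) else NULL,
    group_comparison = group_comparison,
    regression = regression,
    age_correlation = age_corr,
    roc = if (length(roc_rows)) do.call(rbind, roc_rows) else NULL,
    auc_comparisons = if (length(auc_cmp)) do.call(rbind, unname(auc_cmp)) else NULL,
    power_n6 = power,
    meta = list(vd_convention = config$vd_convention,
                icc_model = "two-way random, absolute agreement, single measures (ICC(A,1))",
                rel_diff_denominator = config$rel_diff_denominator,
                alpha = config$alpha, seed = config$sim$seed,
                n_eyes = nrow(eye_meta), algorithms = algs)),
    class = "octa_report")
}

#' @export
print.octa_report <- function(x, ...) {
  cat(sprintf("<octa_report> %d eyes, %d algorithms; vd_convention=%s, seed=%d\n",
              x$meta$n_eyes, length(x$meta$algorithms),
              x$meta$vd_convention, x$meta$seed))
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits `repeatability.csv`, `tests.csv` (one row per statistical test:
#' name, subset, statistic, raw p, Holm-corrected p), `roc.csv`, and a
#' structured `report.json` carrying every raw and corrected p-value plus
#' the analysis metadata (vessel-density convention, ICC model, seed).
#'
#' @param report An `octa_report` from [compare_measurements()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta_line <- sprintf(
    "vd_convention=%s; icc_model=%s; rel_diff_denominator=%s; seed=%d",
    report$meta$vd_convention, report$meta$icc_model,
    report$meta$rel_diff_denominator, report$meta$seed)

  rep_tab <- report$repeatability
  rep_tab$meta <- meta_line
  utils::write.csv(rep_tab, file.path(out_dir, "repeatability.csv"),
                   row.names = FALSE)

  tests <- list()
  for (key in names(report$friedman)) {
    ft <- report$friedman[[key]]
    tests[[length(tests) + 1L]] <- data.frame(
      test = "Friedman", subset = key, statistic = ft$statistic,
      p = ft$p, p_c = NA_real_, stringsAsFactors = FALSE)
  }
  if (!is.null(report$posthoc)) {
    ph <- report$posthoc
    tests[[length(tests) + 1L]] <- data.frame(
      test = "Wilcoxon signed-rank",
      subset = paste(ph$metric, ph$layer, ph$a, "vs", ph$b),
      statistic = ph$statistic, p = ph$p, p_c = ph$p_c,
      stringsAsFactors = FALSE)
  }
  gc_tab <- report$group_comparison
  tests[[length(tests) + 1L]] <- data.frame(
    test = "Mann-Whitney U (healthy vs pathology)",
    subset = paste(gc_tab$metric, gc_tab$layer),
    statistic = gc_tab$u_statistic, p = gc_tab$p, p_c = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(report$auc_comparisons)) {
    ac <- report$auc_comparisons
    tests[[length(tests) + 1L]] <- data.frame(
      test = "DeLong paired AUC (Manual vs automated)",
      subset = paste(ac$metric, ac$layer, ac$algorithm),
      statistic = ac$z, p = ac$p, p_c = ac$p_c, stringsAsFactors = FALSE)
  }
  tests_tab <- do.call(rbind, tests)
  tests_tab$meta <- meta_line
  utils::write.csv(tests_tab, file.path(out_dir, "tests.csv"),
                   row.names = FALSE)

  if (!is.null(report$roc)) {
    roc_tab <- report$roc
    roc_tab$meta <- meta_line
    utils::write.csv(roc_tab, file.path(out_dir, "roc.csv"), row.names = FALSE)
  }

  json <- list(
    meta = report$meta,
    repeatability = report$repeatability,
    friedman = lapply(report$friedman, function(f)
      list(statistic = f$statistic, p = f$p)),
    posthoc = report$posthoc,
    group_comparison = report$group_comparison,
    regression = lapply(report$regression, function(r)
      list(coefficients = as.list(r$coefficients),
           p_values = as.list(r$p_values))),
    age_correlation = lapply(report$age_correlation, function(a)
      list(r = a$statistic, p = a$p)),
    roc = report$roc,
    auc_comparisons = report$auc_comparisons,
    power_n6 = report$power_n6)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' @rdname compare_measurements
#' @param out_dir Report output directory.
#' @export
run_compare <- function(measurements, out_dir, config = run_config()) {
  report <- compare_measurements(measurements, config)
  write_report(report, out_dir)
  invisible(report)
}
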