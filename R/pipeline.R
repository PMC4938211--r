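#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: the run design, the
#' simulation scenario and noise model, the HRF variant (canonical
#' dual-gamma for cortex-like regions, early-peak for collicular ones), the
#' ROI thresholding rule, the MVPA parameters, and the master seed. Child
#' seeds for each stochastic stage are derived from the master seed by
#' name, so adding a stage never perturbs earlier streams.
#'
#' @param scenario simulation scenario, see [make_dataset()].
#' @param n_participants,n_runs,n_voxels dataset dimensions.
#' @param design a [design_config()].
#' @param hrf_variant `"dual_gamma"` or `"early_peak"`.
#' @param noise_sd,drift_amplitude,baseline,ar1 noise model, see
#'   [simulate_bold_run()].
#' @param threshold_method,threshold_level ROI map thresholding, see
#'   [threshold_map()].
#' @param roi_definition `"auto"` (functional for `cortex_like`, anatomical
#'   otherwise), `"functional_map"` or `"anatomical_label"`.
#' @param max_voxels cap on voxels entering MVPA per participant (500 for
#'   cortex-sized regions, 200 for the superior colliculus).
#' @param n_permutations label permutations for the decoding null.
#' @param curve_sizes voxel sample sizes for the accuracy curve (`NULL`
#'   skips the curve).
#' @param curve_repeats random voxel selections per curve size.
#' @param sample_voxels voxel sample size of the p-value-histogram
#'   analysis (`NULL` skips it).
#' @param n_iterations iterations of the p-value-histogram analysis.
#' @param svm_cost SVM regularisation constant.
#' @param seed master seed.
#' @param ... passed to [ground_truth_patterns()] (gains, `pattern_sd`,
#'   `lateralization`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = "cortex_like",
                            n_participants = 6L,
                            n_runs = 6L,
                            n_voxels = 120L,
                            design = design_config(),
                            hrf_variant = if (scenario == "sc_like")
                              "early_peak" else "dual_gamma",
                            noise_sd = 1,
                            drift_amplitude = 0,
                            baseline = 100,
                            ar1 = 0,
                            threshold_method = "fdr_q",
                            threshold_level = 0.001,
                            roi_definition = "auto",
                            max_voxels = if (scenario == "sc_like") 200L
                              else 500L,
                            n_permutations = 1000L,
                            curve_sizes = NULL,
                            curve_repeats = 20L,
                            sample_voxels = NULL,
                            n_iterations = 1000L,
                            svm_cost = 1,
                            seed = 1L,
                            ...) {
  cfg <- list(scenario = scenario,
              n_participants = as.integer(n_participants),
              n_runs = as.integer(n_runs),
              n_voxels = as.integer(n_voxels),
              design = design,
              hrf_variant = hrf_variant,
              noise_sd = noise_sd,
              drift_amplitude = drift_amplitude,
              baseline = baseline,
              ar1 = ar1,
              threshold_method = threshold_method,
              threshold_level = threshold_level,
              roi_definition = roi_definition,
              max_voxels = as.integer(max_voxels),
              n_permutations = as.integer(n_permutations),
              curve_sizes = curve_sizes,
              curve_repeats = as.integer(curve_repeats),
              sample_voxels = sample_voxels,
              n_iterations = as.integer(n_iterations),
              svm_cost = svm_cost,
              seed = as.integer(seed),
              truth_args = list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Derive a named child seed from a master seed
#'
#' Deterministic, order-independent: the child depends only on the master
#' seed and the stage name, never on how many other stages ran first. The
#' result is kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param name stage name.
#' @return Integer seed.
#' @export
child_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master) %% 65521 * 31013 + h * 7919) %% 2147483647)
}

#' Run the full simulate-fit-decode pipeline
#'
#' Executes the stages in order: synthetic dataset generation, per-
#' participant concatenated-session GLM and ROI definition, univariate
#' condition tables with paired t-tests and the 2 x 2 repeated-measures
#' ANOVA, then per-run GLMs feeding MVPA decoding with its permutation
#' null (and, optionally, the sample-size accuracy curve and the p-value-
#' histogram analysis). Deterministic given the configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, tables and a provenance
#'   block are written there via [summarize_tables()].
#' @return A `run_report` list: `config`, `condition_table` (normalised,
#'   one row per hemisphere-unit), `ipsi_contra_table`, `stats` (paired
#'   t-tests and ANOVA), `mvpa` (per phase: accuracy, null percentile,
#'   significance flag, optional curve and histogram), `roi_sizes`, and a
#'   `provenance` block.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hrf <- hrf_model(config$hrf_variant)

  set.seed(child_seed(config$seed, "simulate"))
  dataset <- do.call(make_dataset, c(list(
    scenario = config$scenario,
    n_participants = config$n_participants,
    n_runs = config$n_runs,
    n_voxels = config$n_voxels,
    config = config$design,
    hrf = hrf,
    noise_sd = config$noise_sd,
    drift_amplitude = config$drift_amplitude,
    baseline = config$baseline,
    ar1 = config$ar1), config$truth_args))

  roi_mode <- config$roi_definition
  if (roi_mode == "auto") {
    roi_mode <- if (config$scenario == "cortex_like") "functional_map"
      else "anatomical_label"
  }

  exec_labels <- c("exec_pro_left", "exec_pro_right",
                   "exec_anti_left", "exec_anti_right")
  left_rows <- list()
  right_rows <- list()
  rois <- list()
  mvpa_sets <- list(preparation = list(), execution = list())

  for (p in seq_along(dataset$participants)) {
    part <- dataset$participants[[p]]
    schedules <- lapply(part$runs, function(r) r$schedule)
    Y <- do.call(cbind, lapply(part$runs, function(r) r$data))
    X <- build_session_design(schedules, "univariate_6reg", hrf)
    fit <- fit_glm(Y, X)

    cvec <- stats::setNames(rep(1 / 4, 4), exec_labels)
    mask <- NULL
    if (roi_mode == "functional_map") {
      tmap <- contrast_t_map(fit, cvec)
      mask <- threshold_map(tmap, config$threshold_method,
                            config$threshold_level)
    }
    hemi <- part$truth$hemisphere
    p_rois <- lapply(c("left", "right"), function(h) {
      define_roi(which(hemi == h), threshold_mask = mask,
                 name = "ROI", hemisphere = h, definition = roi_mode)
    })
    names(p_rois) <- c("left", "right")
    rois[[p]] <- p_rois

    const_cols <- grep("_constant$", fit$regressors)
    vox_baseline <- rowMeans(fit$betas[, const_cols, drop = FALSE])
    unit_row <- function(roi) {
      v <- roi$voxels
      b <- colMeans(fit$betas[v, attr(X, "task_labels"), drop = FALSE])
      data.frame(participant = p, t(b),
                 baseline = mean(vox_baseline[v]),
                 check.names = FALSE)
    }
    left_rows[[p]] <- unit_row(p_rois$left)
    right_rows[[p]] <- unit_row(p_rois$right)

    mv_vox <- sort(unique(c(p_rois$left$voxels, p_rois$right$voxels)))
    if (length(mv_vox) > config$max_voxels) {
      mv_vox <- sort(sample(mv_vox, config$max_voxels))
    }
    per_run <- lapply(part$runs, function(r) {
      Xr <- build_design_matrix(r$schedule, "mvpa_5reg", hrf)
      Xr <- cbind(Xr[, attr(Xr, "task_labels"), drop = FALSE],
                  dct_drift_basis(nrow(Xr)))
      fit_glm(r$data[mv_vox, , drop = FALSE], Xr)
    })
    for (ph in c("preparation", "execution")) {
      mvpa_sets[[ph]][[p]] <- normalize_exemplars(
        build_exemplars(per_run, phase = ph, participant = p))
    }
  }

  left_tab <- do.call(rbind, left_rows)
  right_tab <- do.call(rbind, right_rows)
  ic_tab <- pool_ipsi_contra(left_tab, right_tab)

  cond_cols <- c("prep_pro", "prep_anti",
                 "exec_pro_ipsi", "exec_pro_contra",
                 "exec_anti_ipsi", "exec_anti_contra", "return")
  norm <- normalize_signal_change(ic_tab[, cond_cols], ic_tab$baseline)
  norm_tab <- cbind(ic_tab[, c("participant", "hemisphere")],
                    as.data.frame(norm))
  norm_tab$exec_pro <- (norm_tab$exec_pro_ipsi + norm_tab$exec_pro_contra) / 2
  norm_tab$exec_anti <-
    (norm_tab$exec_anti_ipsi + norm_tab$exec_anti_contra) / 2

  stats_out <- list(
    ipsi_contra_pro = paired_t_test(norm_tab$exec_pro_ipsi,
                                    norm_tab$exec_pro_contra),
    ipsi_contra_anti = paired_t_test(norm_tab$exec_anti_ipsi,
                                     norm_tab$exec_anti_contra),
    prep_anti_vs_pro = paired_t_test(norm_tab$prep_anti, norm_tab$prep_pro),
    exec_anti_vs_pro = paired_t_test(norm_tab$exec_anti, norm_tab$exec_pro)
  )
  long <- data.frame(
    unit = rep(seq_len(nrow(norm_tab)), 4),
    type = rep(rep(c("pro", "anti"), each = nrow(norm_tab)), 2),
    phase = rep(c("preparation", "execution"), each = 2 * nrow(norm_tab)),
    value = c(norm_tab$prep_pro, norm_tab$prep_anti,
              norm_tab$exec_pro, norm_tab$exec_anti))
  stats_out$anova <- rm_anova_2x2(long)

  mvpa_out <- list()
  for (ph in c("preparation", "execution")) {
    set.seed(child_seed(config$seed, paste0("mvpa_", ph)))
    set <- concatenate_participants(mvpa_sets[[ph]])
    acc <- loro_cv_decode(set, cost = config$svm_cost)
    null <- permutation_null(set, config$n_permutations,
                             cost = config$svm_cost)
    res <- list(accuracy = as.numeric(acc),
                fold_accuracies = attr(acc, "fold_accuracies"),
                percentile_95 = null$percentile_95,
                null_mean = mean(null$accuracies),
                significant = as.numeric(acc) > null$percentile_95,
                n_voxels = ncol(set$features))
    if (!is.null(config$curve_sizes)) {
      res$curve <- decoding_curve(set, config$curve_sizes,
                                  n_repeats = config$curve_repeats,
                                  n_permutations = config$n_permutations,
                                  cost = config$svm_cost)
    }
    if (!is.null(config$sample_voxels)) {
      res$pvalue_histogram <- pvalue_histogram(
        set, config$sample_voxels, config$n_iterations,
        cost = config$svm_cost)
    }
    mvpa_out[[ph]] <- res
  }

  report <- list(
    config = config,
    condition_table = norm_tab,
    ipsi_contra_table = ic_tab,
    stats = stats_out,
    mvpa = mvpa_out,
    roi_sizes = lapply(rois, function(r) {
      c(left = length(r$left$voxels), right = length(r$right$voxels))
    }),
    provenance = list(
      package = "prepsaccade",
      version = as.character(utils::packageVersion("prepsaccade")),
      seed = config$seed,
      scenario = config$scenario,
      n_units = nrow(norm_tab))
  )
  class(report) <- "run_report"
  if (!is.null(out_dir)) summarize_tables(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline report (", x$config$scenario, ", seed ", x$config$seed,
      ")\n", sep = "")
  cat("  units:", nrow(x$condition_table),
      " prep anti-vs-pro: t =",
      round(x$stats$prep_anti_vs_pro$statistic, 2),
      ", p =", signif(x$stats$prep_anti_vs_pro$p_value, 3), "\n")
  for (ph in names(x$mvpa)) {
    m <- x$mvpa[[ph]]
    cat("  decoding (", ph, "): accuracy ",
        round(100 * m$accuracy, 1), "% vs null 95th pct ",
        round(100 * m$percentile_95, 1), "% -> ",
        if (m$significant) "significant" else "not significant", "\n",
        sep = "")
  }
  invisible(x)
}

#' Write report tables as TSV files with a provenance block
#'
#' Produces one condition table per phase (mean and standard error per
#' condition across hemisphere-units, the layout of the study's summary
#' tables), the statistics table, any decoding outputs, and a JSON
#' provenance block.
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the named list of file paths written.
#' @export
summarize_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  tab <- report$condition_table
  cond_cols <- setdiff(names(tab), c("participant", "hemisphere"))
  summ <- data.frame(
    condition = cond_cols,
    mean = vapply(cond_cols, function(cc) mean(tab[[cc]]), numeric(1)),
    se = vapply(cond_cols, function(cc) {
      stats::sd(tab[[cc]]) / sqrt(nrow(tab))
    }, numeric(1)),
    n_units = nrow(tab))
  paths$conditions <- file.path(out_dir, "condition_summary.tsv")
  utils::write.table(summ, paths$conditions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$units <- file.path(out_dir, "condition_units.tsv")
  utils::write.table(tab, paths$units, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  tt <- report$stats[setdiff(names(report$stats), "anova")]
  stat_tab <- data.frame(
    test = names(tt),
    statistic = vapply(tt, function(x) x$statistic, numeric(1)),
    dof = vapply(tt, function(x) x$dof, numeric(1)),
    p_value = vapply(tt, function(x) x$p_value, numeric(1)))
  paths$stats <- file.path(out_dir, "paired_tests.tsv")
  utils::write.table(stat_tab, paths$stats, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  av <- report$stats$anova
  anova_tab <- data.frame(
    effect = names(av),
    F = vapply(av, function(x) x$F, numeric(1)),
    dof1 = vapply(av, function(x) x$dof[1], numeric(1)),
    dof2 = vapply(av, function(x) x$dof[2], numeric(1)),
    p_value = vapply(av, function(x) x$p_value, numeric(1)))
  paths$anova <- file.path(out_dir, "anova.tsv")
  utils::write.table(anova_tab, paths$anova, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  mv <- report$mvpa
  mv_tab <- data.frame(
    phase = names(mv),
    accuracy = vapply(mv, function(x) x$accuracy, numeric(1)),
    percentile_95 = vapply(mv, function(x) x$percentile_95, numeric(1)),
    significant = vapply(mv, function(x) x$significant, logical(1)),
    n_voxels = vapply(mv, function(x) x$n_voxels, numeric(1)))
  paths$mvpa <- file.path(out_dir, "decoding.tsv")
  utils::write.table(mv_tab, paths$mvpa, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (ph in names(mv)) {
    if (!is.null(mv[[ph]]$curve)) {
      pth <- file.path(out_dir, paste0("decoding_curve_", ph, ".tsv"))
      utils::write.table(mv[[ph]]$curve, pth, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[[paste0("curve_", ph)]] <- pth
    }
  }

  paths$provenance <- file.path(out_dir, "provenance.json")
  prov <- report$provenance
  prov$config <- config_to_list(report$config)
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$design <- unclass(out$design)
  out
}
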