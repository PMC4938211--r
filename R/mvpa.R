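#' Construct an exemplar set
#'
#' Labelled beta-pattern vectors feeding the decoder: one row per exemplar
#' (a run-by-class beta pattern), one column per voxel. Voxel columns carry
#' a participant tag so that per-participant normalisation still works after
#' cross-participant concatenation.
#'
#' @param features exemplars x voxels numeric matrix.
#' @param class per-exemplar class label, `"pro"` or `"anti"`.
#' @param run per-exemplar run id.
#' @param phase `"preparation"` or `"execution"`.
#' @param voxel_participant per-voxel participant id (recycled if scalar).
#' @return An `exemplar_set`.
#' @export
exemplar_set <- function(features, class, run,
                         phase = c("preparation", "execution"),
                         voxel_participant = 1L) {
  phase <- match.arg(phase)
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(class), length(class) == length(run))
  if (!all(class %in% c("pro", "anti"))) {
    stop("class labels must be 'pro' or 'anti'", call. = FALSE)
  }
  if (!all(is.finite(features))) {
    stop("exemplar features must be finite", call. = FALSE)
  }
  tab <- table(class, run)
  if (any(tab != 1)) {
    stop("each (run, class) pair must contribute exactly one exemplar",
         call. = FALSE)
  }
  structure(list(features = features,
                 class = as.character(class),
                 run = as.integer(run),
                 phase = phase,
                 voxel_participant = rep_len(voxel_participant,
                                             ncol(features))),
            class = "exemplar_set")
}

#' @export
print.exemplar_set <- function(x, ...) {
  cat("Exemplar set:", nrow(x$features), "exemplars x", ncol(x$features),
      "voxels,", length(unique(x$run)), "runs,",
      length(unique(x$voxel_participant)), "participant(s), phase", x$phase,
      "\n")
  invisible(x)
}

#' Build exemplars from per-run GLM betas
#'
#' Selects the two regressors of the requested phase from each run's
#' direction-collapsed (5-regressor scheme) beta estimates, yielding one
#' pro and one anti pattern per run: 6 runs give 12 exemplars.
#'
#' @param per_run_betas list over runs; each element either a
#'   [fit_glm()] result or a voxels x regressors matrix whose columns
#'   include `prep_pro`/`prep_anti` (or `exec_pro`/`exec_anti`).
#' @param phase `"preparation"` or `"execution"`.
#' @param participant participant id attached to the voxel columns.
#' @return An [exemplar_set()].
#' @export
build_exemplars <- function(per_run_betas,
                            phase = c("preparation", "execution"),
                            participant = 1L) {
  phase <- match.arg(phase)
  if (length(per_run_betas) == 0) stop("no runs provided", call. = FALSE)
  prefix <- if (phase == "preparation") "prep" else "exec"
  cols <- paste0(prefix, c("_pro", "_anti"))
  rows <- list()
  class <- character(0)
  run <- integer(0)
  for (r in seq_along(per_run_betas)) {
    B <- per_run_betas[[r]]
    if (inherits(B, "beta_estimates")) {
      M <- B$betas
      colnames(M) <- B$regressors
      B <- M
    }
    if (is.null(B)) stop("missing betas for run ", r, call. = FALSE)
    miss <- setdiff(cols, colnames(B))
    if (length(miss) > 0) {
      stop("run ", r, " betas lack regressor(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- B[, cols[1]]
    rows[[length(rows) + 1L]] <- B[, cols[2]]
    class <- c(class, "pro", "anti")
    run <- c(run, r, r)
  }
  exemplar_set(do.call(rbind, rows), class, run, phase,
               voxel_participant = participant)
}

#' Two-stage exemplar normalisation
#'
#' Stage 1 scales each participant's full feature block to unit magnitude,
#' removing overall amplitude differences between participants. Stage 2
#' rescales each class's block within each participant to unit magnitude,
#' removing amplitude differences between classes so that only the spatial
#' pattern can drive decoding. "Unit magnitude" is root-mean-square = 1 by
#' default; maximum absolute value = 1 is available.
#'
#' @param set an [exemplar_set()].
#' @param method `"rms"` or `"max_abs"`.
#' @return The normalised exemplar set.
#' @export
normalize_exemplars <- function(set, method = c("rms", "max_abs")) {
  method <- match.arg(method)
  stopifnot(inherits(set, "exemplar_set"))
  mag <- function(x) {
    if (method == "rms") sqrt(mean(x^2)) else max(abs(x))
  }
  F <- set$features
  for (p in unique(set$voxel_participant)) {
    vox <- set$voxel_participant == p
    m <- mag(F[, vox])
    if (m == 0) {
      stop("all-zero feature block for participant ", p, call. = FALSE)
    }
    F[, vox] <- F[, vox] / m
    for (cl in unique(set$class)) {
      sel <- set$class == cl
      m2 <- mag(F[sel, vox])
      if (m2 == 0) {
        stop("all-zero class block (participant ", p, ", class ", cl, ")",
             call. = FALSE)
      }
      F[sel, vox] <- F[sel, vox] / m2
    }
  }
  set$features <- F
  set
}

#' Concatenate exemplar sets across participants along the voxel axis
#'
#' Aligns exemplars by (run, class) and joins feature matrices column-wise:
#' the exemplar count is unchanged and the voxel count is the sum over
#' participants, emulating pooling of small ROIs across participants before
#' decoding.
#'
#' @param sets list of [exemplar_set()]s sharing run structure, class
#'   labels and phase.
#' @return A single [exemplar_set()].
#' @export
concatenate_participants <- function(sets) {
  stopifnot(length(sets) >= 1)
  if (length(sets) == 1) return(sets[[1]])
  ref <- sets[[1]]
  ord_ref <- order(ref$run, ref$class)
  feats <- list()
  vox_p <- list()
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (s$phase != ref$phase ||
        !identical(sort(unique(s$run)), sort(unique(ref$run))) ||
        nrow(s$features) != nrow(ref$features)) {
      stop("participant ", i, " has a mismatched run/class structure",
           call. = FALSE)
    }
    ord <- order(s$run, s$class)
    feats[[i]] <- s$features[ord, , drop = FALSE]
    vp <- s$voxel_participant
    if (length(unique(vp)) == 1 && length(sets) > 1) vp <- rep(i, length(vp))
    vox_p[[i]] <- vp
  }
  exemplar_set(do.call(cbind, feats),
               ref$class[ord_ref], ref$run[ord_ref], ref$phase,
               voxel_participant = unlist(vox_p))
}

#' Restrict an exemplar set to a subset of voxels
#'
#' @param set an [exemplar_set()].
#' @param voxels integer column indices to keep.
#' @return The reduced exemplar set.
#' @export
subset_voxels <- function(set, voxels) {
  stopifnot(inherits(set, "exemplar_set"))
  set$features <- set$features[, voxels, drop = FALSE]
  set$voxel_participant <- set$voxel_participant[voxels]
  set
}

# Linear-SVM decision values for one train/test split. An exemplar exactly
# on the decision boundary (value 0) counts as misclassified, as does any
# split whose training features are constant (no separating direction).
svm_fold_correct <- function(train_x, train_y, test_x, test_y, cost) {
  lev <- c("pro", "anti")
  if (length(unique(train_y)) < 2) {
    stop("training fold contains a single class", call. = FALSE)
  }
  if (all(train_x == train_x[1, 1])) {
    return(rep(FALSE, length(test_y)))
  }
  fit <- e1071::svm(train_x, factor(train_y, levels = lev),
                    kernel = "linear", cost = cost, scale = FALSE)
  pr <- stats::predict(fit, test_x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pos_class <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  predicted <- ifelse(dv[, 1] > 0, pos_class, setdiff(lev, pos_class))
  predicted == test_y & dv[, 1] != 0
}

#' Leave-one-run-out cross-validated decoding accuracy
#'
#' Trains a linear-kernel maximum-margin classifier (support vector
#' machine, fixed cost) on all runs but one and tests on the held-out run;
#' every run serves once as the test set and the fold accuracies are
#' averaged.
#'
#' @param set an [exemplar_set()] with at least 2 runs.
#' @param labels optional replacement class labels (used for permutation
#'   testing); defaults to the set's own labels.
#' @param cost SVM regularisation constant.
#' @return Mean accuracy in `[0, 1]`, with attribute `fold_accuracies`.
#' @export
loro_cv_decode <- function(set, labels = NULL, cost = 1) {
  stopifnot(inherits(set, "exemplar_set"))
  runs <- sort(unique(set$run))
  if (length(runs) < 2) stop("need at least 2 runs", call. = FALSE)
  if (is.null(labels)) labels <- set$class
  folds <- vapply(runs, function(r) {
    te <- set$run == r
    mean(svm_fold_correct(set$features[!te, , drop = FALSE], labels[!te],
                          set$features[te, , drop = FALSE], labels[te],
                          cost))
  }, numeric(1))
  structure(mean(folds), fold_accuracies = folds)
}

#' Randomly permute exemplar class labels
#'
#' The default `within_run` scheme shuffles labels independently within
#' each run, preserving the one-pro-one-anti balance of every run and
#' therefore of every leave-one-run-out training fold. `free` shuffles
#' labels across all exemplars; it leaves many training folds
#' class-imbalanced, which biases the cross-validated null accuracy below
#' chance (a majority-class effect), and is provided for comparison only.
#'
#' @param set an [exemplar_set()].
#' @param scheme `"within_run"` or `"free"`.
#' @return A character vector of permuted labels.
#' @export
permute_labels <- function(set, scheme = c("within_run", "free")) {
  scheme <- match.arg(scheme)
  if (scheme == "free") return(sample(set$class))
  lab <- set$class
  for (r in unique(set$run)) {
    idx <- which(set$run == r)
    lab[idx] <- lab[idx][sample.int(length(idx))]
  }
  lab
}

#' Permutation null distribution of decoding accuracy
#'
#' Shuffles the class labels (see [permute_labels()]) and repeats the
#' identical leave-one-run-out decoding, building the empirical null of
#' accuracies; its 95th percentile is the significance criterion for the
#' true-label accuracy. Random draws are restricted to relabelings that
#' differ from the observed labeling and from its global class swap
#' (which decodes identically), so the null contains only genuinely
#' shuffled assignments; exhaustive enumeration keeps every assignment.
#'
#' @param set an [exemplar_set()].
#' @param n_permutations number of random label permutations.
#' @param cost SVM regularisation constant.
#' @param scheme label permutation scheme, see [permute_labels()].
#' @param exhaustive if `TRUE`, enumerate every distinct label assignment
#'   the scheme can reach instead of sampling (feasible only for small
#'   sets); `n_permutations` is ignored.
#' @return A `permutation_null`: list with `accuracies`, `n_permutations`
#'   and `percentile_95`.
#' @export
permutation_null <- function(set, n_permutations = 1000, cost = 1,
                             scheme = c("within_run", "free"),
                             exhaustive = FALSE) {
  stopifnot(inherits(set, "exemplar_set"))
  scheme <- match.arg(scheme)
  if (exhaustive) {
    labs <- enumerate_labelings(set, scheme)
    acc <- vapply(labs, function(lab) {
      as.numeric(loro_cv_decode(set, labels = lab, cost = cost))
    }, numeric(1))
  } else {
    stopifnot(n_permutations >= 1)
    swapped <- ifelse(set$class == "pro", "anti", "pro")
    acc <- vapply(seq_len(n_permutations), function(i) {
      # draw a relabeling distinct from the observed one; the global
      # class swap is its decoding-equivalent and is excluded too
      for (try in 1:100) {
        lab <- permute_labels(set, scheme)
        if (!identical(lab, set$class) && !identical(lab, swapped)) break
      }
      as.numeric(loro_cv_decode(set, labels = lab, cost = cost))
    }, numeric(1))
  }
  structure(list(accuracies = acc,
                 n_permutations = length(acc),
                 percentile_95 = unname(stats::quantile(acc, 0.95))),
            class = "permutation_null")
}

# All distinct label assignments reachable by a permutation scheme:
# within_run flips each run's pro/anti pair or not (2^runs assignments);
# free places the pro labels on any subset of the right size.
enumerate_labelings <- function(set, scheme) {
  if (scheme == "free") {
    n_pro <- sum(set$class == "pro")
    picks <- utils::combn(length(set$class), n_pro)
    return(lapply(seq_len(ncol(picks)), function(j) {
      lab <- rep("anti", length(set$class))
      lab[picks[, j]] <- "pro"
      lab
    }))
  }
  runs <- sort(unique(set$run))
  flips <- expand.grid(rep(list(c(FALSE, TRUE)), length(runs)))
  lapply(seq_len(nrow(flips)), function(j) {
    lab <- set$class
    for (k in seq_along(runs)) {
      if (flips[j, k]) {
        idx <- set$run == runs[k]
        lab[idx] <- rev(lab[idx])
      }
    }
    lab
  })
}

#' Decoding accuracy as a function of voxel sample size
#'
#' For each sample size, decodes `n_repeats` random voxel subsets with the
#' true labels and averages the accuracies; a matched permutation null
#' (fresh random subset and shuffled labels per permutation) yields the
#' 95th-percentile criterion at each size.
#'
#' @param set an [exemplar_set()].
#' @param sizes increasing voxel sample sizes, all at most the voxel count.
#' @param n_repeats random voxel selections per size.
#' @param n_permutations permutations per size for the null criterion
#'   (0 skips the null).
#' @param cost SVM regularisation constant.
#' @param scheme label permutation scheme, see [permute_labels()].
#' @return A data frame with columns `size`, `mean_accuracy`,
#'   `percentile_95` (NA if the null is skipped).
#' @export
decoding_curve <- function(set, sizes, n_repeats = 20, n_permutations = 200,
                           cost = 1, scheme = "within_run") {
  stopifnot(inherits(set, "exemplar_set"))
  sizes <- as.integer(sizes)
  n_vox <- ncol(set$features)
  if (any(sizes > n_vox)) {
    stop("sample size exceeds voxel count (", n_vox, ")", call. = FALSE)
  }
  if (is.unsorted(sizes, strictly = TRUE)) {
    stop("sizes must be strictly increasing", call. = FALSE)
  }
  out <- lapply(sizes, function(sz) {
    accs <- vapply(seq_len(n_repeats), function(i) {
      sub <- subset_voxels(set, sample.int(n_vox, sz))
      as.numeric(loro_cv_decode(sub, cost = cost))
    }, numeric(1))
    p95 <- NA_real_
    if (n_permutations > 0) {
      null_accs <- vapply(seq_len(n_permutations), function(i) {
        sub <- subset_voxels(set, sample.int(n_vox, sz))
        as.numeric(loro_cv_decode(sub,
                                  labels = permute_labels(set, scheme),
                                  cost = cost))
      }, numeric(1))
      p95 <- unname(stats::quantile(null_accs, 0.95))
    }
    data.frame(size = sz, mean_accuracy = mean(accs), percentile_95 = p95)
  })
  do.call(rbind, out)
}

#' P-value histogram analysis at a fixed voxel sample size
#'
#' Per iteration: draw a fresh random voxel subset and a fresh label
#' permutation, decode both the true-label and permuted-label sets, and
#' compare the two vectors of fold accuracies with a two-sample t-test.
#' Collects the p-values; under the null they are uniform, so about 5%
#' fall below 0.05, while genuine class information makes them cluster at
#' low values.
#'
#' @param set an [exemplar_set()].
#' @param sample_voxels voxels drawn per iteration.
#' @param n_iterations number of subset/permutation iterations.
#' @param alpha significance threshold for the count summary.
#' @param cost SVM regularisation constant.
#' @param scheme label permutation scheme, see [permute_labels()].
#' @return A `pvalue_histogram`: list with `p_values`, `sample_voxels`,
#'   `count_below_alpha` and `alpha`.
#' @export
pvalue_histogram <- function(set, sample_voxels = 500, n_iterations = 1000,
                             alpha = 0.05, cost = 1,
                             scheme = "within_run") {
  stopifnot(inherits(set, "exemplar_set"))
  n_vox <- ncol(set$features)
  if (sample_voxels > n_vox) {
    stop("sample_voxels exceeds voxel count (", n_vox, ")", call. = FALSE)
  }
  pv <- vapply(seq_len(n_iterations), function(i) {
    sub <- subset_voxels(set, sample.int(n_vox, sample_voxels))
    a_true <- attr(loro_cv_decode(sub, cost = cost), "fold_accuracies")
    a_perm <- attr(loro_cv_decode(sub,
                                  labels = permute_labels(set, scheme),
                                  cost = cost), "fold_accuracies")
    if (stats::sd(a_true) == 0 && stats::sd(a_perm) == 0) {
      return(if (mean(a_true) == mean(a_perm)) 1 else 0)
    }
    stats::t.test(a_true, a_perm, var.equal = TRUE)$p.value
  }, numeric(1))
  structure(list(p_values = pv,
                 sample_voxels = sample_voxels,
                 count_below_alpha = sum(pv < alpha),
                 alpha = alpha),
            class = "pvalue_histogram")
}

#' Export an exemplar set to TSV files
#'
#' Writes a metadata table (exemplar id, participant structure, run, class,
#' phase) and the feature matrix.
#'
#' @param set an [exemplar_set()].
#' @param meta_path,matrix_path output file paths.
#' @return Invisibly, the metadata data frame.
#' @export
write_exemplars_tsv <- function(set, meta_path, matrix_path) {
  meta <- data.frame(exemplar = seq_along(set$class),
                     run = set$run,
                     class = set$class,
                     phase = set$phase)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(set$features, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(meta)
}
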