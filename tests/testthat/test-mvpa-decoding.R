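test_that("exemplar construction selects the requested phase per run", {
  set.seed(51)
  d <- make_dataset("cortex_like", n_participants = 1, n_runs = 6,
                    n_voxels = 12, config = tiny_config(4))
  fits <- per_run_mvpa_fits(d$participants[[1]])
  ex <- build_exemplars(fits, "preparation")
  expect_equal(nrow(ex$features), 12)  # 6 runs x 2 classes
  expect_equal(sort(unique(ex$run)), 1:6)
  expect_equal(table(ex$class)[["pro"]], 6)
  # features are exactly the prep regressor betas, not exec
  expect_equal(unname(ex$features[ex$run == 3 & ex$class == "anti", ]),
               unname(fits[[3]]$betas[, "prep_anti"]))
  ex2 <- build_exemplars(fits[1:2], "execution")
  expect_equal(nrow(ex2$features), 4)
  expect_equal(unname(ex2$features[1, ]),
               unname(fits[[1]]$betas[, "exec_pro"]))
  fits_bad <- fits
  fits_bad[[2]] <- NULL  # drops to 5 runs; still fine
  expect_equal(nrow(build_exemplars(fits_bad, "preparation")$features), 10)
  fits_bad[[1]] <- fits[[1]]$betas[, 1, drop = FALSE]
  expect_error(build_exemplars(fits_bad, "preparation"), "lack regressor")
})

test_that("two-stage normalization gives unit per-class magnitude", {
  set.seed(52)
  ex <- toy_exemplar_set(n_runs = 6, n_voxels = 15)
  nx <- normalize_exemplars(ex)
  for (cl in c("pro", "anti")) {
    rms <- sqrt(mean(nx$features[nx$class == cl, ]^2))
    expect_equal(rms, 1, tolerance = 1e-12)
  }
  # classes differing only by a global gain coincide after normalization
  base <- matrix(rnorm(6 * 10), 6, 10)
  ex2 <- exemplar_set(rbind(base, 2 * base),
                      class = rep(c("pro", "anti"), each = 6),
                      run = rep(1:6, 2), phase = "execution")
  nx2 <- normalize_exemplars(ex2)
  expect_equal(colMeans(nx2$features[nx2$class == "pro", ]),
               colMeans(nx2$features[nx2$class == "anti", ]),
               tolerance = 1e-10)
  expect_error(normalize_exemplars(
    exemplar_set(matrix(0, 4, 3), rep(c("pro", "anti"), 2),
                 rep(1:2, each = 2))), "all-zero")
})

test_that("cross-participant concatenation joins the voxel axis", {
  set.seed(53)
  sets <- lapply(1:6, function(p) {
    s <- toy_exemplar_set(n_runs = 6, n_voxels = 300)
    s$voxel_participant <- rep(p, 300)
    s
  })
  cc <- concatenate_participants(sets)
  expect_equal(dim(cc$features), c(12, 1800))
  expect_equal(length(unique(cc$voxel_participant)), 6)
  # single participant: identity
  expect_identical(concatenate_participants(sets[1]), sets[[1]])
  # concatenating then subsampling = subsampling each then concatenating
  idx <- sample(1800, 40)
  direct <- subset_voxels(cc, idx)$features
  ord <- order(sets[[1]]$run, sets[[1]]$class)
  stacked <- do.call(cbind, lapply(sets,
                                   function(s) s$features[ord, ]))[, idx]
  expect_equal(direct, stacked)
  bad <- sets
  bad[[2]]$run <- bad[[2]]$run + 10
  expect_error(concatenate_participants(bad), "mismatched")
})

test_that("alignment by run and class is respected when orders differ", {
  f1 <- matrix(seq_len(8), 4, 2)
  s1 <- exemplar_set(f1, c("pro", "anti", "pro", "anti"),
                     c(1, 1, 2, 2), voxel_participant = 1)
  # second participant stores the same exemplars in scrambled order
  perm <- c(4, 1, 3, 2)
  s2 <- exemplar_set((10 * f1)[perm, ],
                     c("pro", "anti", "pro", "anti")[perm],
                     c(1, 1, 2, 2)[perm], voxel_participant = 2)
  cc <- concatenate_participants(list(s1, s2))
  for (i in seq_along(cc$class)) {
    row1 <- cc$features[i, 1:2]
    row2 <- cc$features[i, 3:4]
    expect_equal(row2, 10 * row1)
  }
})

test_that("leave-one-run-out decoding averages the run folds", {
  set.seed(54)
  # cleanly separable classes decode perfectly
  ex <- toy_exemplar_set(n_runs = 6, n_voxels = 10, sep = 10, noise = 0.01)
  acc <- loro_cv_decode(ex)
  expect_equal(as.numeric(acc), 1)
  expect_equal(length(attr(acc, "fold_accuracies")), 6)
  # signal-free decoding hovers at chance over repeated label shuffles
  null_ex <- toy_exemplar_set(n_runs = 6, n_voxels = 10)
  accs <- replicate(200, as.numeric(
    loro_cv_decode(null_ex, labels = permute_labels(null_ex))))
  expect_lt(abs(mean(accs) - 0.5), 0.03)
  # free shuffling leaves training folds imbalanced and pulls the null
  # mean below chance (the reason within-run is the default)
  accs_free <- replicate(200, as.numeric(
    loro_cv_decode(null_ex, labels = permute_labels(null_ex, "free"))))
  expect_lt(mean(accs_free), mean(accs))
  # single run is undefined
  one_run <- exemplar_set(matrix(rnorm(4), 2, 2), c("pro", "anti"),
                          c(1, 1))
  expect_error(loro_cv_decode(one_run), "at least 2 runs")
})

test_that("decoding is invariant to common positive feature rescaling", {
  set.seed(55)
  ex <- toy_exemplar_set(n_runs = 4, n_voxels = 12, sep = 0.3)
  ex2 <- ex
  ex2$features <- ex$features * 3.7
  expect_identical(as.numeric(loro_cv_decode(ex)),
                   as.numeric(loro_cv_decode(ex2)))
})

test_that("identical exemplars give a degenerate, fully tied null", {
  ex <- exemplar_set(matrix(1, 8, 5), rep(c("pro", "anti"), 4),
                     rep(1:4, each = 2))
  null <- permutation_null(ex, n_permutations = 20)
  expect_equal(var(null$accuracies), 0)
  expect_equal(unique(null$accuracies), 0)  # on-margin counts as wrong
})

test_that("permutation distribution matches exhaustive enumeration", {
  set.seed(56)
  # 4-exemplar, 2-run miniature under within-run shuffling: 2^2 = 4
  # reachable assignments, enumerated independently here by flipping each
  # run's label pair
  ex <- toy_exemplar_set(n_runs = 2, n_voxels = 6, sep = 1)
  enum <- sapply(list(c(1, 2, 3, 4), c(2, 1, 3, 4),
                      c(1, 2, 4, 3), c(2, 1, 4, 3)), function(ord) {
    as.numeric(loro_cv_decode(ex, labels = ex$class[ord]))
  })
  exh <- permutation_null(ex, exhaustive = TRUE)
  expect_equal(sort(exh$accuracies), sort(enum))
  # random sampling reaches exactly the achievable non-identity
  # assignments (the observed labeling and its global swap are excluded
  # from sampled nulls)
  samp <- permutation_null(ex, n_permutations = 200)
  null_enum <- enum[2:3]  # single-run flips; 1 and 4 are identity/swap
  expect_true(all(samp$accuracies %in% null_enum))
  expect_equal(sort(unique(samp$accuracies)), sort(unique(null_enum)))
  expect_equal(samp$n_permutations, 200)
  expect_equal(samp$percentile_95,
               unname(quantile(samp$accuracies, 0.95)))

  # free-scheme enumeration on a 3-run miniature against a combn oracle
  ex3 <- toy_exemplar_set(n_runs = 3, n_voxels = 6, sep = 1)
  enum3 <- apply(combn(6, 3), 2, function(idx) {
    lab <- rep("anti", 6)
    lab[idx] <- "pro"
    as.numeric(loro_cv_decode(ex3, labels = lab))
  })
  exh3 <- permutation_null(ex3, scheme = "free", exhaustive = TRUE)
  expect_equal(sort(exh3$accuracies), sort(enum3))
})

test_that("a training fold reduced to one class is an error", {
  ex <- toy_exemplar_set(n_runs = 2, n_voxels = 4)
  expect_error(loro_cv_decode(ex, labels = c("pro", "pro", "anti", "anti")),
               "single class")
})

test_that("decoding curves grow with informative voxels and validate sizes", {
  set.seed(57)
  ex <- toy_exemplar_set(n_runs = 6, n_voxels = 60, sep = 0.25)
  curve <- decoding_curve(ex, c(2, 10, 40), n_repeats = 8,
                          n_permutations = 0)
  expect_equal(curve$size, c(2, 10, 40))
  expect_true(all(curve$mean_accuracy >= 0 & curve$mean_accuracy <= 1))
  expect_gt(curve$mean_accuracy[3], curve$mean_accuracy[1])
  # full-sample size with repeats: every repeat sees the whole set
  full <- decoding_curve(ex, 60L, n_repeats = 5, n_permutations = 0)
  expect_equal(full$mean_accuracy, as.numeric(loro_cv_decode(ex)))
  expect_error(decoding_curve(ex, c(10, 100)), "exceeds voxel count")
  expect_error(decoding_curve(ex, c(40, 10)), "increasing")
})

test_that("p-value histograms are computed per subset and permutation", {
  set.seed(58)
  ex <- toy_exemplar_set(n_runs = 6, n_voxels = 40)
  ph <- pvalue_histogram(ex, sample_voxels = 20, n_iterations = 50)
  expect_equal(length(ph$p_values), 50)
  expect_true(all(ph$p_values >= 0 & ph$p_values <= 1))
  expect_equal(ph$count_below_alpha, sum(ph$p_values < 0.05))
  # all-tied folds hit the degenerate branch
  tied <- exemplar_set(matrix(1, 12, 8), rep(c("pro", "anti"), 6),
                       rep(1:6, each = 2))
  ph2 <- pvalue_histogram(tied, sample_voxels = 8, n_iterations = 5)
  expect_true(all(ph2$p_values == 1))
  expect_error(pvalue_histogram(ex, sample_voxels = 100), "exceeds")
})
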