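test_that("ROI definition intersects functional maps with templates", {
  mask <- c(rep(TRUE, 6), rep(FALSE, 6))
  roi <- define_roi(1:6, mask, name = "FEF", hemisphere = "left",
                    definition = "functional_map")
  expect_equal(roi$voxels, 1:6)  # threshold mask equals the template label
  roi2 <- define_roi(4:9, mask, definition = "functional_map")
  expect_equal(roi2$voxels, 4:6)
  anat <- define_roi(7:12, definition = "anatomical_label",
                     hemisphere = "right")
  expect_equal(anat$voxels, 7:12)
  expect_error(define_roi(7:12, mask, definition = "functional_map"),
               "empty")
  expect_error(define_roi(1:3, definition = "functional_map"),
               "threshold mask")
})

test_that("null data yield an empty functional ROI via the exec contrast", {
  d <- make_dataset("null", n_participants = 1, n_runs = 2, n_voxels = 20,
                    config = tiny_config(4), seed = 41)
  part <- d$participants[[1]]
  X <- build_session_design(lapply(part$runs, function(r) r$schedule),
                            "univariate_6reg")
  fit <- fit_glm(do.call(cbind, lapply(part$runs, function(r) r$data)), X)
  cv <- setNames(rep(1 / 4, 4), c("exec_pro_left", "exec_pro_right",
                                  "exec_anti_left", "exec_anti_right"))
  mask <- threshold_map(contrast_t_map(fit, cv), "uncorrected_p", 1e-4)
  expect_error(define_roi(1:20, mask, definition = "functional_map"),
               "empty")
})

test_that("functional ROIs recover the ground-truth signal voxels", {
  set.seed(42)
  A <- zero_amplitude(60)
  signal_vox <- 1:30
  for (k in grep("^exec", colnames(A))) A[signal_vox, k] <- 2
  truth <- manual_truth(A)
  scheds <- replicate(3, build_run_schedule(design_config()),
                      simplify = FALSE)
  runs <- lapply(scheds, simulate_bold_run, patterns = truth, noise_sd = 1)
  X <- build_session_design(scheds, "univariate_6reg")
  fit <- fit_glm(do.call(cbind, lapply(runs, function(r) r$data)), X)
  cv <- setNames(rep(1 / 4, 4), c("exec_pro_left", "exec_pro_right",
                                  "exec_anti_left", "exec_anti_right"))
  mask <- threshold_map(contrast_t_map(fit, cv), "fdr_q", 0.001)
  roi <- define_roi(1:60, mask, definition = "functional_map")
  recovered <- mean(signal_vox %in% roi$voxels)
  expect_gte(recovered, 0.95)
  false_pos <- mean(setdiff(1:60, signal_vox) %in% roi$voxels)
  expect_lte(false_pos, 0.2)
})

test_that("ipsi/contra pooling relabels directions per hemisphere", {
  left <- data.frame(participant = 1:2,
                     exec_pro_left = c(1, 2), exec_pro_right = c(3, 4),
                     exec_anti_left = c(5, 6), exec_anti_right = c(7, 8))
  right <- data.frame(participant = 1:2,
                      exec_pro_left = c(10, 20), exec_pro_right = c(30, 40),
                      exec_anti_left = c(50, 60),
                      exec_anti_right = c(70, 80))
  tab <- pool_ipsi_contra(left, right)
  expect_equal(nrow(tab), 4)
  # a left-hemisphere rightward beta lands in the contralateral column
  expect_equal(tab$exec_pro_contra[tab$hemisphere == "left"], c(3, 4))
  expect_equal(tab$exec_pro_ipsi[tab$hemisphere == "left"], c(1, 2))
  # a right-hemisphere rightward beta is ipsilateral
  expect_equal(tab$exec_pro_ipsi[tab$hemisphere == "right"], c(30, 40))
  # swapping the hemisphere inputs swaps ipsi and contra exactly
  swapped <- pool_ipsi_contra(right, left)
  expect_equal(sort(swapped$exec_anti_ipsi), sort(tab$exec_anti_contra))
  expect_error(pool_ipsi_contra(left, NULL), "both hemispheres")
  expect_error(pool_ipsi_contra(left[, 1:3], right), "missing")
})

test_that("without lateralization the ipsi/contra contrast is null", {
  set.seed(43)
  rejections <- replicate(40, {
    d <- make_dataset("cortex_like", n_participants = 2, n_runs = 3,
                      n_voxels = 16, config = tiny_config(8))
    rows <- lapply(c("left", "right"), function(h) {
      do.call(rbind, lapply(d$participants, function(part) {
        X <- build_session_design(lapply(part$runs,
                                         function(r) r$schedule),
                                  "univariate_6reg")
        fit <- fit_glm(do.call(cbind,
                               lapply(part$runs, function(r) r$data)), X)
        v <- which(part$truth$hemisphere == h)
        as.data.frame(t(colMeans(fit$betas[v, attr(X, "task_labels")])))
      }))
    })
    tab <- pool_ipsi_contra(rows[[1]], rows[[2]])
    t_pro <- paired_t_test(tab$exec_pro_ipsi, tab$exec_pro_contra)
    t_pro$p_value < 0.05
  })
  expect_lte(mean(rejections), 0.05 + 2 * sqrt(0.05 * 0.95 / 40) + 1e-9)
})

test_that("percent-signal-change normalization removes unit gain", {
  B <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8))  # unit 2 = 2 x unit 1
  norm <- normalize_signal_change(B, baseline_level = 100)
  expect_equal(norm[1, ], norm[2, ], tolerance = 1e-10)
  # hand-computed rescaling for unit 1: psc / unit mean * grand mean
  psc <- 100 * B / 100
  expect_equal(unname(norm[1, ]), psc[1, ] / mean(psc[1, ]) * mean(psc),
               tolerance = 1e-12)
  # zero maps to zero; doubling betas and baseline together is a no-op
  expect_equal(normalize_signal_change(rbind(c(0, 1), c(0, 2)), 50)[, 1],
               c(0, 0))
  expect_equal(normalize_signal_change(2 * B, c(200, 200)),
               normalize_signal_change(B, c(100, 100)))
  expect_error(normalize_signal_change(B, 0), "positive")
})

test_that("paired t-test matches the closed-form oracle", {
  set.seed(44)
  for (i in 1:25) {
    a <- rnorm(8)
    b <- rnorm(8)
    got <- paired_t_test(a, b)
    want <- paired_t_oracle(a, b)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    expect_equal(got$dof, 7)
  }
  x <- rnorm(12)
  expect_equal(paired_t_test(x, x + rnorm(12))$dof, 11)
  same <- paired_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_t_test(x, x - 1), "zero variance")
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(45)
  for (i in 1:100) {
    n_units <- sample(c(6, 12), 1)
    tab <- expand.grid(unit = seq_len(n_units),
                       type = c("pro", "anti"),
                       phase = c("preparation", "execution"))
    tab$value <- rnorm(nrow(tab)) +
      0.5 * (tab$type == "anti") + 0.8 * (tab$phase == "execution")
    got <- rm_anova_2x2(tab)
    want <- rm_anova_oracle(tab)
    for (eff in c("type", "phase", "interaction")) {
      expect_equal(got[[eff]]$F, want[[eff]]$F, tolerance = 1e-8)
      expect_equal(got[[eff]]$p_value, want[[eff]]$p_value,
                   tolerance = 1e-8)
      expect_equal(got[[eff]]$dof, c(1, n_units - 1))
    }
    # the SS decomposition is exhaustive: effects + errors = total
    ss <- want$ss
    expect_equal(ss$type + ss$phase + ss$interaction + ss$type_x_unit +
                   ss$phase_x_unit + ss$residual + ss$unit,
                 ss$total, tolerance = 1e-8)
  }
})

test_that("ANOVA degenerate and malformed tables are handled", {
  tab <- expand.grid(unit = 1:12, type = c("pro", "anti"),
                     phase = c("preparation", "execution"))
  tab$value <- rnorm(48)
  # identical values across one factor's levels per unit: F = 0
  tab2 <- tab
  base <- rnorm(12)
  tab2$value <- base[tab2$unit] + 0.7 * (tab2$phase == "execution")
  got <- rm_anova_2x2(tab2)
  expect_equal(got$type$F, 0, tolerance = 1e-12)
  expect_gt(got$phase$F, 1)
  expect_error(rm_anova_2x2(tab[-1, ]), "incomplete")
  expect_error(rm_anova_2x2(tab[, -4]), "missing column")
})
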