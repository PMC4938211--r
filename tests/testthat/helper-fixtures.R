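# Shared fixtures and independent oracles used across the test files.

# A shorter run design (fewer trials) for structural tests where the full
# 20-trial run would only add runtime.
tiny_config <- function(n_trials = 8L, ...) {
  design_config(n_trials_per_run = n_trials,
                n_pro = n_trials / 2L, n_anti = n_trials / 2L, ...)
}

# Hand-built schedule from explicit events (onset, kind), for tests that
# need exact control over event placement.
manual_schedule <- function(onsets, kinds, tr = 1.5, duration = 40,
                            impulse_s = 0.5) {
  sched <- data.frame(onset = onsets, kind = kinds,
                      duration = rep(impulse_s, length(onsets)),
                      stringsAsFactors = FALSE)
  attr(sched, "total_duration") <- duration
  attr(sched, "n_volumes") <- as.integer(ceiling(duration / tr))
  attr(sched, "tr") <- tr
  class(sched) <- c("run_schedule", "data.frame")
  sched
}

# Ground truth with fully specified amplitudes (voxels x event kinds).
manual_truth <- function(amplitude, hemisphere = NULL) {
  if (is.null(hemisphere)) {
    hemisphere <- rep(c("left", "right"), length.out = nrow(amplitude))
  }
  structure(list(amplitude = amplitude, hemisphere = hemisphere,
                 scenario = "manual"),
            class = "ground_truth")
}

zero_amplitude <- function(n_voxels) {
  matrix(0, n_voxels, length(event_kinds()),
         dimnames = list(NULL, event_kinds()))
}

# --- independent oracles ---------------------------------------------------

# OLS via explicit normal equations, one voxel at a time.
ols_oracle <- function(y, X) {
  drop(solve(t(X) %*% X) %*% t(X) %*% y)
}

# t statistic for contrast c from first principles.
t_oracle <- function(y, X, cvec) {
  b <- ols_oracle(y, X)
  res <- y - X %*% b
  dof <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / dof
  drop(t(cvec) %*% b) / sqrt(s2 * drop(t(cvec) %*% solve(t(X) %*% X) %*% cvec))
}

# Paired t from first principles.
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  tt <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = tt, dof = n - 1,
       p_value = 2 * pt(-abs(tt), n - 1))
}

# 2x2 within-unit ANOVA by explicit sums-of-squares decomposition.
# `tab` is a long data frame with unit, type, phase, value.
rm_anova_oracle <- function(tab) {
  y <- with(tab, tapply(value, list(unit, type, phase), mean))
  n <- dim(y)[1]
  g <- mean(y)
  m_u <- apply(y, 1, mean); m_t <- apply(y, 2, mean); m_p <- apply(y, 3, mean)
  m_ut <- apply(y, c(1, 2), mean)
  m_up <- apply(y, c(1, 3), mean)
  m_tp <- apply(y, c(2, 3), mean)
  ss_type <- 2 * n * sum((m_t - g)^2)
  ss_phase <- 2 * n * sum((m_p - g)^2)
  ss_txu <- 2 * sum((m_ut - outer(m_u, rep(1, 2)) -
                       outer(rep(1, n), m_t) + g)^2)
  ss_pxu <- 2 * sum((m_up - outer(m_u, rep(1, 2)) -
                       outer(rep(1, n), m_p) + g)^2)
  ss_int <- n * sum((m_tp - outer(m_t, rep(1, 2)) -
                       outer(rep(1, 2), m_p) + g)^2)
  resid <- y
  for (u in 1:n) for (t in 1:2) for (p in 1:2) {
    resid[u, t, p] <- y[u, t, p] - m_ut[u, t] - m_up[u, p] - m_tp[t, p] +
      m_u[u] + m_t[t] + m_p[p] - g
  }
  ss_res <- sum(resid^2)
  f <- function(ss_eff, ss_err) {
    Fv <- (ss_eff / 1) / (ss_err / (n - 1))
    list(F = Fv, dof = c(1, n - 1), p_value = pf(Fv, 1, n - 1,
                                                 lower.tail = FALSE))
  }
  list(type = f(ss_type, ss_txu),
       phase = f(ss_phase, ss_pxu),
       interaction = f(ss_int, ss_res),
       ss = list(type = ss_type, phase = ss_phase, interaction = ss_int,
                 type_x_unit = ss_txu, phase_x_unit = ss_pxu,
                 residual = ss_res,
                 unit = 4 * sum((m_u - g)^2),
                 total = sum((y - g)^2)))
}

# Small labelled exemplar set with controllable class separation.
toy_exemplar_set <- function(n_runs = 6, n_voxels = 20, sep = 0, noise = 1,
                             phase = "preparation") {
  n <- 2 * n_runs
  mu <- rep(c(-sep, sep), n_runs)
  features <- matrix(rnorm(n * n_voxels, 0, noise), n, n_voxels) + mu
  exemplar_set(features,
               class = rep(c("pro", "anti"), n_runs),
               run = rep(seq_len(n_runs), each = 2),
               phase = phase)
}

# Per-run 5-regressor GLM betas over the given voxels, as used upstream of
# exemplar construction.
per_run_mvpa_fits <- function(participant, hrf = hrf_model("dual_gamma"),
                              voxels = NULL) {
  lapply(participant$runs, function(r) {
    X <- build_design_matrix(r$schedule, "mvpa_5reg", hrf)
    X <- cbind(X[, attr(X, "task_labels"), drop = FALSE],
               dct_drift_basis(nrow(X)))
    Y <- r$data
    if (!is.null(voxels)) Y <- Y[voxels, , drop = FALSE]
    fit_glm(Y, X)
  })
}

# Concatenated, normalised exemplar set straight from a dataset.
dataset_exemplars <- function(dataset, phase = "preparation") {
  sets <- lapply(seq_along(dataset$participants), function(p) {
    fits <- per_run_mvpa_fits(dataset$participants[[p]], dataset$hrf)
    normalize_exemplars(build_exemplars(fits, phase, participant = p))
  })
  concatenate_participants(sets)
}
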