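#' Ground-truth voxel response patterns for one simulated participant
#'
#' Encodes the two hypotheses the decoding analysis discriminates:
#'
#' * `cortex_like` — pro- and anti-saccade responses use distinct multi-voxel
#'   patterns (class-specific patterns with nonzero distance) and the
#'   anti-saccade preparation gain exceeds the pro-saccade gain, mirroring
#'   task-specific neural specialisation in FEF/DLPFC/IPS;
#' * `sc_like` — both classes share the same pattern and the same gain
#'   (amplitude-matched, pattern-free), mirroring the collicular profile of
#'   preparatory activity without class information;
#' * `null` — all preparation/execution/return amplitudes are zero.
#'
#' Per-voxel pattern values are drawn as Normal(1, `pattern_sd`), so voxels
#' respond with heterogeneous but mostly positive weights; amplitudes are
#' gain times pattern, in units of the unit-peak-scaled regressor.
#' Execution amplitudes are modulated by direction: contralateral targets
#' (relative to the voxel's hemisphere) are scaled by `1 + lateralization`,
#' ipsilateral by `1 - lateralization` (default 0, no contralateral bias).
#'
#' @param scenario `"cortex_like"`, `"sc_like"` or `"null"`.
#' @param n_voxels voxels in the simulated region (split evenly into left
#'   and right hemispheres).
#' @param prep_gain_pro,prep_gain_anti preparation-phase gains per class;
#'   `sc_like` requires them equal.
#' @param exec_gain execution-phase gain (common to both classes).
#' @param return_gain gain of the centripetal return saccade response.
#' @param pattern_sd standard deviation of the per-voxel pattern draws.
#' @param lateralization contralateral execution bias L (0 or more).
#' @return A `ground_truth` object: list with `amplitude` (voxels x event
#'   kinds matrix), `hemisphere` (per-voxel `"left"`/`"right"`), `scenario`,
#'   and the gains used.
#' @export
ground_truth_patterns <- function(scenario = c("cortex_like", "sc_like",
                                               "null"),
                                  n_voxels = 120L,
                                  prep_gain_pro = NULL,
                                  prep_gain_anti = NULL,
                                  exec_gain = 2,
                                  return_gain = NULL,
                                  pattern_sd = 0.35,
                                  lateralization = 0) {
  scenario <- match.arg(scenario)
  if (lateralization < 0) stop("lateralization must be >= 0", call. = FALSE)
  if (is.null(prep_gain_pro)) {
    prep_gain_pro <- switch(scenario, cortex_like = 0.8, sc_like = 1, 0)
  }
  if (is.null(prep_gain_anti)) {
    prep_gain_anti <- switch(scenario, cortex_like = 1.3, sc_like = 1, 0)
  }
  if (is.null(return_gain)) {
    return_gain <- switch(scenario, cortex_like = 0.8, sc_like = 0.5, 0)
  }
  if (scenario == "sc_like" && prep_gain_pro != prep_gain_anti) {
    stop("sc_like requires equal preparation gains for both classes",
         call. = FALSE)
  }
  if (scenario == "cortex_like" && prep_gain_anti <= prep_gain_pro) {
    stop("cortex_like requires prep_gain_anti > prep_gain_pro", call. = FALSE)
  }
  hemi <- rep(c("left", "right"), length.out = n_voxels)

  A <- matrix(0, n_voxels, length(EVENT_KINDS),
              dimnames = list(NULL, EVENT_KINDS))
  if (scenario != "null") {
    p_pro <- stats::rnorm(n_voxels, 1, pattern_sd)
    p_anti <- if (scenario == "cortex_like") {
      stats::rnorm(n_voxels, 1, pattern_sd)
    } else {
      p_pro
    }
    p_ret <- stats::rnorm(n_voxels, 1, pattern_sd)
    contra <- function(dir) {
      ifelse((hemi == "left") == (dir == "right"),
             1 + lateralization, 1 - lateralization)
    }
    A[, "prep_pro"] <- prep_gain_pro * p_pro
    A[, "prep_anti"] <- prep_gain_anti * p_anti
    A[, "exec_pro_left"] <- exec_gain * p_pro * contra("left")
    A[, "exec_pro_right"] <- exec_gain * p_pro * contra("right")
    A[, "exec_anti_left"] <- exec_gain * p_anti * contra("left")
    A[, "exec_anti_right"] <- exec_gain * p_anti * contra("right")
    A[, "return_saccade"] <- return_gain * p_ret
  }
  structure(list(amplitude = A,
                 hemisphere = hemi,
                 scenario = scenario,
                 gains = list(prep_pro = prep_gain_pro,
                              prep_anti = prep_gain_anti,
                              exec = exec_gain,
                              return_saccade = return_gain),
                 pattern_sd = pattern_sd,
                 lateralization = lateralization),
            class = "ground_truth")
}

#' Simulate one BOLD run from a schedule and ground-truth patterns
#'
#' Forward model: each voxel's series is the unit-peak-scaled, HRF-convolved
#' event regressors weighted by the voxel's ground-truth amplitudes, plus a
#' baseline offset, optional low-frequency cosine drift, and Gaussian noise
#' (optionally AR(1)). With zero noise and zero drift the data are exactly
#' design matrix times amplitudes, so GLM recovery is exact.
#'
#' @param schedule a [build_run_schedule()] result.
#' @param patterns a [ground_truth_patterns()] result.
#' @param hrf an [hrf_model()].
#' @param noise_sd Gaussian noise standard deviation per volume.
#' @param drift_amplitude standard deviation of random low-frequency cosine
#'   drift (components below the default 3 cycles/run cutoff); 0 disables.
#' @param baseline mean signal level added to every voxel.
#' @param ar1 lag-one autocorrelation of the noise (0 for white noise).
#' @return A `bold_run`: list with `data` (voxels x volumes matrix), `tr`,
#'   `roi_labels` (hemisphere tags) and the `schedule`.
#' @export
simulate_bold_run <- function(schedule, patterns,
                              hrf = hrf_model("dual_gamma"),
                              noise_sd = 1,
                              drift_amplitude = 0,
                              baseline = 100,
                              ar1 = 0) {
  stopifnot(inherits(patterns, "ground_truth"))
  X <- build_design_matrix(schedule, "univariate_6reg", hrf)
  labels <- attr(X, "task_labels")
  map <- scheme_map("univariate_6reg")
  kinds <- names(map)[match(labels, map)]
  missing <- setdiff(kinds, colnames(patterns$amplitude))
  if (length(missing) > 0) {
    stop("no amplitude entry for event kind(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  A <- patterns$amplitude[, kinds, drop = FALSE]
  n_vox <- nrow(A)
  n_vol <- nrow(X)
  Y <- A %*% t(X[, labels, drop = FALSE]) + baseline

  if (drift_amplitude > 0) {
    B <- dct_drift_basis(n_vol, include_constant = FALSE)
    coefs <- matrix(stats::rnorm(n_vox * ncol(B), 0, drift_amplitude),
                    n_vox, ncol(B))
    Y <- Y + coefs %*% t(B)
  }
  if (noise_sd > 0) {
    if (ar1 == 0) {
      Y <- Y + matrix(stats::rnorm(n_vox * n_vol, 0, noise_sd), n_vox, n_vol)
    } else {
      innov_sd <- noise_sd * sqrt(1 - ar1^2)
      e <- matrix(stats::rnorm(n_vox * n_vol, 0, innov_sd), n_vol, n_vox)
      e <- apply(e, 2, function(z) stats::filter(z, ar1, "recursive"))
      Y <- Y + t(e)
    }
  }
  structure(list(data = Y,
                 tr = attr(schedule, "tr"),
                 roi_labels = patterns$hemisphere,
                 schedule = schedule),
            class = "bold_run")
}

#' Generate a complete synthetic multi-participant dataset
#'
#' Draws per-participant ground-truth patterns according to the scenario,
#' builds an independent randomised schedule for every run, and simulates
#' the BOLD data. A fixed seed fully determines the dataset.
#'
#' @param scenario `"cortex_like"`, `"sc_like"` or `"null"`.
#' @param n_participants number of simulated participants.
#' @param n_runs runs per participant (at least 2; leave-one-run-out
#'   cross-validation is undefined otherwise).
#' @param n_voxels voxels per participant.
#' @param config a [design_config()].
#' @param hrf an [hrf_model()].
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @param ... passed to [ground_truth_patterns()] (gains, `pattern_sd`,
#'   `lateralization`) .
#' @inheritParams simulate_bold_run
#' @return A `saccade_dataset`: list with `participants` (each holding
#'   `truth` and `runs`, a list of `bold_run`s), `config`, `scenario`,
#'   `hrf`, `seed` and the simulation parameters.
#' @export
make_dataset <- function(scenario = c("cortex_like", "sc_like", "null"),
                         n_participants = 6L,
                         n_runs = 6L,
                         n_voxels = 120L,
                         config = design_config(),
                         hrf = hrf_model("dual_gamma"),
                         noise_sd = 1,
                         drift_amplitude = 0,
                         baseline = 100,
                         ar1 = 0,
                         seed = NULL,
                         ...) {
  scenario <- match.arg(scenario)
  if (n_runs < 2) {
    stop("n_runs must be at least 2 (leave-one-run-out is undefined for a ",
         "single run)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  participants <- lapply(seq_len(n_participants), function(p) {
    truth <- ground_truth_patterns(scenario, n_voxels = n_voxels, ...)
    runs <- lapply(seq_len(n_runs), function(r) {
      sched <- build_run_schedule(config)
      simulate_bold_run(sched, truth, hrf,
                        noise_sd = noise_sd,
                        drift_amplitude = drift_amplitude,
                        baseline = baseline,
                        ar1 = ar1)
    })
    list(truth = truth, runs = runs)
  })
  structure(list(participants = participants,
                 config = config,
                 scenario = scenario,
                 hrf = hrf,
                 noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 baseline = baseline,
                 ar1 = ar1,
                 seed = seed),
            class = "saccade_dataset")
}

#' @export
print.saccade_dataset <- function(x, ...) {
  cat("Synthetic saccade fMRI dataset:", length(x$participants),
      "participants x", length(x$participants[[1]]$runs), "runs,",
      nrow(x$participants[[1]]$truth$amplitude), "voxels, scenario",
      x$scenario, "\n")
  invisible(x)
}
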