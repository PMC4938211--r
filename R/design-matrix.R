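# Regressor schemes: map event kinds to design-matrix columns.
# univariate_6reg keeps execution direction resolved (6 task regressors plus
# the return-saccade regressor); mvpa_5reg collapses direction (5 task
# regressors) as used for pattern decoding.
scheme_map <- function(scheme = c("univariate_6reg", "mvpa_5reg")) {
  scheme <- match.arg(scheme)
  if (scheme == "univariate_6reg") {
    c(prep_pro = "prep_pro", prep_anti = "prep_anti",
      exec_pro_left = "exec_pro_left", exec_pro_right = "exec_pro_right",
      exec_anti_left = "exec_anti_left", exec_anti_right = "exec_anti_right",
      return_saccade = "return")
  } else {
    c(prep_pro = "prep_pro", prep_anti = "prep_anti",
      exec_pro_left = "exec_pro", exec_pro_right = "exec_pro",
      exec_anti_left = "exec_anti", exec_anti_right = "exec_anti",
      return_saccade = "return")
  }
}

scheme_labels <- function(scheme) unique(unname(scheme_map(scheme)))

#' Build an HRF-convolved design matrix for one run
#'
#' For each regressor, places 0.5 s (configurable) boxcars at the onsets of
#' its member events on a fine time grid, convolves with the HRF, samples
#' the result at volume acquisition times, and scales the column so its
#' maximum is one. Event onsets need not align with the TR grid. A constant
#' column is appended.
#'
#' @param schedule a [build_run_schedule()] result (or any data frame with
#'   `onset`, `kind`, `duration`).
#' @param scheme `"univariate_6reg"` (direction-resolved execution
#'   regressors) or `"mvpa_5reg"` (direction collapsed).
#' @param hrf an [hrf_model()].
#' @param tr volume repetition time in seconds; defaults to the schedule's.
#' @param n_volumes number of volumes; defaults to the schedule's.
#' @param grid_step convolution grid step in seconds.
#' @return A `design_matrix`: numeric matrix of `n_volumes` rows whose last
#'   column is the constant, with attributes `task_labels`, `tr` and
#'   `scheme`. Task columns with no events are all-zero and reported via a
#'   warning.
#' @export
build_design_matrix <- function(schedule,
                                scheme = c("univariate_6reg", "mvpa_5reg"),
                                hrf = hrf_model("dual_gamma"),
                                tr = NULL,
                                n_volumes = NULL,
                                grid_step = 0.1) {
  scheme <- match.arg(scheme)
  map <- scheme_map(scheme)
  if (is.null(tr)) tr <- attr(schedule, "tr")
  if (is.null(n_volumes)) n_volumes <- attr(schedule, "n_volumes")
  stopifnot(!is.null(tr), !is.null(n_volumes))
  if (nrow(schedule) > 0) {
    unknown <- setdiff(unique(schedule$kind), names(map))
    if (length(unknown) > 0) {
      stop("event kind(s) not mapped by scheme ", scheme, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  labels <- scheme_labels(scheme)
  total <- max(n_volumes * tr, if (nrow(schedule)) max(schedule$onset) else 0)
  grid_n <- ceiling(total / grid_step) + 1L
  h <- evaluate_hrf(hrf, seq(0, hrf$support, by = grid_step))
  vol_idx <- pmin(grid_n, floor((seq_len(n_volumes) - 1) * tr / grid_step) + 1L)

  X <- matrix(0, n_volumes, length(labels), dimnames = list(NULL, labels))
  for (lab in labels) {
    kinds <- names(map)[map == lab]
    ev <- schedule[schedule$kind %in% kinds, , drop = FALSE]
    if (nrow(ev) == 0) next
    stick <- numeric(grid_n)
    for (i in seq_len(nrow(ev))) {
      a <- floor(ev$onset[i] / grid_step) + 1L
      b <- min(grid_n, floor((ev$onset[i] + ev$duration[i]) / grid_step))
      stick[a:max(a, b)] <- 1
    }
    conv <- stats::convolve(stick, rev(h), type = "open")[seq_len(grid_n)]
    col <- conv[vol_idx]
    m <- max(col)
    if (m > 0) col <- col / m
    X[, lab] <- col
  }
  empty <- labels[colSums(abs(X)) == 0]
  if (length(empty) > 0) {
    warning("design columns with no events are all zero: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  X <- cbind(X, constant = 1)
  structure(X, task_labels = labels, tr = tr, scheme = scheme,
            class = c("design_matrix", "matrix", "array"))
}

#' Discrete-cosine drift basis for high-pass filtering
#'
#' DCT-II components whose frequency `k / (2 * run_duration)` lies strictly
#' below `cutoff_cycles / run_duration`, i.e. `k = 1, ..., 2 * cutoff - 1`
#' for an integer cutoff, plus a constant column.
#'
#' @param n_volumes number of volumes in the run.
#' @param cutoff_cycles high-pass cutoff in cycles per run (at least 1).
#' @param include_constant prepend a constant column.
#' @return Matrix of `n_volumes` rows.
#' @export
dct_drift_basis <- function(n_volumes, cutoff_cycles = 3,
                            include_constant = TRUE) {
  if (cutoff_cycles < 1) stop("cutoff must be at least 1 cycle/run",
                              call. = FALSE)
  k_max <- ceiling(2 * cutoff_cycles) - 1L
  i <- seq_len(n_volumes) - 1L
  B <- vapply(seq_len(k_max),
              function(k) cos(pi * k * (2 * i + 1) / (2 * n_volumes)),
              numeric(n_volumes))
  B <- matrix(B, nrow = n_volumes,
              dimnames = list(NULL, paste0("dct", seq_len(k_max))))
  if (include_constant) B <- cbind(constant = 1, B)
  B
}

#' High-pass filter time series by projecting out slow drift
#'
#' Removes the span of the discrete-cosine drift basis (all components below
#' the cutoff frequency, plus the mean) from each voxel's time series by
#' least-squares projection. Projection makes the operation idempotent.
#'
#' @param series voxels x volumes matrix (or a vector, one series).
#' @param cutoff_cycles cutoff in cycles per run.
#' @return Filtered matrix of the same shape.
#' @export
high_pass_filter <- function(series, cutoff_cycles = 3) {
  vec <- is.null(dim(series))
  Y <- if (vec) matrix(series, nrow = 1) else as.matrix(series)
  n <- ncol(Y)
  B <- dct_drift_basis(n, cutoff_cycles)
  if (n <= ncol(B)) {
    stop("fewer volumes (", n, ") than drift-basis size (", ncol(B), ")",
         call. = FALSE)
  }
  fit <- t(stats::lm.fit(B, t(Y))$residuals)
  if (vec) drop(fit) else fit
}

#' Export a design matrix to TSV
#'
#' @param design a [build_design_matrix()] result.
#' @param path output file path.
#' @return Invisibly, the matrix written.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(as.data.frame(unclass(design)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(design)
}
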