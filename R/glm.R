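#' Fit a per-voxel ordinary-least-squares GLM
#'
#' Solves the normal equations for every voxel simultaneously against a
#' common design. The design must have full column rank; rank deficiency is
#' reported with the names of the offending columns. Residual variance is
#' the unbiased estimate (sum of squared residuals over `volumes - rank`).
#'
#' @param data voxels x volumes matrix, or a `bold_run`.
#' @param design volumes x regressors matrix with column names.
#' @return A `beta_estimates` object: `betas` (voxels x regressors),
#'   `residual_variance` (per voxel), `dof`, `xtx_inv`, and the design's
#'   column names.
#' @export
fit_glm <- function(data, design) {
  if (inherits(data, "bold_run")) data <- data$data
  Y <- as.matrix(data)
  X <- as.matrix(design)
  if (ncol(Y) != nrow(X)) {
    stop("data has ", ncol(Y), " volumes but design has ", nrow(X),
         call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qx, t(Y))           # regressors x voxels
  res <- t(Y) - X %*% coef
  dof <- nrow(X) - qx$rank
  rv <- colSums(res^2) / dof
  structure(list(betas = t(coef),
                 residual_variance = unname(rv),
                 dof = dof,
                 xtx_inv = chol2inv(qr.R(qx))[order(qx$pivot),
                                              order(qx$pivot)],
                 regressors = colnames(X)),
            class = "beta_estimates")
}

#' Contrast t-map from GLM estimates
#'
#' For contrast vector c, computes per voxel
#' t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c). Voxels with zero residual
#' variance and a nonzero numerator are reported as signed infinity.
#'
#' @param estimates a [fit_glm()] result.
#' @param contrast numeric vector, one weight per regressor (named vectors
#'   are matched to regressor names, unnamed positions default to 0).
#' @return A `contrast_map`: list with `t_values`, `dof` and the contrast.
#' @export
contrast_t_map <- function(estimates, contrast) {
  stopifnot(inherits(estimates, "beta_estimates"))
  p <- length(estimates$regressors)
  if (!is.null(names(contrast))) {
    cv <- stats::setNames(numeric(p), estimates$regressors)
    unknown <- setdiff(names(contrast), estimates$regressors)
    if (length(unknown) > 0) {
      stop("contrast names not in design: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cv[names(contrast)] <- contrast
  } else {
    if (length(contrast) != p) {
      stop("contrast length ", length(contrast), " != ", p, " regressors",
           call. = FALSE)
    }
    cv <- contrast
  }
  num <- drop(estimates$betas %*% cv)
  cvar <- drop(t(cv) %*% estimates$xtx_inv %*% cv)
  den <- sqrt(estimates$residual_variance * cvar)
  t_values <- ifelse(den > 0, num / den,
                     ifelse(num == 0, 0, sign(num) * Inf))
  structure(list(t_values = t_values,
                 dof = estimates$dof,
                 contrast = cv),
            class = "contrast_map")
}

#' Threshold a t-map into a binary voxel mask
#'
#' Two-sided p-values from the t distribution, thresholded either
#' uncorrected (`p < level`) or with Benjamini-Hochberg false-discovery-rate
#' control over all in-analysis voxels (`q < level`).
#'
#' @param map a [contrast_t_map()] result.
#' @param method `"fdr_q"` or `"uncorrected_p"`.
#' @param level threshold level in (0, 1).
#' @return Logical vector, `TRUE` for suprathreshold voxels.
#' @export
threshold_map <- function(map, method = c("fdr_q", "uncorrected_p"),
                          level = 0.001) {
  method <- match.arg(method)
  stopifnot(inherits(map, "contrast_map"))
  if (length(map$t_values) == 0) stop("empty t-map", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  p <- 2 * stats::pt(-abs(map$t_values), df = map$dof)
  if (method == "uncorrected_p") {
    p < level
  } else {
    stats::p.adjust(p, method = "BH") < level
  }
}

#' Build a multi-run session design with run-wise drift columns
#'
#' Task regressors are built per run and stacked; each run contributes its
#' own discrete-cosine drift block (constant included), giving the
#' concatenated-session GLM used for univariate analysis.
#'
#' @param schedules list of run schedules.
#' @param scheme regressor scheme, see [build_design_matrix()].
#' @param hrf an [hrf_model()].
#' @param cutoff_cycles high-pass cutoff per run, cycles per run.
#' @return A design matrix with attributes `task_labels` and `run_index`
#'   (per-row run of origin).
#' @export
build_session_design <- function(schedules,
                                 scheme = "univariate_6reg",
                                 hrf = hrf_model("dual_gamma"),
                                 cutoff_cycles = 3) {
  parts <- lapply(schedules, build_design_matrix, scheme = scheme, hrf = hrf)
  labels <- attr(parts[[1]], "task_labels")
  task <- do.call(rbind, lapply(parts, function(X) X[, labels, drop = FALSE]))
  drifts <- lapply(seq_along(parts), function(r) {
    B <- dct_drift_basis(nrow(parts[[r]]), cutoff_cycles)
    colnames(B) <- paste0("run", r, "_", colnames(B))
    B
  })
  n_rows <- vapply(parts, nrow, integer(1))
  drift <- matrix(0, sum(n_rows), sum(vapply(drifts, ncol, integer(1))))
  cn <- character(0)
  row0 <- 0L
  col0 <- 0L
  for (r in seq_along(drifts)) {
    drift[row0 + seq_len(n_rows[r]), col0 + seq_len(ncol(drifts[[r]]))] <-
      drifts[[r]]
    cn <- c(cn, colnames(drifts[[r]]))
    row0 <- row0 + n_rows[r]
    col0 <- col0 + ncol(drifts[[r]])
  }
  colnames(drift) <- cn
  X <- cbind(task, drift)
  structure(X, task_labels = labels,
            run_index = rep(seq_along(parts), n_rows))
}

#' Export beta estimates to a long-format TSV
#'
#' @param estimates a [fit_glm()] result.
#' @param path output file path.
#' @return Invisibly, the data frame written (voxel, regressor, value).
#' @export
write_betas_tsv <- function(estimates, path) {
  df <- data.frame(voxel = rep(seq_len(nrow(estimates$betas)),
                               times = ncol(estimates$betas)),
                   regressor = rep(estimates$regressors,
                                   each = nrow(estimates$betas)),
                   value = as.vector(estimates$betas))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
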