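#' Define a region of interest
#'
#' Functional mode intersects a suprathreshold voxel mask (e.g. from the
#' execution-versus-baseline contrast) with an anatomical template label,
#' standing in for manual identification of an activity patch at a known
#' location. Anatomical mode returns the template label itself.
#'
#' @param template_voxels integer indices of the anatomical template label.
#' @param threshold_mask logical per-voxel mask from [threshold_map()]
#'   (required in functional mode).
#' @param name region name, e.g. `"FEF"` or `"SC"`.
#' @param hemisphere `"left"` or `"right"`.
#' @param definition `"functional_map"` or `"anatomical_label"`.
#' @return An `roi_mask`: list with `name`, `hemisphere`, `voxels` (integer
#'   indices) and `definition`. Errors if the result is empty.
#' @export
define_roi <- function(template_voxels,
                       threshold_mask = NULL,
                       name = "ROI",
                       hemisphere = c("left", "right"),
                       definition = c("functional_map", "anatomical_label")) {
  hemisphere <- match.arg(hemisphere)
  definition <- match.arg(definition)
  template_voxels <- as.integer(template_voxels)
  if (definition == "functional_map") {
    if (is.null(threshold_mask)) {
      stop("functional ROI definition needs a threshold mask", call. = FALSE)
    }
    voxels <- intersect(template_voxels, which(threshold_mask))
  } else {
    voxels <- template_voxels
  }
  if (length(voxels) == 0) {
    stop("ROI ", name, " (", hemisphere, ") is empty after ", definition,
         " definition", call. = FALSE)
  }
  structure(list(name = name, hemisphere = hemisphere,
                 voxels = sort(voxels), definition = definition),
            class = "roi_mask")
}

#' Pool direction-resolved execution responses into ipsi/contra columns
#'
#' Relabels leftward/rightward execution betas as ipsilateral or
#' contralateral with respect to each hemisphere (a rightward saccade is
#' contralateral for a left-hemisphere ROI and ipsilateral for a
#' right-hemisphere ROI) and stacks the two hemispheres as analysis units.
#'
#' @param left_betas,right_betas matrices or data frames (units x
#'   conditions) for the left- and right-hemisphere ROIs, aligned row by
#'   row, with columns `exec_pro_left`, `exec_pro_right`, `exec_anti_left`,
#'   `exec_anti_right`; any other columns are carried through unchanged.
#' @return Data frame with one row per hemisphere-unit, columns
#'   `exec_pro_ipsi`, `exec_pro_contra`, `exec_anti_ipsi`,
#'   `exec_anti_contra`, a `hemisphere` column, and any carried columns.
#' @export
pool_ipsi_contra <- function(left_betas, right_betas) {
  if (missing(left_betas) || missing(right_betas) ||
      is.null(left_betas) || is.null(right_betas)) {
    stop("both hemispheres are required", call. = FALSE)
  }
  need <- c("exec_pro_left", "exec_pro_right",
            "exec_anti_left", "exec_anti_right")
  relabel <- function(tab, hemi) {
    tab <- as.data.frame(tab)
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0) {
      stop("missing direction-resolved column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    ipsi_dir <- if (hemi == "left") "left" else "right"
    contra_dir <- if (hemi == "left") "right" else "left"
    out <- tab[setdiff(names(tab), need)]
    out$exec_pro_ipsi <- tab[[paste0("exec_pro_", ipsi_dir)]]
    out$exec_pro_contra <- tab[[paste0("exec_pro_", contra_dir)]]
    out$exec_anti_ipsi <- tab[[paste0("exec_anti_", ipsi_dir)]]
    out$exec_anti_contra <- tab[[paste0("exec_anti_", contra_dir)]]
    out$hemisphere <- hemi
    out
  }
  rbind(relabel(left_betas, "left"), relabel(right_betas, "right"))
}

#' Normalised percent signal change
#'
#' Converts raw beta estimates to percent signal change against a baseline
#' level (100 * beta / baseline), then removes between-unit gain by a
#' mean-preserving rescaling: each unit's values are divided by that unit's
#' grand mean across conditions and multiplied by the group grand mean.
#'
#' @param betas units x conditions matrix (or data frame) of raw betas.
#' @param baseline_level positive baseline signal level, one value per unit
#'   (recycled if scalar).
#' @return Matrix of normalised percent signal change, same shape as
#'   `betas`.
#' @export
normalize_signal_change <- function(betas, baseline_level) {
  B <- as.matrix(betas)
  baseline_level <- rep_len(baseline_level, nrow(B))
  if (any(baseline_level <= 0)) {
    stop("baseline level must be positive", call. = FALSE)
  }
  psc <- 100 * sweep(B, 1, baseline_level, "/")
  unit_mean <- rowMeans(psc)
  if (any(unit_mean == 0)) {
    stop("a unit's grand mean across conditions is zero; gain rescaling ",
         "is undefined", call. = FALSE)
  }
  sweep(psc, 1, unit_mean, "/") * mean(psc)
}

#' Paired t-test
#'
#' Classical paired t on the within-unit differences, two-sided, with
#' `n - 1` degrees of freedom. Exactly identical samples give t = 0, p = 1;
#' constant nonzero differences (zero variance, nonzero mean) are an error
#' because the statistic is undefined.
#'
#' @param values_a,values_b paired numeric vectors of equal length >= 2.
#' @return List with `statistic`, `dof`, `p_value`, `tail = "two_sided"`.
#' @export
paired_t_test <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  tol <- 1e-10 * max(abs(d), 1)
  if (stats::sd(d) <= tol) {
    if (max(abs(d)) <= tol) {
      return(list(statistic = 0, dof = length(d) - 1L, p_value = 1,
                  tail = "two_sided"))
    }
    stop("differences have zero variance with nonzero mean; paired t is ",
         "undefined", call. = FALSE)
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(statistic = unname(ht$statistic),
       dof = unname(ht$parameter),
       p_value = ht$p.value,
       tail = "two_sided")
}

#' Two-way repeated-measures ANOVA (2 x 2 within-unit)
#'
#' Saccade type (pro, anti) crossed with saccade phase (preparation,
#' execution), both within-unit. Each effect is tested against its own
#' effect-by-unit interaction mean square, degrees of freedom (1, n - 1).
#' With two-level factors no sphericity correction is needed.
#'
#' @param table long data frame with columns `unit`, `type`, `phase`,
#'   `value`; every unit must have all four cells exactly once.
#' @return List of three `stat_result`s (`type`, `phase`, `interaction`),
#'   each with `F`, `dof` (length-2), `p_value`.
#' @export
rm_anova_2x2 <- function(table) {
  need <- c("unit", "type", "phase", "value")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    stop("table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  table$unit <- factor(table$unit)
  table$type <- factor(table$type)
  table$phase <- factor(table$phase)
  if (nlevels(table$type) != 2 || nlevels(table$phase) != 2) {
    stop("type and phase must each have exactly two levels", call. = FALSE)
  }
  counts <- table(table$unit, table$type, table$phase)
  if (any(counts != 1)) {
    stop("incomplete or duplicated cells: every unit needs each ",
         "type x phase combination exactly once", call. = FALSE)
  }
  fit <- stats::aov(value ~ type * phase + Error(unit / (type * phase)),
                    data = table)
  s <- summary(fit)
  total_ss <- sum((table$value - mean(table$value))^2)
  pull <- function(term) {
    for (stratum in s) {
      tab <- stratum[[1]]
      rn <- trimws(rownames(tab))
      i <- match(term, rn)
      if (!is.na(i) && !is.na(tab[i, "F value"])) {
        dof <- c(tab[i, "Df"], tab[rn == "Residuals", "Df"])
        # an effect whose sum of squares is numerical noise has F = 0
        if (tab[i, "Sum Sq"] <= 1e-12 * total_ss) {
          return(list(F = 0, dof = dof, p_value = 1))
        }
        return(list(F = tab[i, "F value"],
                    dof = dof,
                    p_value = tab[i, "Pr(>F)"]))
      }
    }
    stop("term ", term, " not found in ANOVA summary", call. = FALSE)
  }
  list(type = pull("type"),
       phase = pull("phase"),
       interaction = pull("type:phase"))
}
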