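#' Write a synthetic dataset to NIfTI volumes and event tables
#'
#' One 4-D NIfTI file per run (voxels along the first axis, volumes along
#' the fourth), a companion integer NIfTI with the voxel-to-hemisphere
#' label map per participant, one tab-separated events file per run with
#' columns `onset`, `duration`, `trial_type` (seconds from run start), a
#' per-participant ground-truth amplitude table, and a `dataset.json`
#' manifest recording the scenario, seed, design parameters and expected
#' volume counts.
#'
#' @param dataset a [make_dataset()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "saccade_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- dataset$config$tr
  n_vol <- list()
  for (p in seq_along(dataset$participants)) {
    part <- dataset$participants[[p]]
    sub <- sprintf("sub-%02d", p)
    labels <- match(part$truth$hemisphere, c("left", "right"))
    RNifti::writeNifti(
      RNifti::asNifti(array(labels, c(length(labels), 1L, 1L))),
      file.path(dir, paste0(sub, "_labels.nii.gz")))
    amp <- as.data.frame(part$truth$amplitude)
    utils::write.table(amp, file.path(dir, paste0(sub, "_truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    vols <- integer(0)
    for (r in seq_along(part$runs)) {
      run <- part$runs[[r]]
      stem <- sprintf("%s_run-%02d", sub, r)
      img <- RNifti::asNifti(array(run$data,
                                   c(nrow(run$data), 1L, 1L,
                                     ncol(run$data))),
                             pixdim = c(3, 3, 3, tr))
      RNifti::writeNifti(img, file.path(dir, paste0(stem, "_bold.nii.gz")))
      ev <- data.frame(onset = run$schedule$onset,
                       duration = run$schedule$duration,
                       trial_type = run$schedule$kind)
      utils::write.table(ev, file.path(dir, paste0(stem, "_events.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      vols <- c(vols, ncol(run$data))
    }
    n_vol[[sub]] <- vols
  }
  manifest <- list(scenario = dataset$scenario,
                   seed = dataset$seed,
                   n_participants = length(dataset$participants),
                   n_runs = length(dataset$participants[[1]]$runs),
                   n_voxels = nrow(dataset$participants[[1]]$truth$amplitude),
                   tr = tr,
                   noise_sd = dataset$noise_sd,
                   baseline = dataset$baseline,
                   design = unclass(dataset$config),
                   hrf_variant = dataset$hrf$variant,
                   n_volumes = n_vol)
  jsonlite::write_json(manifest, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' Reconstructs the runs and schedules, validating the events schema and
#' checking every volume count against the manifest; a truncated or
#' mismatched volume file is an error naming the run, never silently
#' padded.
#'
#' @param dir directory produced by [write_dataset()].
#' @return A `saccade_dataset`-shaped list (ground-truth amplitudes are
#'   restored from the truth tables; gains are not round-tripped).
#' @export
read_dataset <- function(dir) {
  manifest_path <- file.path(dir, "dataset.json")
  if (!file.exists(manifest_path)) {
    stop("no dataset.json manifest in ", dir, call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  design <- do.call(design_config, man$design[setdiff(names(man$design),
                                                      character(0))])
  participants <- lapply(seq_len(man$n_participants), function(p) {
    sub <- sprintf("sub-%02d", p)
    labels <- as.vector(RNifti::readNifti(
      file.path(dir, paste0(sub, "_labels.nii.gz"))))
    hemi <- c("left", "right")[labels]
    amp <- as.matrix(utils::read.delim(
      file.path(dir, paste0(sub, "_truth.tsv")), check.names = FALSE))
    runs <- lapply(seq_len(man$n_runs), function(r) {
      stem <- sprintf("%s_run-%02d", sub, r)
      ev <- utils::read.delim(file.path(dir, paste0(stem, "_events.tsv")))
      need <- c("onset", "duration", "trial_type")
      miss <- setdiff(need, names(ev))
      if (length(miss) > 0) {
        stop("events file for ", stem, " is missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      img <- RNifti::readNifti(file.path(dir, paste0(stem, "_bold.nii.gz")))
      dd <- dim(img)
      data <- matrix(img, nrow = dd[1], ncol = dd[4])
      expected <- man$n_volumes[[sub]][r]
      if (ncol(data) != expected) {
        stop("run ", stem, ": volume count ", ncol(data),
             " does not match the manifest (", expected, ")", call. = FALSE)
      }
      sched <- data.frame(onset = ev$onset, kind = ev$trial_type,
                          duration = ev$duration,
                          stringsAsFactors = FALSE)
      attr(sched, "n_volumes") <- as.integer(expected)
      attr(sched, "total_duration") <- expected * man$tr
      attr(sched, "tr") <- man$tr
      class(sched) <- c("run_schedule", "data.frame")
      structure(list(data = data, tr = man$tr, roi_labels = hemi,
                     schedule = sched),
                class = "bold_run")
    })
    truth <- structure(list(amplitude = amp, hemisphere = hemi,
                            scenario = man$scenario),
                       class = "ground_truth")
    list(truth = truth, runs = runs)
  })
  structure(list(participants = participants,
                 config = design,
                 scenario = man$scenario,
                 hrf = hrf_model(man$hrf_variant),
                 noise_sd = man$noise_sd,
                 baseline = man$baseline,
                 seed = man$seed),
            class = "saccade_dataset")
}
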