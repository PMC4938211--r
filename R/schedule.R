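#' Build a randomised event schedule for one run
#'
#' Lays out one scanner run: a lead-in blank, then the configured trials in
#' random order, then a lead-out blank. Each trial contributes three timed
#' events — a preparation cue, an execution target after the sampled
#' preparation duration, and a return cue after the sampled post-saccade
#' hold — followed by a sampled inter-trial interval. Leftward and rightward
#' targets are balanced within each saccade class, which requires even
#' per-class trial counts.
#'
#' @param config a [design_config()].
#' @return A `run_schedule`: a data frame with columns `onset` (seconds from
#'   run start), `kind` (see [event_kinds()]) and `duration` (the impulse
#'   width), with attributes `total_duration` (seconds) and `n_volumes`
#'   (`ceiling(total_duration / tr)`), plus `tr`, `config` and a `trials`
#'   bookkeeping table (type, direction, sampled durations per trial).
#' @export
build_run_schedule <- function(config = design_config()) {
  if (config$n_pro %% 2L != 0L || config$n_anti %% 2L != 0L) {
    stop("n_pro and n_anti must be even to balance saccade directions",
         call. = FALSE)
  }
  types <- c(rep("pro", config$n_pro), rep("anti", config$n_anti))
  dirs <- c(rep(c("left", "right"), each = config$n_pro / 2L),
            rep(c("left", "right"), each = config$n_anti / 2L))
  ord <- sample.int(config$n_trials_per_run)
  types <- types[ord]
  dirs <- dirs[ord]

  n <- config$n_trials_per_run
  prep_dur <- sample_prep_duration(n, config)
  hold <- sample_delay(n, config)
  iti <- sample_delay(n, config)

  onset <- numeric(0)
  kind <- character(0)
  t <- config$lead_s
  for (i in seq_len(n)) {
    onset <- c(onset, t, t + prep_dur[i], t + prep_dur[i] + hold[i])
    kind <- c(kind,
              paste0("prep_", types[i]),
              paste0("exec_", types[i], "_", dirs[i]),
              "return_saccade")
    t <- t + prep_dur[i] + hold[i] + iti[i]
  }
  total <- t + config$trail_s

  sched <- data.frame(onset = onset,
                      kind = kind,
                      duration = config$impulse_s,
                      stringsAsFactors = FALSE)
  structure(sched,
            trials = data.frame(type = types, direction = dirs,
                                prep = prep_dur, hold = hold, iti = iti),
            total_duration = total,
            n_volumes = as.integer(ceiling(total / config$tr)),
            tr = config$tr,
            config = config,
            class = c("run_schedule", "data.frame"))
}

#' Number of volumes acquired for a schedule
#' @param schedule a `run_schedule`.
#' @return Integer volume count.
#' @export
schedule_n_volumes <- function(schedule) attr(schedule, "n_volumes")

#' Total run duration in seconds
#' @param schedule a `run_schedule`.
#' @return Run duration in seconds, lead-in and lead-out included.
#' @export
schedule_duration <- function(schedule) attr(schedule, "total_duration")
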