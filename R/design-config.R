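#' Trial-design configuration for a delayed pro-/anti-saccade run
#'
#' Encodes the timing structure of one scanner run: trial counts per class,
#' the discrete set of preparation durations, the truncated-Poisson hold /
#' inter-trial delay distribution, lead-in/lead-out blanks, the event impulse
#' width used for GLM predictors, and the volume repetition time.
#'
#' Defaults reproduce the paradigm this package models: 20 trials per run
#' (10 pro-saccade, 10 anti-saccade, half leftward and half rightward within
#' each class), preparation durations drawn uniformly from {6, 10, 14} s,
#' hold and inter-trial delays from a Poisson distribution truncated to
#' [2, 12] s with post-truncation mean 4 s, 15 s of blank at the start and
#' end of each run, 0.5 s impulse events, and a TR of 1.5 s.
#'
#' @param n_trials_per_run total trials per run.
#' @param n_pro,n_anti trials per saccade class; must sum to
#'   `n_trials_per_run` and each must be even so that leftward and rightward
#'   targets can be balanced.
#' @param prep_durations possible preparation-phase durations in seconds.
#' @param delay_mean,delay_min,delay_max target mean and truncation bounds
#'   (integer seconds) of the hold / inter-trial delay distribution.
#' @param lead_s,trail_s blank intervals at run start and end, seconds.
#' @param impulse_s width of the impulse modelled for each event, seconds.
#' @param tr volume repetition time, seconds.
#' @return An object of class `design_config` (a validated list).
#' @export
#' @examples
#' cfg <- design_config()
#' cfg$tr
design_config <- function(n_trials_per_run = 20L,
                          n_pro = 10L,
                          n_anti = 10L,
                          prep_durations = c(6, 10, 14),
                          delay_mean = 4,
                          delay_min = 2,
                          delay_max = 12,
                          lead_s = 15,
                          trail_s = 15,
                          impulse_s = 0.5,
                          tr = 1.5) {
  cfg <- list(
    n_trials_per_run = as.integer(n_trials_per_run),
    n_pro = as.integer(n_pro),
    n_anti = as.integer(n_anti),
    prep_durations = as.numeric(prep_durations),
    delay_mean = delay_mean,
    delay_min = delay_min,
    delay_max = delay_max,
    lead_s = lead_s,
    trail_s = trail_s,
    impulse_s = impulse_s,
    tr = tr
  )
  if (cfg$n_pro + cfg$n_anti != cfg$n_trials_per_run) {
    stop("n_pro + n_anti must equal n_trials_per_run", call. = FALSE)
  }
  if (!(cfg$delay_min <= cfg$delay_mean && cfg$delay_mean <= cfg$delay_max)) {
    stop("require delay_min <= delay_mean <= delay_max", call. = FALSE)
  }
  durs <- c(cfg$prep_durations, cfg$delay_min, cfg$lead_s, cfg$trail_s,
            cfg$impulse_s, cfg$tr)
  if (any(durs <= 0)) stop("all durations must be positive", call. = FALSE)
  class(cfg) <- "design_config"
  cfg
}

#' @export
print.design_config <- function(x, ...) {
  cat("Saccade run design:", x$n_trials_per_run, "trials (",
      x$n_pro, "pro /", x$n_anti, "anti ), TR", x$tr, "s\n")
  cat("  preparation durations:", paste(x$prep_durations, collapse = "/"),
      "s; hold/ITI ~ truncated Poisson [", x$delay_min, ",", x$delay_max,
      "] mean", x$delay_mean, "s\n")
  invisible(x)
}

# Canonical event kinds, in the order used throughout the package.
EVENT_KINDS <- c("prep_pro", "prep_anti",
                 "exec_pro_left", "exec_pro_right",
                 "exec_anti_left", "exec_anti_right",
                 "return_saccade")

#' Event kinds recognised by the simulator and design-matrix builder
#'
#' @return Character vector of the seven event kinds: the two preparation
#'   cues, the four execution events (class crossed with direction), and the
#'   centripetal return saccade.
#' @export
event_kinds <- function() EVENT_KINDS
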