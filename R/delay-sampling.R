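#' Sample preparation-phase durations
#'
#' Draws uniformly from the configured discrete set of preparation durations
#' (default 6, 10 or 14 s). Uses R's global random-number stream; seed with
#' [set.seed()].
#'
#' @param n number of draws.
#' @param config a [design_config()].
#' @return Numeric vector of durations in seconds.
#' @export
sample_prep_duration <- function(n = 1L, config = design_config()) {
  config$prep_durations[sample.int(length(config$prep_durations), n,
                                   replace = TRUE)]
}

#' Calibrate the Poisson rate of the truncated delay distribution
#'
#' The hold and inter-trial delays are integer seconds from a Poisson
#' distribution truncated to `[delay_min, delay_max]`. An untruncated rate
#' equal to the target mean does not give that mean after truncation (a
#' Poisson(4) truncated to \[2, 12\] has mean about 4.32), so the rate is
#' found by root search such that the post-truncation expectation equals
#' `delay_mean` exactly.
#'
#' @param delay_mean target mean of the truncated distribution, seconds.
#' @param delay_min,delay_max truncation bounds (integer seconds).
#' @return The calibrated Poisson rate (lambda).
#' @export
#' @examples
#' calibrate_delay_rate(4, 2, 12)
calibrate_delay_rate <- function(delay_mean = 4, delay_min = 2,
                                 delay_max = 12) {
  support <- seq(ceiling(delay_min), floor(delay_max))
  tmean <- function(lam) {
    p <- stats::dpois(support, lam)
    sum(support * p) / sum(p)
  }
  # The truncated mean is monotone in lambda and spans (delay_min, delay_max);
  # a mean outside the open interval is unattainable.
  lo <- 1e-8
  hi <- delay_max * 4
  if (tmean(lo) > delay_mean || tmean(hi) < delay_mean) {
    stop("no Poisson rate achieves truncated mean ", delay_mean,
         " on [", delay_min, ", ", delay_max, "]", call. = FALSE)
  }
  stats::uniroot(function(l) tmean(l) - delay_mean, c(lo, hi),
                 tol = 1e-12)$root
}

#' Sample hold / inter-trial delays from the calibrated truncated Poisson
#'
#' @param n number of draws.
#' @param config a [design_config()] supplying the mean and bounds.
#' @return Integer-valued numeric vector of delays in seconds, all inside
#'   `[delay_min, delay_max]`.
#' @export
sample_delay <- function(n = 1L, config = design_config()) {
  key <- paste(config$delay_mean, config$delay_min, config$delay_max)
  lam <- delay_rate_cache[[key]]
  if (is.null(lam)) {
    lam <- calibrate_delay_rate(config$delay_mean, config$delay_min,
                                config$delay_max)
    delay_rate_cache[[key]] <- lam
  }
  support <- seq(ceiling(config$delay_min), floor(config$delay_max))
  prob <- stats::dpois(support, lam)
  support[sample.int(length(support), n, replace = TRUE, prob = prob)]
}

# memoises calibrated rates per (mean, min, max) triple
delay_rate_cache <- new.env(parent = emptyenv())
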