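#' Transformed up-down (1-up/2-down) adaptive staircase
#'
#' Runs a Levitt-style 1-up/2-down staircase against a simulated
#' observer to estimate the level of 70.7% detection: the level steps
#' down after two consecutive detections and up after every miss, so the
#' procedure converges where the probability of two detections in a row
#' is 1/2, i.e. p = sqrt(0.5) = 0.707. The step size starts at
#' `step_initial` dB and is reduced to `step_reduced` dB once
#' `reversals_to_reduce` reversals have occurred; the run stops after
#' `reversals_to_stop` reversals and returns the mean level of the last
#' `reversals_averaged` reversal points.
#'
#' The two-down counter resets whenever the level changes (standard
#' transformed up-down bookkeeping).
#'
#' @param observer An [observer()].
#' @param start_level Starting level in dB.
#' @param step_initial Initial step size in dB (default 1).
#' @param step_reduced Reduced step size in dB (default 0.5).
#' @param reversals_to_reduce Reversal count at which the step shrinks
#'   (default 4).
#' @param reversals_to_stop Reversal count at which the run ends
#'   (default 9).
#' @param reversals_averaged Number of final reversal levels averaged
#'   into the threshold (default 5).
#' @param seed Integer seed for the observer's Bernoulli responses.
#' @param max_trials Guard against non-termination (default 200).
#' @param responses Optional scripted logical response sequence; when
#'   supplied the observer is ignored (used for rule-trace testing).
#' @return The threshold estimate (dB) with attribute `trace`, a data
#'   frame of per-trial `level`, `detected`, `reversal`.
#' @export
run_staircase <- function(observer, start_level,
                          step_initial = 1, step_reduced = 0.5,
                          reversals_to_reduce = 4, reversals_to_stop = 9,
                          reversals_averaged = 5, seed = 1,
                          max_trials = 200, responses = NULL) {
  if (reversals_averaged > reversals_to_stop)
    stopf("`reversals_averaged` must not exceed `reversals_to_stop`")
  if (step_initial <= 0 || step_reduced <= 0) stopf("step sizes must be > 0")

  run <- function() {
    level <- start_level
    n_correct <- 0L
    last_dir <- 0L # -1 down, +1 up, 0 no move yet
    rev_levels <- numeric(0)
    trace <- list()
    for (trial in seq_len(max_trials)) {
      detected <- if (!is.null(responses)) {
        if (trial > length(responses))
          stopf("scripted response sequence exhausted before reversal %d",
                reversals_to_stop)
        isTRUE(responses[[trial]])
      } else {
        stats::runif(1) < observer$psychometric(level)
      }
      move <- 0L
      if (detected) {
        n_correct <- n_correct + 1L
        if (n_correct >= 2L) move <- -1L
      } else {
        move <- +1L
      }
      is_rev <- move != 0L && last_dir != 0L && move != last_dir
      if (is_rev) rev_levels <- c(rev_levels, level)
      trace[[trial]] <- c(level = level, detected = detected, reversal = is_rev)
      if (length(rev_levels) >= reversals_to_stop) break
      if (move != 0L) {
        step <- if (length(rev_levels) >= reversals_to_reduce) step_reduced else step_initial
        level <- level + move * step
        n_correct <- 0L
        last_dir <- move
      }
    }
    if (length(rev_levels) < reversals_to_stop)
      stopf("staircase did not reach %d reversals within %d trials (last level %.2f dB)",
            reversals_to_stop, max_trials, level)
    tr <- as.data.frame(do.call(rbind, trace))
    tr$detected <- as.logical(tr$detected)
    tr$reversal <- as.logical(tr$reversal)
    thr <- mean(utils::tail(rev_levels, reversals_averaged))
    structure(thr, trace = tr, reversal_levels = rev_levels)
  }
  if (is.null(responses)) with_seed(seed, run()) else run()
}

#' Individual hearing level by self-adjusted bracketing
#'
#' Estimates the audibility reference for the masking noise: the level
#' descends in `step_db` steps from a clearly audible start until the
#' observer stops hearing the bursts (the "not hearing anymore" report),
#' drops by `drop_db`, then ascends in `step_db` steps until the
#' observer hears again (the "hearing again" report). The descent/ascent
#' pair is repeated `repeats` times and the mean of all report levels
#' (both kinds pooled) is the individual hearing level (IHL).
#'
#' @param observer An [observer()]; its psychometric is read as the
#'   probability of hearing the noise burst at a given level.
#' @param start_level Starting level, clearly audible (dB).
#' @param step_db Step size in dB (default 2).
#' @param drop_db Drop after the "not hearing" report (default 10).
#' @param repeats Number of descent/ascent repeats (default 3).
#' @param seed Integer seed.
#' @param max_steps Guard per track (default 500).
#' @return IHL in dB, with attribute `reports`: data frame of
#'   `repeat_`, `kind` ("stop_hearing"/"hear_again"), `level`.
#' @export
estimate_ihl <- function(observer, start_level, step_db = 2, drop_db = 10,
                         repeats = 3, seed = 1, max_steps = 500) {
  if (step_db <= 0 || drop_db <= 0 || repeats <= 0)
    stopf("`step_db`, `drop_db` and `repeats` must be positive")
  with_seed(seed, {
    hears <- function(level) stats::runif(1) < observer$psychometric(level)
    reports <- list()
    for (r in seq_len(repeats)) {
      level <- start_level
      for (i in seq_len(max_steps)) {
        if (!hears(level)) break
        level <- level - step_db
        if (i == max_steps) stopf("observer never stopped hearing (guard %d steps)", max_steps)
      }
      reports[[length(reports) + 1L]] <-
        data.frame(repeat_ = r, kind = "stop_hearing", level = level)
      level <- level - drop_db
      for (i in seq_len(max_steps)) {
        level <- level + step_db
        if (hears(level)) break
        if (i == max_steps) stopf("observer never heard again (guard %d steps)", max_steps)
      }
      reports[[length(reports) + 1L]] <-
        data.frame(repeat_ = r, kind = "hear_again", level = level)
    }
    reports <- do.call(rbind, reports)
    structure(mean(reports$level), reports = reports)
  })
}
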