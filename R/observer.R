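#' Simulated psychophysical observer
#'
#' Stand-in for a participant in the threshold procedures and the main
#' session: a psychometric function mapping stimulus level (dB) to
#' detection probability, a response-time sampler, and a spontaneous
#' false-alarm rate (responses not caused by any stimulus, Poisson in
#' time).
#'
#' @param psychometric Function `level -> detection probability`,
#'   monotonically non-decreasing, values in \[0, 1\].
#' @param rt_sampler Function `n -> n response latencies (s)`; defaults
#'   to a log-normal with median ~0.65 s truncated to \[0.3, 1.8\] s.
#' @param fa_rate Spontaneous response rate in events/s (default 0).
#' @return An `observer` object.
#' @examples
#' obs <- logistic_observer(midpoint = 0, slope = 1)
#' obs$psychometric(c(-5, 0, 5))
#' @export
observer <- function(psychometric, rt_sampler = NULL, fa_rate = 0) {
  stopifnot(is.function(psychometric))
  if (is.null(rt_sampler)) {
    rt_sampler <- function(n) {
      rt <- stats::rlnorm(n, meanlog = log(0.65), sdlog = 0.3)
      pmin(pmax(rt, 0.3), 1.8)
    }
  }
  structure(list(psychometric = psychometric, rt_sampler = rt_sampler,
                 fa_rate = fa_rate), class = "observer")
}

#' Logistic observer
#'
#' @param midpoint Level of 50% detection (dB).
#' @param slope Logistic scale: p(x) = 1 / (1 + exp(-(x - midpoint) * slope)),
#'   in 1/dB.
#' @param ... Passed to [observer()].
#' @return An `observer`.
#' @export
logistic_observer <- function(midpoint = 0, slope = 1, ...) {
  observer(function(level) stats::plogis((level - midpoint) * slope), ...)
}

#' Deterministic step-function observer
#'
#' Detects with probability 1 at or above `threshold`, 0 below; useful
#' for hand-traceable staircase tests.
#'
#' @param threshold Detection threshold (dB).
#' @param ... Passed to [observer()].
#' @return An `observer`.
#' @export
step_observer <- function(threshold = 0, ...) {
  observer(function(level) as.numeric(level >= threshold), ...)
}

#' Level of a given detection probability for a logistic observer
#'
#' @param midpoint,slope Logistic parameters as in [logistic_observer()].
#' @param p Target probability.
#' @return The level (dB) at which detection probability equals `p`.
#' @export
logistic_quantile <- function(midpoint, slope, p) {
  midpoint + stats::qlogis(p) / slope
}
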