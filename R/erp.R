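#' Average epochs into an event-related potential
#'
#' Computes the trial mean and the standard error of the mean (trial SD
#' divided by sqrt(n)) per channel and time point.
#'
#' @param epochs An `eeg_epochs` with at least 2 trials.
#' @return An `erp` object: `mean` and `sem` (channels x time matrices),
#'   `times`, `rate`, `channels`, `n_trials`, `baseline_window`
#'   (NULL until corrected).
#' @export
average_erp <- function(epochs) {
  n <- n_trials(epochs)
  if (n < 2) stopf("need at least 2 trials (SEM undefined for n = %d)", n)
  m <- apply(epochs$data, c(2, 3), mean)
  s <- apply(epochs$data, c(2, 3), stats::sd) / sqrt(n)
  dimnames(m) <- dimnames(s) <- list(epochs$channels, NULL)
  structure(list(mean = m, sem = s, times = epochs$times, rate = epochs$rate,
                 channels = epochs$channels, n_trials = n,
                 alignment = epochs$alignment, condition = epochs$condition,
                 baseline_window = NULL),
            class = "erp")
}

#' @export
print.erp <- function(x, ...) {
  cat(sprintf("<erp> '%s': %d channels x %d samples (n = %d trials), t in [%.3f, %.3f] s%s\n",
              x$condition, nrow(x$mean), ncol(x$mean), x$n_trials,
              min(x$times), max(x$times),
              if (is.null(x$baseline_window)) "" else
                sprintf(", baseline [%.3f, %.3f] s", x$baseline_window[1],
                        x$baseline_window[2])))
  invisible(x)
}

#' Baseline-correct an ERP
#'
#' Subtracts each channel's mean over the baseline window. The study
#' uses -200 to 0 ms before stimulus onset for stimulus-aligned ERPs and
#' -3100 to -2900 ms before the button press for response-aligned ERPs.
#' Idempotent: correcting twice equals correcting once.
#'
#' @param x An `erp`.
#' @param window `c(from, to)` in seconds, inside the epoch.
#' @return The corrected `erp` (with `baseline_window` recorded).
#' @export
baseline_correct <- function(x, window) {
  idx <- which(x$times >= window[1] & x$times <= window[2])
  if (length(idx) == 0L)
    stopf("baseline window [%g, %g] s outside the epoch [%g, %g] s",
          window[1], window[2], min(x$times), max(x$times))
  x$mean <- x$mean - rowMeans(x$mean[, idx, drop = FALSE])
  x$baseline_window <- window
  x
}

#' Extract a component peak from an ERP
#'
#' Finds the extremum (maximum for positive components, minimum for
#' negative) of the ERP on one channel inside a latency window; the raw
#' sample extremum is used (no interpolation) and ties break to the
#' earliest sample. Default study windows: stimulus-aligned late
#' positivity at Pz in 400-1300 ms and early negativity in 100-600 ms;
#' response-aligned positivity in -250 to 250 ms and negativity in -900
#' to -100 ms.
#'
#' @param x An `erp`.
#' @param channel Channel label.
#' @param window `c(from, to)` latency window in seconds.
#' @param polarity `"positive"` or `"negative"`.
#' @return List with `latency` (s) and `amplitude` (microvolts).
#' @export
component_peak <- function(x, channel, window,
                           polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  ch <- match(channel, x$channels)
  if (is.na(ch)) stopf("channel '%s' not found", channel)
  idx <- which(x$times >= window[1] & x$times <= window[2])
  if (length(idx) == 0L) stopf("empty component window")
  y <- x$mean[ch, idx]
  k <- if (polarity == "positive") which.max(y) else which.min(y)
  list(latency = x$times[idx[k]], amplitude = y[k])
}

#' Component-window presets
#'
#' The latency windows used to pick the late positivity (LP) and early
#' negativity (EN) per alignment, as configured for the study.
#'
#' @return Nested list `stimulus`/`response` x `lp`/`en` of
#'   `c(from, to)` windows in seconds.
#' @export
component_windows <- function() {
  list(stimulus = list(lp = c(0.4, 1.3), en = c(0.1, 0.6)),
       response = list(lp = c(-0.25, 0.25), en = c(-0.9, -0.1)))
}

#' Scalp topography of a component
#'
#' Per-channel time-average of the ERP over a latency interval (a
#' single latency gives that sample's column), e.g. over the interval a
#' cluster test marked significant.
#'
#' @param x An `erp`.
#' @param latency A single latency (s) or `c(from, to)` interval.
#' @return A `topography`: named numeric vector (one value per channel).
#' @export
component_topography <- function(x, latency) {
  idx <- if (length(latency) == 1L) {
    which.min(abs(x$times - latency))
  } else {
    which(x$times >= latency[1] & x$times <= latency[2])
  }
  if (length(idx) == 0L) stopf("latency interval outside the epoch")
  v <- rowMeans(x$mean[, idx, drop = FALSE])
  structure(stats::setNames(v, x$channels), class = "topography")
}

#' Spatial correlation of two topographies
#'
#' Pearson correlation across channels between two component
#' topographies — the similarity measure used to compare component
#' scalp distributions across alignments and conditions.
#'
#' @param a,b `topography` vectors over the same channel set.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
spatial_correlation <- function(a, b) {
  if (length(a) != length(b) || !all(names(a) == names(b)))
    stopf("topographies must share one channel set")
  if (length(a) < 3) stopf("need at least 3 channels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stopf("zero-variance topography")
  stats::cor(as.numeric(a), as.numeric(b))
}
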