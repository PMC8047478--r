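#' Assemble a continuous stimulation session
#'
#' Embeds level-jittered speech snippets in a continuous speech-shaped
#' noise bed and returns the mixed audio together with the ground-truth
#' event table. Two modes mirror the two recorded tasks:
#'
#' * `"main"`: snippet onsets follow the supplied ISI schedule and each
#'   snippet's level is drawn uniformly within +/- `level_jitter` dB of
#'   the detection threshold, so roughly 70% of presentations are heard.
#' * `"button_press"`: 60 clearly audible snippets (threshold + 5 to 6
#'   dB) presented every 10 s with +/- 1 s onset jitter; the listener's
#'   delayed button presses provide a motor control condition.
#'
#' Levels are applied as gains relative to the snippet's normalized RMS:
#' a snippet at level L dB is scaled by `10^(L/20)` relative to unit
#' RMS.
#'
#' @param noise `waveform` noise bed (defines session duration and rate).
#' @param snippets List of `waveform` speech snippets (same rate as
#'   `noise`), cycled through in seeded random order.
#' @param schedule An [build_isi_schedule()] result (`"main"` mode).
#' @param threshold_db Detection-threshold level (dB) from the staircase.
#' @param mode `"main"` or `"button_press"`.
#' @param seed Integer seed for level and onset jitter.
#' @param level_jitter Half-range of the level jitter in dB (default 1.5).
#' @param bp_n,bp_period,bp_jitter Button-press mode: number of stimuli
#'   (60), mean period (10 s), onset jitter (+/- 1 s).
#' @param bp_gain_range Button-press level range above threshold (dB),
#'   default `c(5, 6)`.
#' @return A list of class `continuous_session`: `audio` (`waveform`),
#'   `events` (data frame `onset_s`, `type`, `level_db`), `mode`, `seed`.
#' @export
assemble_session <- function(noise, snippets, schedule = NULL, threshold_db = 0,
                             mode = c("main", "button_press"), seed = 1,
                             level_jitter = 1.5, bp_n = 60, bp_period = 10,
                             bp_jitter = 1, bp_gain_range = c(5, 6)) {
  mode <- match.arg(mode)
  rate <- noise$rate
  for (s in snippets) if (s$rate != rate) stopf("snippet rate differs from noise rate")
  dur <- duration(noise)

  with_seed(seed, {
    if (mode == "main") {
      if (is.null(schedule)) stopf("`schedule` is required in main mode")
      onsets <- schedule$onsets
      levels <- stats::runif(length(onsets), threshold_db - level_jitter,
                             threshold_db + level_jitter)
    } else {
      # jittered intervals: consecutive gaps uniform in period +/- jitter
      onsets <- cumsum(stats::runif(bp_n, bp_period - bp_jitter,
                                    bp_period + bp_jitter))
      levels <- stats::runif(bp_n, threshold_db + bp_gain_range[1],
                             threshold_db + bp_gain_range[2])
    }
    snip_idx <- sample(rep_len(seq_along(snippets), length(onsets)))

    snip_len <- vapply(snippets, function(s) length(s$samples), numeric(1))
    ends <- onsets + snip_len[snip_idx] / rate
    if (any(onsets < 0) || any(ends > dur))
      stopf("schedule does not fit inside the %g s noise bed", dur)
    if (any(onsets[-1] < ends[-length(ends)]))
      stopf("snippets overlap in time")

    x <- noise$samples
    for (i in seq_along(onsets)) {
      s <- snippets[[snip_idx[i]]]
      gain <- 10^(levels[i] / 20) / max(rms(s), .Machine$double.eps)
      i0 <- round(onsets[i] * rate) + 1
      idx <- i0:(i0 + length(s$samples) - 1)
      x[idx] <- x[idx] + s$samples * gain
    }
    structure(list(audio = waveform(x, rate),
                   events = data.frame(onset_s = onsets, type = "stim",
                                       level_db = levels),
                   mode = mode, seed = seed),
              class = "continuous_session")
  })
}

#' @export
print.continuous_session <- function(x, ...) {
  cat(sprintf("<continuous_session> mode '%s': %d stimuli in %.1f s of noise @ %g Hz\n",
              x$mode, nrow(x$events), duration(x$audio), x$audio$rate))
  invisible(x)
}

#' Write / read an event table as TSV
#'
#' Plain-text interchange for stimulus/response event streams: columns
#' `onset_s`, `type`, and any extras (e.g. `level_db`, `label`).
#'
#' @param events Data frame with at least `onset_s` and `type`.
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `read_events` the
#'   data frame.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("onset_s", "type") %in% names(events)))
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
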