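#' Epoch container: trials x channels x time
#'
#' @param data Numeric array trials x channels x time (microvolts).
#' @param times Time axis in seconds relative to the alignment anchor,
#'   uniform spacing `1/rate`, anchor at t = 0.
#' @param rate Sampling rate (Hz).
#' @param channels Channel labels.
#' @param alignment `"stimulus"`, `"response"` or `"none"`.
#' @param condition Condition tag (e.g. `"hit_stim"`, `"fa"`, `"cr"`).
#' @param positions Optional electrode positions.
#' @return An `eeg_epochs` object.
#' @export
eeg_epochs <- function(data, times, rate, channels = NULL,
                       alignment = c("none", "stimulus", "response"),
                       condition = "unknown", positions = NULL) {
  alignment <- match.arg(alignment)
  data <- as.array(data)
  if (length(dim(data)) != 3L) stopf("`data` must be trials x channels x time")
  if (dim(data)[3] != length(times)) stopf("time axis length mismatch")
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(abs(dt - 1 / rate) > 1e-9)) stopf("`times` must be uniform at 1/rate")
  }
  if (is.null(channels)) channels <- paste0("Ch", seq_len(dim(data)[2]))
  structure(list(data = data, times = times, rate = rate, channels = channels,
                 alignment = alignment, condition = condition,
                 positions = positions),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> '%s': %d trials x %d channels x %d samples @ %g Hz, t in [%.3f, %.3f] s, %s-aligned\n",
              x$condition, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$rate, min(x$times), max(x$times), x$alignment))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs An `eeg_epochs`.
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Segment a continuous recording around event anchors
#'
#' Cuts `[anchor - pre, anchor + post]` windows (both endpoints
#' included, sample convention anchored at t = 0 on the recording's
#' sample grid) around each anchor time. Anchors too close to the record
#' edges for a full window are dropped and reported via the `dropped`
#' attribute and a message.
#'
#' @param rec An `eeg_recording`.
#' @param anchors Anchor times (s).
#' @param window `c(pre, post)` in seconds, both positive (e.g.
#'   `c(4.6, 1.9)` for response-aligned epochs, `c(2.8, 3.7)` for
#'   stimulus-aligned).
#' @param alignment,condition Metadata stored on the result.
#' @return An `eeg_epochs` with attribute `dropped` (indices of skipped
#'   anchors).
#' @export
epoch <- function(rec, anchors, window, alignment = "none",
                  condition = "unknown") {
  if (length(window) != 2L || any(window < 0))
    stopf("`window` must be c(pre, post), both >= 0 seconds")
  n_pre <- round(window[1] * rec$rate)
  n_post <- round(window[2] * rec$rate)
  n_samp <- ncol(rec$data)
  centers <- round(anchors * rec$rate) + 1
  ok <- centers - n_pre >= 1 & centers + n_post <= n_samp
  if (any(!ok))
    message(sum(!ok), " anchor(s) dropped: window extends beyond the record")
  keep <- centers[ok]
  out <- array(0, dim = c(length(keep), nrow(rec$data), n_pre + n_post + 1))
  for (i in seq_along(keep)) {
    out[i, , ] <- rec$data[, (keep[i] - n_pre):(keep[i] + n_post), drop = FALSE]
  }
  times <- seq(-n_pre, n_post) / rec$rate
  ep <- eeg_epochs(out, times, rec$rate, channels = rec$channels,
                   alignment = alignment, condition = condition,
                   positions = rec$positions)
  attr(ep, "dropped") <- which(!ok)
  ep
}

#' Reject trials by peak-to-peak amplitude
#'
#' Drops every trial whose maximum peak-to-peak amplitude (max minus min
#' per channel) over the non-excluded channels exceeds `threshold`
#' microvolts; the boundary is strict ("higher than"), so a trial at
#' exactly the threshold is kept. The study screens epochs at 300 uV
#' (and at 400 uV with frontal channels excluded before the artifact
#' decomposition stage, so blink trials survive to it).
#'
#' @param epochs An `eeg_epochs`.
#' @param threshold Peak-to-peak threshold (microvolts, default 300).
#' @param exclude_channels Channel labels ignored by the screen.
#' @return List with `epochs` (kept trials) and `mask` (logical, TRUE =
#'   kept).
#' @export
reject_peak_to_peak <- function(epochs, threshold = 300,
                                exclude_channels = character(0)) {
  if (threshold <= 0) stopf("`threshold` must be > 0")
  use <- !(epochs$channels %in% exclude_channels)
  if (!any(use)) stopf("all channels excluded from the rejection screen")
  p2p <- apply(epochs$data[, use, , drop = FALSE], 1,
               function(tr) max(apply(tr, 1, function(ch) max(ch) - min(ch))))
  mask <- p2p <= threshold
  kept <- epochs
  kept$data <- epochs$data[mask, , , drop = FALSE]
  list(epochs = kept, mask = mask)
}

#' Optional artifact-decomposition hook
#'
#' The study removes ocular/cardiac components with an independent
#' component analysis plus visual inspection; that manual stage is out
#' of scope here and exposed only as a pluggable hook: any function
#' taking and returning an `eeg_recording` can be inserted into the
#' pipeline. The default is the identity.
#'
#' @param rec An `eeg_recording`.
#' @param hook Function `eeg_recording -> eeg_recording` (default
#'   identity).
#' @return The (possibly cleaned) recording.
#' @export
apply_artifact_hook <- function(rec, hook = identity) {
  out <- hook(rec)
  if (!inherits(out, "eeg_recording"))
    stopf("artifact hook must return an `eeg_recording`")
  out
}

#' Serialize an epoch set to plain text (TSV + JSON header)
#'
#' Writes `<path>.json` (rate, times, channels, alignment, condition)
#' and `<path>.tsv` (one row per trial x channel, samples as columns).
#' Round-trips losslessly at full double precision.
#'
#' @param epochs An `eeg_epochs`.
#' @param path Base path (without extension).
#' @return `write_epochs` returns `path` invisibly; `read_epochs` the
#'   reconstructed `eeg_epochs`.
#' @export
write_epochs <- function(epochs, path) {
  meta <- list(rate = epochs$rate, times = epochs$times,
               channels = epochs$channels, alignment = epochs$alignment,
               condition = epochs$condition, dim = dim(epochs$data))
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 ncol = d[3], byrow = TRUE)
  df <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                   channel = rep(epochs$channels, d[1]))
  utils::write.table(cbind(df, format(flat, digits = 17, trim = TRUE,
                                      scientific = TRUE)),
                     paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t")
  d <- meta$dim
  flat <- as.matrix(tab[, -(1:2), drop = FALSE])
  arr <- aperm(array(t(flat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  eeg_epochs(arr, meta$times, meta$rate, channels = meta$channels,
             alignment = meta$alignment, condition = meta$condition)
}
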