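#' Design a Hamming windowed-sinc FIR filter
#'
#' Linear-phase one-pass FIR design used throughout the preprocessing
#' chain: an ideal sinc lowpass truncated to `order + 1` taps, tapered
#' by a Hamming window and normalized to exactly unit DC gain; a
#' highpass is the spectral inverse (delta minus the lowpass), giving an
#' exact DC null. `order` must be even so the filter is symmetric about
#' a single center tap and the group delay (`order/2` samples) can be
#' compensated exactly.
#'
#' When `order` is `NULL` it is chosen from the transition width by the
#' Hamming-window rule `order = 3.3 * rate / transition`, rounded up to
#' even — this reproduces the preprocessing orders used for the study
#' (0.3 Hz highpass, 0.6 Hz transition, order 1100 at 200 Hz; 45 Hz
#' lowpass, 8 Hz transition, order 84; 30 Hz lowpass, 7.5 Hz transition,
#' order 88).
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff Cutoff frequency (Hz), the -6 dB point.
#' @param rate Sampling rate (Hz).
#' @param transition Transition width (Hz), used when `order` is `NULL`.
#' @param order Filter order (number of taps minus one), even.
#' @return Numeric vector of `order + 1` taps with attributes `kind`,
#'   `cutoff`, `rate`, `order`.
#' @examples
#' taps <- design_windowed_sinc("lowpass", 45, rate = 200, transition = 8)
#' length(taps) # order 84 -> 85 taps
#' @export
design_windowed_sinc <- function(kind = c("lowpass", "highpass"), cutoff, rate,
                                 transition = NULL, order = NULL) {
  kind <- match.arg(kind)
  if (cutoff <= 0 || cutoff >= rate / 2)
    stopf("cutoff %g Hz must lie in (0, Nyquist = %g Hz)", cutoff, rate / 2)
  if (is.null(order)) {
    if (is.null(transition)) stopf("give either `order` or `transition`")
    if (cutoff + transition / 2 >= rate / 2)
      stopf("transition band extends beyond Nyquist")
    order <- ceiling(3.3 * rate / transition)
    if (order %% 2 == 1) order <- order + 1
  }
  if (order %% 2 != 0) stopf("`order` must be even (linear phase, integer delay)")
  m <- order / 2
  n <- seq(-m, m)
  fc <- cutoff / rate # cycles per sample
  h <- 2 * fc * sinc(2 * fc * n)
  w <- 0.54 + 0.46 * cos(pi * n / m) # Hamming window
  h <- h * w
  h <- h / sum(h) # exact unit DC gain
  if (kind == "highpass") {
    h <- -h
    h[m + 1] <- h[m + 1] + 1 # spectral inversion: exact DC null
  }
  structure(h, kind = kind, cutoff = cutoff, rate = rate, order = order)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Frequency response of an FIR filter
#'
#' @param taps FIR taps.
#' @param freq Frequencies (Hz) at which to evaluate.
#' @param rate Sampling rate (Hz); defaults to the taps' attribute.
#' @return Complex response (magnitude = gain).
#' @export
fir_response <- function(taps, freq, rate = attr(taps, "rate")) {
  n <- seq_along(taps) - 1
  vapply(freq, function(f) sum(taps * exp(-1i * 2 * pi * f / rate * n)),
         complex(1))
}

#' Multichannel EEG recording container
#'
#' @param data Numeric channels x samples matrix (microvolts).
#' @param rate Sampling rate (Hz).
#' @param channels Character channel labels (defaults to Ch1..ChN).
#' @param positions Optional data frame of unit-sphere positions
#'   matching `channels` (see [montage_1010()]).
#' @return An `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channels = NULL, positions = NULL) {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("Ch", seq_len(nrow(data)))
  if (length(channels) != nrow(data))
    stopf("%d labels for %d data rows", length(channels), nrow(data))
  rownames(data) <- channels
  structure(list(data = data, rate = rate, channels = channels,
                 positions = positions), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

#' Apply an FIR filter with zero effective phase
#'
#' Single forward convolution with compensation of the linear-phase
#' group delay (`order/2` samples), so features stay at their original
#' latencies: a unit impulse maps onto the taps centered at the impulse
#' sample. Edges are zero-padded.
#'
#' @param rec An `eeg_recording` (or numeric vector/matrix).
#' @param taps Symmetric FIR taps from [design_windowed_sinc()].
#' @return Filtered object of the same type and size.
#' @export
filter_zero_phase <- function(rec, taps) {
  apply_mat <- function(m) {
    if (ncol(m) <= length(taps))
      stopf("record (%d samples) not longer than the filter (%d taps)",
            ncol(m), length(taps))
    t(apply(m, 1, conv_centered, taps = taps))
  }
  if (inherits(rec, "eeg_recording")) {
    out <- rec
    out$data <- apply_mat(rec$data)
    rownames(out$data) <- rec$channels
    out
  } else if (is.matrix(rec)) {
    apply_mat(rec)
  } else {
    drop(apply_mat(matrix(rec, nrow = 1)))
  }
}

# FFT-based 'same' convolution centered on the filter's middle tap
conv_centered <- function(x, taps) {
  n <- length(x); L <- length(taps); m <- (L - 1) %/% 2
  nfft <- stats::nextn(n + L - 1, 2)
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                     stats::fft(c(taps, rep(0, nfft - L))), inverse = TRUE)) / nfft
  y[(m + 1):(m + n)]
}

#' Downsample a recording with anti-alias protection
#'
#' Lowpass-filters at 0.8 x the target Nyquist (Hamming windowed sinc)
#' and decimates by the integer factor `rate / target`. The time base is
#' preserved: sample k of the output is sample `1 + (k-1)*factor` of the
#' input, so an event at t seconds stays at t seconds.
#'
#' @param rec An `eeg_recording`.
#' @param target Target rate (Hz), must divide the current rate.
#' @return The downsampled `eeg_recording`.
#' @export
downsample <- function(rec, target = 200) {
  if (target > rec$rate) stopf("target rate %g above current rate %g", target, rec$rate)
  if (target == rec$rate) return(rec)
  factor <- rec$rate / target
  if (factor != round(factor)) stopf("rate %g not an integer multiple of target %g",
                                     rec$rate, target)
  aa <- design_windowed_sinc("lowpass", cutoff = 0.8 * target / 2, rate = rec$rate,
                             transition = 0.2 * target / 2)
  out <- filter_zero_phase(rec, aa)
  out$data <- out$data[, seq(1, ncol(out$data), by = factor), drop = FALSE]
  out$rate <- target
  out
}
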