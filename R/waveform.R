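#' Audio waveform container
#'
#' A minimal container for a single-channel audio waveform: a numeric
#' sample vector plus its sampling rate. Stimulus material for the
#' psychoacoustic task (speech snippets, masking noise, assembled
#' sessions) is carried in this form; the experiment standard is 50 kHz.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units).
#' @param rate Sampling rate in Hz.
#' @return An object of class `waveform` with fields `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' duration(w)
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is_number(rate) || rate <= 0) stopf("`rate` must be a positive number")
  if (length(samples) == 0L) stopf("waveform must contain at least one sample")
  if (!all(is.finite(samples))) stopf("waveform samples must be finite")
  structure(list(samples = samples, rate = rate), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s), rms %.4g\n",
              length(x$samples), x$rate, duration(x), rms(x)))
  invisible(x)
}

#' Waveform duration in seconds
#' @param wave A `waveform`.
#' @return Duration in seconds.
#' @export
duration <- function(wave) length(wave$samples) / wave$rate

#' Root-mean-square amplitude
#' @param wave A `waveform` or numeric vector.
#' @return RMS value.
#' @export
rms <- function(wave) {
  x <- if (inherits(wave, "waveform")) wave$samples else as.numeric(wave)
  sqrt(mean(x^2))
}

#' Normalize a waveform to a target RMS power
#'
#' Scales the waveform by a single factor so that its root-mean-square
#' amplitude equals `target_rms`. Used to equate the intensity of the
#' speech snippets before threshold titration.
#'
#' @param wave A `waveform`.
#' @param target_rms Target RMS amplitude (> 0).
#' @return The rescaled `waveform`.
#' @export
rms_normalize <- function(wave, target_rms = 1) {
  if (!is_number(target_rms) || target_rms <= 0) stopf("`target_rms` must be > 0")
  r <- rms(wave)
  if (r == 0) stopf("cannot normalize a zero-energy waveform")
  waveform(wave$samples * (target_rms / r), wave$rate)
}

#' Apply raised-cosine (Hann) onset/offset ramps
#'
#' Smooths the first and last `ramp_ms` milliseconds of a waveform with
#' half Hann windows so stimuli start and end without spectral splatter.
#' The gain is 0 at the first/last sample, 0.5 at the ramp midpoint, and
#' 1 over the interior.
#'
#' @param wave A `waveform`.
#' @param ramp_ms Ramp length in milliseconds (default 100).
#' @return The ramped `waveform`.
#' @export
hann_ramp <- function(wave, ramp_ms = 100) {
  n_ramp <- round(wave$rate * ramp_ms / 1000)
  n <- length(wave$samples)
  if (n < 2 * n_ramp) stopf("waveform (%d samples) shorter than two %g ms ramps", n, ramp_ms)
  if (n_ramp < 1) return(wave)
  # half Hann: 0 at sample 1, 0.5 at the midpoint, approaches 1 at ramp end
  g <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 1) / n_ramp))
  x <- wave$samples
  x[seq_len(n_ramp)] <- x[seq_len(n_ramp)] * g
  x[n - seq_len(n_ramp) + 1] <- x[n - seq_len(n_ramp) + 1] * g
  waveform(x, wave$rate)
}

#' Synthesize speech-shaped noise (SSN)
#'
#' Builds stationary masking noise whose long-term magnitude spectrum
#' matches the ensemble spectrum of a set of speech snippets: the
#' snippets' magnitude spectra (zero-padded to a common length) are
#' averaged, random phases are drawn uniformly on \[0, 2*pi) with
#' Hermitian symmetry enforced, and the result is inverse-transformed to
#' a real waveform. Speech-shaped noise masks speech more effectively
#' than white or pink noise because the spectra overlap.
#'
#' The noise is generated segment-wise at the snippet-spectrum length and
#' concatenated (each segment with fresh phases) until `dur_s` is
#' covered, then cropped and scaled to `target_rms`.
#'
#' @param snippets List of `waveform`s sharing one sampling rate.
#' @param dur_s Output duration in seconds.
#' @param seed Integer seed for the phase draws.
#' @param target_rms RMS of the output (default 1).
#' @return A `waveform` of length `round(dur_s * rate)`.
#' @export
make_ssn <- function(snippets, dur_s, seed, target_rms = 1) {
  if (length(snippets) == 0L) stopf("`snippets` must be a non-empty list of waveforms")
  rates <- vapply(snippets, function(s) s$rate, numeric(1))
  if (length(unique(rates)) != 1L) stopf("all snippets must share one sampling rate")
  rate <- rates[1]
  if (!is_number(dur_s) || dur_s <= 0) stopf("`dur_s` must be > 0")

  nfft <- max(vapply(snippets, function(s) length(s$samples), numeric(1)))
  mags <- vapply(snippets, function(s) {
    x <- c(s$samples, rep(0, nfft - length(s$samples)))
    Mod(stats::fft(x))
  }, numeric(nfft))
  target_mag <- rowMeans(mags)

  n_out <- round(dur_s * rate)
  n_seg <- ceiling(n_out / nfft)
  out <- with_seed(seed, {
    segs <- lapply(seq_len(n_seg), function(i) random_phase_noise(target_mag))
    unlist(segs, use.names = FALSE)[seq_len(n_out)]
  })
  rms_normalize(waveform(out, rate), target_rms)
}

# one real-valued noise segment with the given magnitude spectrum and
# uniform random phases (Hermitian-symmetric so the inverse FFT is real)
random_phase_noise <- function(target_mag) {
  nfft <- length(target_mag)
  half <- floor(nfft / 2)
  phase <- numeric(nfft)
  # bins 2..half get free phases; the mirror bins get the negated phases
  k <- 2:(half + 1)
  phase[k] <- stats::runif(length(k), 0, 2 * pi)
  if (nfft %% 2 == 0) phase[half + 1] <- 0 # Nyquist bin must stay real
  phase[nfft + 2 - 2:half] <- -phase[2:half]
  spec <- target_mag * exp(1i * phase)
  Re(stats::fft(spec, inverse = TRUE)) / nfft
}

#' Power spectral density by Welch's method of averaged periodograms
#'
#' @param wave A `waveform`.
#' @param nfft Segment length in samples (Hann-windowed, 50% overlap).
#' @return A list with `freq` (Hz) and `psd` (power/Hz).
#' @export
welch_psd <- function(wave, nfft = 1024) {
  x <- wave$samples
  n <- length(x)
  if (n < nfft) stopf("waveform shorter than one PSD segment")
  step <- nfft %/% 2
  starts <- seq(1, n - nfft + 1, by = step)
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(nfft) - 1) / (nfft - 1)))
  u <- sum(win^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)] * win
    p <- Mod(stats::fft(seg))^2 / (u * wave$rate)
    acc <- acc + p[seq_along(acc)]
  }
  list(freq = (seq_along(acc) - 1) * wave$rate / nfft, psd = acc / length(starts))
}
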