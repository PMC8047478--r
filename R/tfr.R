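#' Single-trial Morlet wavelet transform
#'
#' Convolves every trial and channel with each wavelet of the bank and
#' samples the complex coefficients on the bank's output time grid
#' (10 ms steps by default). Samples closer to an epoch edge than half
#' the wavelet length are flagged invalid per frequency — no statistic
#' downstream is ever computed from edge-contaminated samples.
#'
#' @param epochs An `eeg_epochs`.
#' @param bank A [wavelet_bank()].
#' @return A `tfr_coefs` object: complex array trials x channels x
#'   freqs x times, `times` (s), `freqs` (Hz), logical `valid`
#'   (freqs x times), and metadata.
#' @export
tfr_transform <- function(epochs, bank = wavelet_bank()) {
  rate <- epochs$rate
  d <- dim(epochs$data)
  n_samp <- d[3]
  step <- max(1L, round(bank$time_step * rate))
  out_idx <- seq(1L, n_samp, by = step)
  out_times <- epochs$times[out_idx]
  freqs <- bank$freqs

  wavelets <- lapply(freqs, make_wavelet, rate = rate, bank = bank)
  half_len <- vapply(wavelets, function(w) (length(w) - 1) %/% 2, numeric(1))
  if (any(2 * half_len + 1 > n_samp))
    stopf("epoch (%d samples) shorter than the longest wavelet (%d taps)",
          n_samp, max(2 * half_len + 1))

  valid <- t(vapply(half_len, function(h) out_idx > h & out_idx <= n_samp - h,
                    logical(length(out_idx))))

  nfft <- stats::nextn(n_samp + max(2 * half_len + 1) - 1, 2)
  wav_fft <- lapply(wavelets, function(w)
    stats::fft(c(w, rep(0, nfft - length(w)))))

  coef <- array(complex(1), dim = c(d[1], d[2], length(freqs), length(out_idx)))
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      xf <- stats::fft(c(epochs$data[tr, ch, ], rep(0, nfft - n_samp)))
      for (fi in seq_along(freqs)) {
        y <- stats::fft(xf * wav_fft[[fi]], inverse = TRUE) / nfft
        m <- half_len[fi]
        coef[tr, ch, fi, ] <- y[m + out_idx]
      }
    }
  }
  structure(list(coef = coef, times = out_times, freqs = freqs, valid = valid,
                 rate = rate, channels = epochs$channels,
                 alignment = epochs$alignment, condition = epochs$condition,
                 bank = bank),
            class = "tfr_coefs")
}

#' @export
print.tfr_coefs <- function(x, ...) {
  d <- dim(x$coef)
  cat(sprintf("<tfr_coefs> %d trials x %d channels x %d freqs x %d times ('%s')\n",
              d[1], d[2], d[3], d[4], x$condition))
  invisible(x)
}

#' Event-related spectral perturbation (trial-averaged power)
#'
#' Averages single-trial wavelet power (squared coefficient magnitude,
#' the default) or magnitude over trials, yielding the raw ERSP. The
#' magnitude/power choice is exposed because the two appear
#' interchangeably in the ERSP literature; all downstream quantities
#' here are expressed as power.
#'
#' @param coefs A [tfr_transform()] result.
#' @param measure `"power"` (|W|^2, default) or `"magnitude"` (|W|).
#' @return An `eeg_tfr` with `power` (channels x freqs x times),
#'   `kind = "raw"`, and the validity mask.
#' @export
ersp <- function(coefs, measure = c("power", "magnitude")) {
  measure <- match.arg(measure)
  a <- Mod(coefs$coef)
  if (measure == "power") a <- a^2
  p <- apply(a, c(2, 3, 4), mean)
  structure(list(power = p, times = coefs$times, freqs = coefs$freqs,
                 valid = coefs$valid, kind = "raw", measure = measure,
                 channels = coefs$channels, alignment = coefs$alignment,
                 condition = coefs$condition, bank = coefs$bank,
                 n_trials = dim(coefs$coef)[1], baseline_end_of_f = NULL),
            class = "eeg_tfr")
}

#' @export
print.eeg_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<eeg_tfr> %s %s: %d channels x %d freqs (%g-%g Hz) x %d times ('%s', n = %d)\n",
              x$kind, x$measure, d[1], length(x$freqs), min(x$freqs),
              max(x$freqs), d[3], x$condition, x$n_trials))
  invisible(x)
}

#' Express a TFR as relative change from a per-frequency baseline
#'
#' Computes `(P(t, f) - B(f)) / B(f)` where `B(f)` is the mean power
#' over the baseline window of frequency `f`. Because wavelet power
#' smears over the temporal FDHM, the baseline window at each frequency
#' must end at least `FDHM(f)` before the activation start; the window
#' is `[baseline_start, activation_start - FDHM(f)]` intersected with
#' the valid samples, and a frequency whose margin cannot be honored is
#' reported by name.
#'
#' @param tfr A raw `eeg_tfr` from [ersp()].
#' @param activation_start Start of the activation period (s).
#' @param baseline_start Start of the baseline window (s); defaults to
#'   the epoch start (valid samples only).
#' @return An `eeg_tfr` with `kind = "relative"` and
#'   `baseline_end_of_f` recorded.
#' @export
relative_baseline <- function(tfr, activation_start, baseline_start = -Inf) {
  if (tfr$kind != "raw") stopf("input must be a raw-power TFR")
  p <- tfr$power
  rel <- p
  base_end <- numeric(length(tfr$freqs))
  for (fi in seq_along(tfr$freqs)) {
    f <- tfr$freqs[fi]
    margin <- fdhm(f, tfr$bank)
    base_end[fi] <- activation_start - margin
    ok <- tfr$valid[fi, ] & tfr$times >= baseline_start &
      tfr$times <= base_end[fi]
    if (!any(ok))
      stopf("no valid baseline samples at %g Hz: window ends %.3f s (FDHM margin %.3f s)",
            f, base_end[fi], margin)
    b <- apply(p[, fi, ok, drop = FALSE], 1, mean)
    rel[, fi, ] <- sweep(sweep(p[, fi, , drop = FALSE], 1, b, `-`),
                         1, b, `/`)
  }
  tfr$power <- rel
  tfr$kind <- "relative"
  tfr$baseline_end_of_f <- base_end
  tfr
}

#' Band-average power trace
#'
#' Averages the TFR over the frequency bins inside a band, returning a
#' channels x time matrix. Standard bands: slow cortical potentials
#' (SCP) 1-4 Hz, alpha 8-12 Hz, beta 15-25 Hz.
#'
#' @param tfr An `eeg_tfr`.
#' @param band `c(lo, hi)` in Hz, or one of `"scp"`, `"alpha"`, `"beta"`.
#' @param valid_only Replace edge-contaminated samples by `NA`
#'   (default TRUE).
#' @return Channels x time matrix with attribute `times`.
#' @export
band_trace <- function(tfr, band = "scp", valid_only = TRUE) {
  if (is.character(band))
    band <- switch(match.arg(band, c("scp", "alpha", "beta")),
                   scp = c(1, 4), alpha = c(8, 12), beta = c(15, 25))
  sel <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (length(sel) == 0L) stopf("no frequency bins inside [%g, %g] Hz", band[1], band[2])
  p <- tfr$power[, sel, , drop = FALSE]
  if (valid_only) {
    for (k in seq_along(sel))
      p[, k, !tfr$valid[sel[k], ]] <- NA_real_
  }
  tr <- apply(p, c(1, 3), mean)
  if (is.null(dim(tr))) tr <- matrix(tr, nrow = 1)
  rownames(tr) <- tfr$channels
  attr(tr, "times") <- tfr$times
  tr
}
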