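#' Spatially correlated 1/f ("pink") background noise
#'
#' Generates multichannel noise with a power spectral density falling
#' as `1/f^exponent` — the standard model for ongoing EEG background
#' activity — by shaping the spectrum of Gaussian white noise. Spatial
#' correlation between channels is introduced by mixing one shared
#' noise source into every channel (`shared` is the shared variance
#' fraction), which makes cluster statistics behave realistically under
#' the null. Each channel is scaled to standard deviation `sigma`.
#'
#' @param n_samples Samples per channel.
#' @param n_channels Number of channels (default 1).
#' @param exponent Spectral slope (default 1; valid 0.5-2).
#' @param sigma Channel standard deviation in microvolts (default 20).
#' @param seed Integer seed, or `NULL` to draw from the current RNG
#'   stream (used internally when a caller already seeded).
#' @param shared Shared-variance fraction in \[0, 1) (default 0.3).
#' @return Channels x samples numeric matrix.
#' @export
pink_noise <- function(n_samples, n_channels = 1, exponent = 1, sigma = 20,
                       seed = NULL, shared = 0.3) {
  if (exponent < 0.5 || exponent > 2) stopf("`exponent` must be in [0.5, 2]")
  if (sigma <= 0) stopf("`sigma` must be > 0")
  if (shared < 0 || shared >= 1) stopf("`shared` must be in [0, 1)")
  gen <- function() {
    # draw the spectrum directly (Hermitian complex Gaussian scaled by
    # f^(-exponent/2)) at a composite FFT length and crop; cropping 1/f
    # noise leaves its spectrum intact and keeps the FFT fast for awkward
    # epoch lengths
    nfft <- stats::nextn(n_samples, 2)
    k <- 0:(nfft - 1)
    f <- pmin(k, nfft - k)
    scale <- c(0, f[-1]^(-exponent / 2)) # zero out DC
    shape <- function(n_series) {
      re <- matrix(stats::rnorm(nfft * n_series), nfft)
      im <- matrix(stats::rnorm(nfft * n_series), nfft)
      sp <- (re + 1i * im) * scale
      x <- Re(stats::mvfft(sp, inverse = TRUE))[seq_len(n_samples), , drop = FALSE]
      sw <- apply(x, 2, stats::sd)
      sweep(x, 2, pmax(sw, .Machine$double.eps), `/`)
    }
    indep <- shape(n_channels)
    x <- if (shared > 0) {
      com <- shape(1)
      sqrt(shared) * as.numeric(com) + sqrt(1 - shared) * indep
    } else indep
    sw <- apply(x, 2, stats::sd)
    t(sweep(x, 2, pmax(sw, .Machine$double.eps), `/`)) * sigma
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Planted-effect specification
#'
#' Describes one ground-truth effect added to synthetic epochs:
#'
#' * `"EN"` / `"LP"`: a Gaussian-windowed voltage deflection
#'   (`amplitude` in microvolts, negative for EN, positive for LP) at
#'   `latency` seconds with Gaussian SD `width`, weighted across
#'   channels by `topography`.
#' * `"SCP"` / `"alphaERD"` / `"betaERD"`: a relative *power* change of
#'   the noise inside `band` (`amplitude` = relative change, e.g. +0.5
#'   for a 50% enhancement, -0.4 for a 40% desynchronization) under a
#'   smooth plateau envelope of duration `width` centered at `latency`;
#'   the band-limited component of each trial is scaled by
#'   `sqrt(1 + amplitude)` so the planted power change equals
#'   `amplitude` exactly.
#'
#' @param name One of `"EN"`, `"LP"`, `"SCP"`, `"alphaERD"`, `"betaERD"`.
#' @param amplitude Microvolts (EN/LP) or relative power change (bands).
#' @param latency Center latency (s).
#' @param width Gaussian SD (EN/LP) or plateau duration (bands), s.
#' @param topography Named per-channel weight vector.
#' @param band `c(lo, hi)` Hz for band effects.
#' @param band_edge Spectral shoulder width (Hz) over which the
#'   modulation rolls off smoothly outside `band` (default 0.5);
#'   band-limited physiological modulations are not brick-wall.
#' @return An `effect_spec`.
#' @export
effect_spec <- function(name, amplitude, latency, width, topography,
                        band = NULL, band_edge = 0.5) {
  name <- match.arg(name, c("EN", "LP", "SCP", "alphaERD", "betaERD"))
  if (width <= 0) stopf("`width` must be > 0")
  if (name %in% c("SCP", "alphaERD", "betaERD")) {
    if (is.null(band)) band <- switch(name, SCP = c(1, 4), alphaERD = c(8, 12),
                                      betaERD = c(15, 25))
    if (amplitude <= -1) stopf("relative power change must be > -1")
  }
  structure(list(name = name, amplitude = amplitude, latency = latency,
                 width = width, topography = topography, band = band,
                 band_edge = band_edge), class = "effect_spec")
}

#' Cosine-falloff scalp topography template
#'
#' Raised-cosine weight around one or more center electrodes: weight 1
#' at a center, falling to 0 at 3D distance `spread`, maximum over
#' centers. Centro-parietal templates (center Pz/CPz) model the EN, LP
#' and SCP distributions; bilateral central templates (C3 and C4) the
#' motor desynchronizations.
#'
#' @param positions Montage data frame ([montage_1010()]).
#' @param centers Character labels of center electrodes.
#' @param spread Falloff radius on the unit head (default 0.8).
#' @return Named weight vector over all channels.
#' @export
topography_template <- function(positions, centers = c("Pz", "CPz"),
                                spread = 0.8) {
  xyz <- as.matrix(positions[, c("x", "y", "z")])
  rownames(xyz) <- positions$label
  miss <- setdiff(centers, positions$label)
  if (length(miss)) stopf("center channel(s) not in montage: %s",
                          paste(miss, collapse = ", "))
  w <- rep(0, nrow(xyz))
  for (ctr in centers) {
    d <- sqrt(colSums((t(xyz) - xyz[ctr, ])^2))
    w <- pmax(w, ifelse(d < spread, 0.5 * (1 + cos(pi * d / spread)), 0))
  }
  stats::setNames(w, positions$label)
}

# smooth plateau envelope: 1 over [center - width/2, center + width/2],
# raised-cosine ramps of `ramp` seconds outside
plateau_envelope <- function(times, center, width, ramp = 0.3) {
  d <- abs(times - center) - width / 2
  ifelse(d <= 0, 1, ifelse(d >= ramp, 0, 0.5 * (1 + cos(pi * d / ramp))))
}

# spectral weight of a band modulation: 1 inside the band, raised-cosine
# shoulders of `edge` Hz outside
band_weight <- function(f, band, edge) {
  d <- pmax(band[1] - f, f - band[2], 0)
  ifelse(d <= 0, 1, ifelse(d >= edge, 0, 0.5 * (1 + cos(pi * d / edge))))
}

#' Add a planted effect to an epoch set
#'
#' Adds the deflection or band-power modulation described by an
#' [effect_spec()] to every trial. For band effects, each trial and
#' channel is decomposed by FFT masking into the in-band and out-of-band
#' parts and the in-band part is scaled by
#' `1 + (sqrt(1 + amplitude) - 1) * envelope * topography`, so a fully
#' weighted channel carries exactly the planted relative power change at
#' the envelope plateau.
#'
#' @param epochs An `eeg_epochs`.
#' @param spec An [effect_spec()]; its `topography` is matched to the
#'   epoch channels by name (missing channels get weight 0).
#' @param latency_jitter Optional per-trial latency offsets (s), length
#'   `n_trials(epochs)` (used for response-time jitter between
#'   alignments).
#' @return The modified `eeg_epochs`.
#' @export
add_component <- function(epochs, spec, latency_jitter = NULL) {
  if (spec$amplitude == 0) return(epochs)
  topo <- spec$topography[epochs$channels]
  topo[is.na(topo)] <- 0
  topo <- as.numeric(topo)
  nt <- n_trials(epochs)
  lat <- rep(spec$latency, nt)
  if (!is.null(latency_jitter)) {
    if (length(latency_jitter) != nt) stopf("latency_jitter length mismatch")
    lat <- lat + latency_jitter
  }
  t <- epochs$times
  if (spec$name %in% c("EN", "LP")) {
    for (i in seq_len(nt)) {
      if (lat[i] - 3 * spec$width < min(t) || lat[i] + 3 * spec$width > max(t))
        stopf("component at %.3f s (+/- 3 width) outside the epoch", lat[i])
      bump <- spec$amplitude * exp(-(t - lat[i])^2 / (2 * spec$width^2))
      epochs$data[i, , ] <- epochs$data[i, , ] + outer(topo, bump)
    }
  } else {
    n <- length(t)
    nfft <- stats::nextn(n, 2) # composite length keeps the FFT fast
    f <- pmin(0:(nfft - 1), nfft - 0:(nfft - 1)) * epochs$rate / nfft
    bw <- band_weight(f, spec$band, spec$band_edge)
    gain <- sqrt(1 + spec$amplitude) - 1
    pad <- matrix(0, nfft, dim(epochs$data)[2])
    for (i in seq_len(nt)) {
      env <- plateau_envelope(t, lat[i], spec$width)
      x <- pad
      x[seq_len(n), ] <- t(matrix(epochs$data[i, , ],
                                  nrow = dim(epochs$data)[2])) # time x chan
      sp <- stats::mvfft(x) * bw
      band_part <- Re(stats::mvfft(sp, inverse = TRUE))[seq_len(n), , drop = FALSE] / nfft
      epochs$data[i, , ] <- epochs$data[i, , ] +
        t(band_part * env) * (gain * topo)
    }
  }
  epochs
}

# apply several band-power modulations sharing one forward FFT per trial
plant_band_effects <- function(epochs, specs, latency_jitter = NULL) {
  nt <- n_trials(epochs)
  t <- epochs$times
  n <- length(t)
  nch <- dim(epochs$data)[2]
  nfft <- stats::nextn(n, 2)
  f <- pmin(0:(nfft - 1), nfft - 0:(nfft - 1)) * epochs$rate / nfft
  prep <- lapply(specs, function(e) {
    topo <- e$topography[epochs$channels]
    topo[is.na(topo)] <- 0
    list(bw = band_weight(f, e$band, e$band_edge),
         gain = sqrt(1 + e$amplitude) - 1,
         topo = as.numeric(topo), latency = e$latency, width = e$width)
  })
  pad <- matrix(0, nfft, nch)
  for (i in seq_len(nt)) {
    x <- pad
    x[seq_len(n), ] <- t(matrix(epochs$data[i, , ], nrow = nch))
    sp <- stats::mvfft(x)
    for (p in prep) {
      lat <- p$latency + if (is.null(latency_jitter)) 0 else latency_jitter[i]
      env <- plateau_envelope(t, lat, p$width)
      spb <- sp * p$bw
      band_part <- Re(stats::mvfft(spb, inverse = TRUE))[seq_len(n), ,
                                                         drop = FALSE] / nfft
      epochs$data[i, , ] <- epochs$data[i, , ] +
        t(band_part * env) * (p$gain * p$topo)
    }
  }
  epochs
}

#' Default ground truth mirroring the study's qualitative findings
#'
#' Effect parameters for the synthetic generator, set to the component
#' amplitudes and latencies reported for the group: response-aligned
#' hits carry an early negativity (-2.7 uV at -250 ms), a late
#' positivity (+7.5 uV at -25 ms), a +50% slow (1-4 Hz) power
#' enhancement and alpha/beta desynchronizations; false alarms carry
#' the same pattern with a weaker positivity (+4.2 uV at -15 ms, i.e.
#' scaled by `fa_scale`) and EN at -415 ms; misses and correct
#' rejections are background noise only; button presses carry only the
#' motor desynchronizations. These are generator settings for
#' parameter-recovery testing, not reproductions of the participants'
#' data.
#'
#' @param positions Montage (default [montage_1010()]).
#' @param fa_scale Scaling of the LP and SCP effects in FAs relative to
#'   hits (default 0.56 = 4.2/7.5).
#' @param noise_sigma Trial noise SD in microvolts (default 14,
#'   calibrated so the planted condition differences are detectable by
#'   the cluster tests at the study's sample size).
#' @param noise_exponent Spectral slope of the background (default 1).
#' @param noise_shared Shared-variance fraction across channels
#'   (default 0.3).
#' @param subject_sd SD of the log-normal between-subject amplitude
#'   factor (default 0.2).
#' @param rt_meanlog,rt_sdlog Log-normal response-time parameters
#'   (median 0.65 s); RTs are truncated to \[0.3, 1.8\] s.
#' @return A `ground_truth` list with per-condition effect lists and
#'   noise/observer parameters.
#' @export
default_ground_truth <- function(positions = montage_1010(), fa_scale = 4.2 / 7.5,
                                 noise_sigma = 14, noise_exponent = 1,
                                 noise_shared = 0.3, subject_sd = 0.2,
                                 rt_meanlog = log(0.65), rt_sdlog = 0.25) {
  cp <- topography_template(positions, c("Pz", "CPz"))
  motor <- topography_template(positions, c("C3", "C4"), spread = 0.6)
  erd <- list(
    effect_spec("alphaERD", -0.40, latency = 0.0, width = 1.0, topography = motor),
    effect_spec("betaERD", -0.30, latency = -0.1, width = 0.8, topography = motor))
  hits <- c(list(
    effect_spec("EN", -2.7, latency = -0.250, width = 0.12, topography = cp),
    effect_spec("LP", 7.5, latency = -0.025, width = 0.08, topography = cp),
    effect_spec("SCP", 0.5, latency = -0.2, width = 1.2, topography = cp)), erd)
  fas <- c(list(
    effect_spec("EN", -2.9, latency = -0.415, width = 0.12, topography = cp),
    effect_spec("LP", 7.5 * fa_scale, latency = -0.015, width = 0.08, topography = cp),
    effect_spec("SCP", 0.5 * fa_scale, latency = -0.2, width = 1.2, topography = cp)),
    erd)
  structure(list(
    effects = list(hit = hits, fa = fas, miss = list(), cr = list(), bp = erd),
    positions = positions,
    noise = list(sigma = noise_sigma, exponent = noise_exponent,
                 shared = noise_shared),
    subject_sd = subject_sd,
    rt = list(meanlog = rt_meanlog, sdlog = rt_sdlog, lo = 0.3, hi = 1.8),
    fa_scale = fa_scale), class = "ground_truth")
}

scale_effects <- function(effects, g) {
  lapply(effects, function(e) { e$amplitude <- e$amplitude * g; e })
}

#' Noiseless ground-truth waveform of a condition
#'
#' Evaluates the expectation of a condition's planted mean time course
#' on one channel: the sum of the EN/LP Gaussian deflections weighted
#' by their topography at that channel (band-power modulations have
#' zero mean and do not contribute). This is the exact target that ERP
#' averaging estimates, so parameter-recovery tests compare against its
#' extrema rather than re-deriving them by hand.
#'
#' @param gt A ground truth (see [default_ground_truth()]).
#' @param condition `"hit"`, `"fa"`, `"miss"`, `"cr"` or `"bp"`.
#' @param channel Channel label.
#' @param times Time axis (s).
#' @return Numeric vector of the planted mean (microvolts) over `times`.
#' @export
ground_truth_waveform <- function(gt, condition, channel, times) {
  y <- numeric(length(times))
  for (e in gt$effects[[condition]]) {
    if (!e$name %in% c("EN", "LP")) next
    w <- e$topography[channel]
    if (is.na(w)) w <- 0
    y <- y + e$amplitude * as.numeric(w) *
      exp(-(times - e$latency)^2 / (2 * e$width^2))
  }
  y
}

#' Simulate one subject's epoch sets for all conditions
#'
#' Draws background 1/f noise epochs per condition and plants the
#' ground-truth effects: response-aligned hits and FAs get their full
#' effect lists; stimulus-aligned hits are the same effects shifted by
#' a per-trial response time (drawn from the ground truth's truncated
#' log-normal), which reproduces the smeared, lower-amplitude
#' stimulus-aligned positivity seen when RTs vary; misses (stimulus
#' aligned) and CRs carry noise only; button presses only the motor
#' desynchronizations. A per-subject log-normal gain scales all effect
#' amplitudes (between-subject variability).
#'
#' @param gt A [default_ground_truth()] (possibly modified).
#' @param n_trials Named trial counts, e.g.
#'   `c(hit = 100, miss = 60, fa = 60, cr = 60, bp = 60)`; conditions
#'   may be omitted.
#' @param seed Integer seed.
#' @param rate Sampling rate (Hz, default 200).
#' @param window_stim,window_resp Epoch windows `c(pre, post)` s
#'   (defaults 2.8/3.7 and 4.6/1.9).
#' @param channels Subset of montage channels to simulate (default all).
#' @param stim_aligned Also generate the stimulus-aligned hit copy
#'   (default TRUE; skipping it saves time when only response-aligned
#'   conditions are analyzed).
#' @return Named list of `eeg_epochs`: `hit_stim`, `hit_resp`, `miss`,
#'   `fa`, `cr`, `bp` (only those requested), with attribute
#'   `subject_gain`.
#' @export
simulate_subject <- function(gt, n_trials = c(hit = 100, miss = 60, fa = 60,
                                              cr = 60, bp = 60),
                             seed = 1, rate = 200,
                             window_stim = c(2.8, 3.7),
                             window_resp = c(4.6, 1.9),
                             channels = NULL, stim_aligned = TRUE) {
  pos <- gt$positions
  if (!is.null(channels)) pos <- pos[pos$label %in% channels, , drop = FALSE]
  with_seed(seed, {
    g <- stats::rlnorm(1, meanlog = -gt$subject_sd^2 / 2, sdlog = gt$subject_sd)
    noise_epochs <- function(n, window, alignment, condition) {
      times <- seq(-round(window[1] * rate), round(window[2] * rate)) / rate
      arr <- array(0, dim = c(n, nrow(pos), length(times)))
      for (i in seq_len(n))
        arr[i, , ] <- pink_noise(length(times), nrow(pos),
                                 exponent = gt$noise$exponent,
                                 sigma = gt$noise$sigma, seed = NULL,
                                 shared = gt$noise$shared)
      eeg_epochs(arr, times, rate, channels = pos$label, alignment = alignment,
                 condition = condition, positions = pos)
    }
    # band modulations act on the background noise, then the deflections
    # are added on top; band effects share one forward FFT per trial
    plant <- function(ep, effects, jitter = NULL) {
      is_band <- vapply(effects, function(e) !e$name %in% c("EN", "LP"),
                        logical(1))
      if (any(is_band)) ep <- plant_band_effects(ep, effects[is_band], jitter)
      for (e in effects[!is_band]) ep <- add_component(ep, e, latency_jitter = jitter)
      ep
    }
    rt_draw <- function(n) {
      rt <- stats::rlnorm(n, gt$rt$meanlog, gt$rt$sdlog)
      pmin(pmax(rt, gt$rt$lo), gt$rt$hi)
    }
    out <- list()
    if (!is.na(n_trials["hit"])) {
      n <- n_trials[["hit"]]
      rts <- rt_draw(n)
      eff <- scale_effects(gt$effects$hit, g)
      out$hit_resp <- plant(noise_epochs(n, window_resp, "response", "hit_resp"),
                            eff)
      if (stim_aligned) {
        out$hit_stim <- plant(noise_epochs(n, window_stim, "stimulus", "hit_stim"),
                              eff, jitter = rts)
        attr(out$hit_stim, "rts") <- rts
      }
    }
    if (!is.na(n_trials["miss"]))
      out$miss <- noise_epochs(n_trials[["miss"]], window_stim, "stimulus", "miss")
    if (!is.na(n_trials["fa"]))
      out$fa <- plant(noise_epochs(n_trials[["fa"]], window_resp, "response", "fa"),
                      scale_effects(gt$effects$fa, g))
    if (!is.na(n_trials["cr"]))
      out$cr <- noise_epochs(n_trials[["cr"]], window_stim, "none", "cr")
    if (!is.na(n_trials["bp"]))
      out$bp <- plant(noise_epochs(n_trials[["bp"]], window_resp, "response", "bp"),
                      scale_effects(gt$effects$bp, g))
    attr(out, "subject_gain") <- g
    out
  })
}

#' Simulate a full multi-subject dataset
#'
#' @inheritParams simulate_subject
#' @param n_subjects Number of subjects (default 16, the analyzed
#'   sample size).
#' @param ... Passed to [simulate_subject()].
#' @return List of per-subject condition lists; deterministic in
#'   `(gt, seed)`.
#' @export
simulate_dataset <- function(gt, n_subjects = 16, seed = 1, ...) {
  lapply(seq_len(n_subjects), function(s)
    simulate_subject(gt, seed = derive_seed(seed, paste0("subject", s)), ...))
}

#' Simulate a behavioral session from an observer and a schedule
#'
#' Plays the stimulus schedule against a simulated observer: each
#' stimulus is detected with the psychometric probability at its
#' presented level and, if detected, answered after a truncated
#' log-normal response time; spontaneous responses (illusory
#' perceptions) arrive as a Poisson process at `observer$fa_rate`,
#' suppressed within `fa_suppress` seconds after any stimulus so they
#' remain unambiguous false alarms. Returns the event stream plus the
#' generating truth for label round-trip testing.
#'
#' @param obs An [observer()].
#' @param onsets Stimulus onset times (s), e.g.
#'   `build_isi_schedule()$onsets`.
#' @param levels Stimulus levels (dB), recycled to `length(onsets)`.
#' @param dur_s Session duration (s); default covers the last onset
#'   + 5 s.
#' @param seed Integer seed.
#' @param fa_suppress Stimulus-locked suppression window for
#'   spontaneous responses (s, default 3.6).
#' @return List: `stream` ([event_stream()]), `truth` (list with
#'   `stim_label` hit/miss and `response_source` stim index or NA).
#' @export
simulate_observer_session <- function(obs, onsets, levels = 0, dur_s = NULL,
                                      seed = 1, fa_suppress = 3.6) {
  levels <- rep_len(levels, length(onsets))
  if (is.null(dur_s)) dur_s <- max(onsets, 0) + 5
  with_seed(seed, {
    p <- obs$psychometric(levels)
    detected <- stats::runif(length(onsets)) < p
    rts <- obs$rt_sampler(sum(detected))
    rts <- pmin(pmax(rts, 0.3), 1.8)
    resp <- onsets[detected] + rts
    src <- which(detected)
    if (obs$fa_rate > 0) {
      n_fa <- stats::rpois(1, obs$fa_rate * dur_s)
      fa_t <- sort(stats::runif(n_fa, 0, dur_s))
      keep <- vapply(fa_t, function(t0) {
        prev <- onsets[onsets <= t0]
        length(prev) == 0 || t0 - max(prev) > fa_suppress
      }, logical(1))
      fa_t <- fa_t[keep]
      resp <- c(resp, fa_t)
      src <- c(src, rep(NA_integer_, length(fa_t)))
    }
    ord <- order(resp)
    resp <- resp[ord]; src <- src[ord]
    # enforce strict ordering for the stream container
    dup <- duplicated(resp)
    resp <- resp[!dup]; src <- src[!dup]
    ok <- resp <= dur_s
    resp <- resp[ok]; src <- src[ok]
    list(stream = event_stream(onsets, resp, dur_s),
         truth = list(stim_label = ifelse(detected, "hit", "miss"),
                      response_source = src))
  })
}
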