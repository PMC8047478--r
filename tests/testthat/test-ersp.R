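test_that("cycle counts interpolate linearly from 3 to 10", {
  b <- wavelet_bank()
  expect_equal(cycles_at(1, b), 3)
  expect_equal(cycles_at(45, b), 10)
  expect_equal(cycles_at(23, b), 6.5)
  expect_error(cycles_at(0.5, b), "outside")
})

test_that("closed-form widths reproduce the printed extremes", {
  b <- wavelet_bank()
  expect_equal(round(fdhm(1, b) * 1000), 1124)
  expect_equal(round(fdhm(45, b) * 1000), 83)
  expect_equal(round(spectral_fwhm(1, b), 2), 0.78)
  expect_equal(round(spectral_fwhm(45, b), 2), 10.60)
  # time-bandwidth identity holds across the whole grid
  for (f in b$freqs)
    expect_equal(fdhm(f, b) * spectral_fwhm(f, b), 4 * log(2) / pi,
                 tolerance = 1e-12)
  # doubling n at fixed f halves the spectral width
  b2 <- wavelet_bank(cycles_min = 6, cycles_max = 20)
  expect_equal(spectral_fwhm(1, b2), spectral_fwhm(1, b) / 2)
})

test_that("generated wavelets match their closed-form widths", {
  b <- wavelet_bank()
  rate <- 200
  w <- make_wavelet(10, rate, b)
  m <- Mod(w)
  expect_equal(m, rev(m))                       # symmetric envelope
  expect_equal(sum(m^2), 1, tolerance = 1e-12)  # unit energy
  measured <- sum(m >= max(m) / 2) / rate       # half-max duration
  expect_lte(abs(measured - fdhm(10, b)), 1 / rate)
  # spectral peak at the nominal frequency
  spec <- Mod(fft(c(w, rep(0, 8192 - length(w)))))
  f_axis <- (seq_along(spec) - 1) * rate / 8192
  expect_lte(abs(f_axis[which.max(spec)] - 10), rate / 8192 + 0.01)
  expect_error(make_wavelet(150, 200), "too low")
})

test_that("the transform localizes tones with power scaling as amplitude squared", {
  rate <- 200
  times <- seq(-2, 2, by = 1 / rate)
  bank <- wavelet_bank(fmin = 4, fmax = 24, freq_step = 0.5)
  tone <- function(f, a = 1) {
    arr <- array(0, c(1, 1, length(times)))
    arr[1, 1, ] <- a * sin(2 * pi * f * times)
    eeg_epochs(arr, times, rate)
  }
  tf <- ersp(tfr_transform(tone(10), bank))
  ci <- which.min(abs(tf$times))
  expect_equal(tf$freqs[which.max(tf$power[1, , ci])], 10, tolerance = 0.51)
  tf2 <- ersp(tfr_transform(tone(10, a = 3), bank))
  fi <- which.min(abs(tf$freqs - 10))
  expect_equal(tf2$power[1, fi, ci] / tf$power[1, fi, ci], 9, tolerance = 1e-6)

  # two tones produce two distinct ridges matching single-tone runs
  arr <- array(0, c(1, 1, length(times)))
  arr[1, 1, ] <- sin(2 * pi * 5 * times) + sin(2 * pi * 20 * times)
  both <- ersp(tfr_transform(eeg_epochs(arr, times, rate), bank))
  p <- both$power[1, , ci]
  ridge <- tf$freqs[c(which.min(abs(tf$freqs - 5)), which.min(abs(tf$freqs - 20)))]
  local_max <- tf$freqs[which(diff(sign(diff(p))) == -2) + 1]
  expect_true(all(vapply(ridge, function(r) any(abs(local_max - r) <= 0.5),
                         logical(1))))
  expect_error(tfr_transform(tone(10), wavelet_bank(fmin = 0.2, fmax = 1)),
               "shorter than the longest wavelet")
})

test_that("ERSP is the trial-average power, invariant to phase and duplication", {
  rate <- 100
  times <- seq(-1.5, 1.5, by = 1 / rate)
  bank <- wavelet_bank(fmin = 8, fmax = 12, freq_step = 1)
  set.seed(21)
  x <- rnorm(length(times))
  arr1 <- array(x, c(1, 1, length(times)))
  co1 <- tfr_transform(eeg_epochs(arr1, times, rate), bank)
  e1 <- ersp(co1)
  expect_equal(e1$power[1, , ], Mod(co1$coef[1, 1, , ])^2)
  # magnitude measure on request
  expect_equal(ersp(co1, "magnitude")$power[1, , ], Mod(co1$coef[1, 1, , ]))

  # duplicating the trial set leaves the ERSP unchanged
  arr2 <- array(0, c(2, 1, length(times)))
  arr2[1, 1, ] <- x; arr2[2, 1, ] <- x
  e2 <- ersp(tfr_transform(eeg_epochs(arr2, times, rate), bank))
  expect_equal(e2$power, e1$power)
})

test_that("ERSP power of a noisy tone matches a spectrogram oracle", {
  rate <- 100
  times <- seq(-2, 2, by = 1 / rate)
  f0 <- 10
  set.seed(17)
  n_tr <- 60
  amp <- 2
  arr <- array(rnorm(n_tr * length(times), sd = 1), c(n_tr, 1, length(times)))
  for (i in seq_len(n_tr))
    arr[i, 1, ] <- arr[i, 1, ] + amp * sin(2 * pi * f0 * times + runif(1, 0, 2 * pi))
  bank <- wavelet_bank(fmin = 8, fmax = 12, freq_step = 0.5)
  tf <- ersp(tfr_transform(eeg_epochs(arr, times, rate), bank))
  fi <- which.min(abs(tf$freqs - f0))
  mid <- tf$valid[fi, ] & abs(tf$times) < 1
  got <- mean(tf$power[1, fi, mid])
  # oracle: unit-energy wavelet response to A sin() is A^2/4 * sum|w| at f0
  # measured independently from the generated taps' transfer gain
  w <- make_wavelet(f0, rate, bank)
  gain <- Mod(sum(w * exp(-1i * 2 * pi * f0 * (seq_along(w) - 1) / rate)))^2
  want_tone <- amp^2 / 4 * gain
  # white-noise floor: sigma^2 spread over the wavelet's energy bandwidth
  want_noise <- 1
  expect_equal(got, want_tone + want_noise, tolerance = 0.1 * (want_tone + want_noise))
})

test_that("relative baseline normalization and FDHM margins behave", {
  rate <- 100
  times <- seq(-3, 2, by = 1 / rate)
  bank <- wavelet_bank(fmin = 8, fmax = 12, freq_step = 1)
  set.seed(9)
  # stationary noise: relative power ~ 0 everywhere
  arr <- array(rnorm(60 * length(times)), c(60, 1, length(times)))
  tf <- ersp(tfr_transform(eeg_epochs(arr, times, rate), bank))
  rel <- relative_baseline(tf, activation_start = 0, baseline_start = -2.5)
  act <- rel$times > 0 & rel$times < 1.5
  expect_lt(max(abs(apply(rel$power[1, , act], 1, mean))), 0.15)
  expect_equal(rel$baseline_end_of_f, -fdhm(bank$freqs, bank))

  # a doubled-power segment reads as relative change 1
  arr2 <- arr
  boost <- times >= 0.2
  for (i in 1:60) arr2[i, 1, boost] <- sqrt(2) * arr2[i, 1, boost]
  tf2 <- ersp(tfr_transform(eeg_epochs(arr2, times, rate), bank))
  rel2 <- relative_baseline(tf2, activation_start = 0.2, baseline_start = -2.5)
  late <- rel2$times > 0.7 & rel2$times < 1.5
  expect_equal(mean(rel2$power[1, , late]), 1, tolerance = 0.25)

  # margin violation is reported with the offending frequency
  short <- eeg_epochs(arr[, , times > -0.8, drop = FALSE], times[times > -0.8],
                      rate)
  tfs <- ersp(tfr_transform(short, bank))
  expect_error(relative_baseline(tfs, activation_start = -0.45), "8")
})

test_that("band traces average the requested bins and expose planted ERD", {
  rate <- 100
  times <- seq(-3, 1.5, by = 1 / rate)
  bank <- wavelet_bank(fmin = 8, fmax = 12, freq_step = 1)
  pos <- montage_1010()
  motor <- topography_template(pos, c("C3", "C4"), spread = 0.6)
  gt <- default_ground_truth()
  gt$subject_sd <- 1e-9
  gt$effects$hit <- list(effect_spec("alphaERD", -0.4, latency = 0, width = 1.0,
                                     topography = motor))
  subj <- simulate_subject(gt, n_trials = c(hit = 80), seed = 13, rate = 200,
                           window_resp = c(3, 1.5), stim_aligned = FALSE,
                           channels = c("C3", "C4"))
  tf <- ersp(tfr_transform(subj$hit_resp, bank))
  rel <- relative_baseline(tf, activation_start = -0.8, baseline_start = -2.6)
  tr <- band_trace(rel, "alpha")
  dip <- min(colMeans(tr), na.rm = TRUE)
  expect_lt(abs(dip - (-0.4)), 0.2 * 0.4 + 0.05)

  # single-bin band equals that bin's trace; flat spectrum equals its mean
  tr1 <- band_trace(rel, c(9, 9))
  expect_equal(tr1[1, ], ifelse(rel$valid[2, ], rel$power[1, 2, ], NA),
               ignore_attr = TRUE)
  expect_error(band_trace(rel, c(30, 40)), "no frequency bins")
})
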