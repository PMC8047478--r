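test_that("windowed-sinc designs have exact DC behavior and symmetry", {
  lp <- design_windowed_sinc("lowpass", 45, rate = 200, order = 84)
  expect_equal(Mod(fir_response(lp, 0)), 1, tolerance = 1e-6)
  hp <- design_windowed_sinc("highpass", 0.3, rate = 200, order = 1100)
  expect_equal(Mod(fir_response(hp, 0)), 0, tolerance = 1e-6)
  expect_equal(as.numeric(lp), rev(as.numeric(lp)))
  expect_equal(as.numeric(hp), rev(as.numeric(hp)))
  # transition widths imply the preprocessing orders via the Hamming rule
  expect_equal(attr(design_windowed_sinc("highpass", 0.3, 200, transition = 0.6),
                    "order"), 1100)
  expect_equal(attr(design_windowed_sinc("lowpass", 45, 200, transition = 8),
                    "order"), 84)
  expect_equal(attr(design_windowed_sinc("lowpass", 30, 200, transition = 7.5),
                    "order"), 88)
  expect_error(design_windowed_sinc("lowpass", 150, rate = 200, order = 10),
               "Nyquist")
})

test_that("lowpass taps agree with an independent FIR designer", {
  skip_if_not_installed("signal")
  ours <- design_windowed_sinc("lowpass", 45, rate = 200, order = 84)
  theirs <- signal::fir1(84, 45 / 100, type = "low")
  # design methods differ in detail; the realized frequency responses of the
  # two Hamming-windowed designs must agree across pass, transition and stop
  freq <- seq(0, 99, by = 0.5)
  ga <- Mod(fir_response(ours, freq))
  gb <- Mod(fir_response(structure(as.numeric(theirs), rate = 200), freq))
  expect_lt(max(abs(ga - gb)), 0.05)
  flank <- freq < 40 | freq > 50 # tight agreement outside the transition band
  expect_lt(max(abs(ga[flank] - gb[flank])), 0.01)
})

test_that("single-pass filtering is zero-phase and linear", {
  lp <- design_windowed_sinc("lowpass", 45, rate = 200, order = 84)
  x <- numeric(3000); x[1500] <- 1
  y <- filter_zero_phase(x, lp)
  expect_equal(which.max(y), 1500)
  expect_equal(y[1500 + (-42:42)], as.numeric(lp), tolerance = 1e-12)

  t <- (0:2999) / 200
  s10 <- sin(2 * pi * 10 * t)
  y10 <- filter_zero_phase(s10, lp)
  mid <- 500:2500
  fit <- lm(y10[mid] ~ sin(2 * pi * 10 * t[mid]) + cos(2 * pi * 10 * t[mid]))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.01)   # gain ~ 1
  expect_lt(abs(unname(coef(fit)[3])), 0.01)                # phase ~ 0

  s60 <- sin(2 * pi * 60 * t)
  y60 <- filter_zero_phase(s60, lp)
  want_gain <- Mod(fir_response(lp, 60))
  expect_equal(sd(y60[mid]) / sd(s60[mid]), want_gain, tolerance = 0.1 * want_gain + 1e-4)

  # linearity
  set.seed(2)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_equal(filter_zero_phase(2 * a + 3 * b, lp),
               2 * filter_zero_phase(a, lp) + 3 * filter_zero_phase(b, lp),
               tolerance = 1e-9)
  expect_error(filter_zero_phase(rnorm(50), lp), "not longer")
})

test_that("downsampling preserves amplitude, constants and the time base", {
  t <- (0:9999) / 1000
  rec <- eeg_recording(rbind(sin(2 * pi * 5 * t), rep(2, 10000)), 1000)
  dn <- downsample(rec, 200)
  expect_equal(dn$rate, 200)
  expect_equal(ncol(dn$data), 2000)
  mid <- 300:1700
  expect_equal(sd(dn$data[1, mid]), sd(rec$data[1, ]), tolerance = 0.01)
  expect_equal(dn$data[2, mid], rep(2, length(mid)), tolerance = 1e-6)
  # a feature at t = 3 s stays at t = 3 s: sample index 601 at 200 Hz
  rec2 <- eeg_recording(matrix(exp(-((t - 3) / 0.05)^2), nrow = 1), 1000)
  dn2 <- downsample(rec2, 200)
  expect_equal(which.max(dn2$data[1, ]), 601)
  expect_error(downsample(rec, 3000), "above current rate")
})

test_that("epoching cuts exact windows and reports out-of-range anchors", {
  rate <- 200
  ramp <- matrix(seq_len(30 * rate), nrow = 1) # linear ramp, 30 s
  rec <- eeg_recording(ramp, rate)
  expect_message(ep <- epoch(rec, anchors = c(10, 1, 29.9), window = c(4.6, 1.9)),
                 "dropped")
  expect_equal(dim(ep$data), c(1, 1, 1301))
  expect_equal(attr(ep, "dropped"), c(2L, 3L))
  expect_equal(ep$times[1], -4.6)
  expect_equal(ep$times[1301], 1.9)
  # the epoch is exactly the ramp segment
  center <- 10 * rate + 1
  expect_equal(ep$data[1, 1, ], as.numeric(ramp[1, (center - 920):(center + 380)]))
})

test_that("peak-to-peak rejection is strict, exhaustive and order-invariant", {
  times <- (0:199) / 200
  arr <- array(0, dim = c(22, 2, 200))
  set.seed(8)
  for (i in 1:20) arr[i, 1, ] <- rnorm(200, sd = 40)
  arr[21, 1, ] <- 160 * sin(2 * pi * 5 * times) # p2p 320 -> rejected at 300
  arr[22, 1, ] <- seq(0, 300, length.out = 200) # p2p exactly 300 -> kept
  ep <- eeg_epochs(arr, times, 200, channels = c("Cz", "Fp1"))
  res <- reject_peak_to_peak(ep, threshold = 300)
  expect_false(res$mask[21])
  expect_true(res$mask[22])
  # brute-force per-trial min/max scan
  want <- vapply(seq_len(22), function(i) {
    max(apply(arr[i, , , drop = FALSE][1, , , drop = TRUE], 1,
              function(ch) max(ch) - min(ch))) <= 300
  }, logical(1))
  expect_equal(res$mask, want)
  # permutation invariance over trials
  perm <- sample(22)
  ep2 <- eeg_epochs(arr[perm, , , drop = FALSE], times, 200,
                    channels = c("Cz", "Fp1"))
  expect_equal(reject_peak_to_peak(ep2, 300)$mask, res$mask[perm])
  # excluded channels are ignored by the screen
  arr2 <- arr; arr2[1, 2, ] <- c(-500, rep(0, 199))
  ep3 <- eeg_epochs(arr2, times, 200, channels = c("Cz", "Fp1"))
  expect_true(reject_peak_to_peak(ep3, 400, exclude_channels = "Fp1")$mask[1])
  expect_false(reject_peak_to_peak(ep3, 400)$mask[1])
  expect_error(reject_peak_to_peak(ep, 300, exclude_channels = c("Cz", "Fp1")),
               "all channels")
})

test_that("epoch sets round-trip losslessly through the text container", {
  set.seed(4)
  ep <- eeg_epochs(array(rnorm(3 * 2 * 25), c(3, 2, 25)),
                   times = seq(-0.05, 0.07, by = 0.005), rate = 200,
                   channels = c("Cz", "Pz"), alignment = "response",
                   condition = "fa")
  path <- file.path(tempdir(), "ep_roundtrip")
  write_epochs(ep, path)
  back <- read_epochs(path)
  expect_equal(back$data, ep$data)
  expect_equal(back$times, ep$times)
  expect_equal(back$channels, ep$channels)
  expect_equal(back$condition, "fa")
})

test_that("BrainVision ASCII recordings are read with scaling and markers", {
  dir <- tempdir()
  dat <- rbind(Ch1 = c(1.5, -2, 3, 0.25), Ch2 = c(10, 20, -30, 5))
  write.table(t(dat), file.path(dir, "toy.dat"), row.names = FALSE,
              col.names = FALSE)
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "DataFile=toy.dat",
    "MarkerFile=toy.vmrk",
    "DataFormat=ASCII",
    "DataOrientation=VECTORIZED",
    "NumberOfChannels=2",
    "SamplingInterval=5000",
    "[Channel Infos]",
    "Ch1=Cz,,0.5",
    "Ch2=Pz,,1",
    "[ASCII Infos]",
    "SkipLines=0"), file.path(dir, "toy.vhdr"))
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Marker Infos]",
    "Mk1=Stimulus,S  1,41,1,0",
    "Mk2=Response,R  1,101,1,0"), file.path(dir, "toy.vmrk"))
  rec <- read_brainvision(file.path(dir, "toy.vhdr"))
  expect_equal(rec$rate, 200)
  expect_equal(rec$channels, c("Cz", "Pz"))
  expect_equal(rec$data[1, ], c(1.5, -2, 3, 0.25) * 0.5, ignore_attr = TRUE)
  expect_equal(rec$data[2, ], c(10, 20, -30, 5), ignore_attr = TRUE)
  mk <- attr(rec, "markers")
  expect_equal(mk$onset_s, c(0.2, 0.5))
  expect_equal(mk$type, c("Stimulus", "Response"))
})

test_that("the artifact hook is the identity unless a cleaner is supplied", {
  rec <- eeg_recording(matrix(rnorm(200), 2), 100)
  expect_identical(apply_artifact_hook(rec), rec)
  halved <- apply_artifact_hook(rec, function(r) { r$data <- r$data / 2; r })
  expect_equal(halved$data, rec$data / 2)
  expect_error(apply_artifact_hook(rec, function(r) r$data), "must return")
})
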