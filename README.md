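# illusioneeg

EEG analysis for continuous-design auditory signal-detection experiments
in which listeners report near-threshold speech embedded in
speech-shaped noise — and sometimes report speech that was never
presented. The package is aimed at auditory/EEG researchers who want a
complete, testable implementation of that paradigm's analysis chain:
stimulus construction and threshold titration, timing-rule trial
categorization, FIR preprocessing and epoching, ERP component analysis,
Morlet-wavelet spectral perturbations, and nonparametric cluster-based
permutation statistics — plus a seeded synthetic-data generator with
full ground truth, so the whole chain can be validated end to end by
parameter recovery without any participant data.

## What is implemented

* **Stimuli & psychophysics** — speech-shaped noise by phase
  randomization of the snippet ensemble spectrum (`make_ssn`), RMS
  normalization and Hann onset ramps, pseudo-random ISI schedules with
  a repeating short-to-long sub-block pattern (`build_isi_schedule`),
  hearing-level bracketing (`estimate_ihl`) and a transformed
  1-up/2-down staircase (`run_staircase`) run against simulated
  observers. The staircase converges at the level where two consecutive
  detections are as likely as not, i.e. a detection probability of
  sqrt(1/2) = 70.7%.
* **Behavior** — the continuous design has no trial bins; responses and
  stimuli are classified by timing rules (`classify_events`): hits
  (response 0.3–1.8 s after onset), misses (none within 3.6 s), false
  alarms (no onset within the preceding 3.6 s), margins in between, and
  correct-rejection anchors tiled into event-free stretches.
* **Preprocessing** — one-pass zero-phase Hamming windowed-sinc FIR
  filters (`design_windowed_sinc`, `filter_zero_phase`), anti-aliased
  downsampling, epoching with exact sample conventions, strict
  peak-to-peak rejection, and a minimal BrainVision reader.
* **ERP / ERSP** — trial averaging with SEM, baseline correction,
  component peaks and topographies with spatial correlation; a Morlet
  wavelet bank (1–45 Hz, 3–10 cycles) with closed-form temporal FDHM
  `n sqrt(2 ln 2) / (pi f)` (1124 ms at 1 Hz to 83 ms at 45 Hz) and
  spectral FWHM `2 sqrt(2 ln 2) f / n` (0.78 to 10.60 Hz), trial-level
  transforms, relative-baseline ERSPs with per-frequency FDHM margins,
  and band traces (SCP 1–4, alpha 8–12, beta 15–25 Hz).
* **Statistics** — cluster-based permutation tests on paired
  multi-subject maps: paired t maps thresholded at the t-distribution's
  2.5th/97.5th quantiles, clusters by spatio-temporal(-spectral)
  adjacency, max-|sum| null distribution from per-subject condition
  swaps, Monte-Carlo p-values `(1 + hits) / (1 + B)` with exact
  enumeration when feasible, and trial-count equalization.
* **Synthesis** — `simulate_dataset` builds multi-subject epoch sets
  from spatially correlated 1/f noise with planted components (early
  negativity, late positivity, slow-band enhancement, alpha/beta
  desynchronization) whose defaults mirror the study's reported effect
  pattern; `simulate_observer_session` ties the stimulus schedule to
  the behavioral classifier with known labels.

See `vignettes/methods.Rmd` for the models, parameter defaults and the
reasoning behind every open design choice.

## A worked example

```r
library(illusioneeg)

## the wavelet bank and its closed-form widths
wavelet_bank()
#> <wavelet_bank> 1-45 Hz in 0.2 Hz steps (221 wavelets), 3-10 cycles, FDHM 1124-83 ms

## titrate a simulated listener (true 70.7% point at -11.1 dB)
obs <- logistic_observer(midpoint = -12, slope = 1)
thr <- mean(sapply(1:20, function(i)
  as.numeric(run_staircase(obs, start_level = -6, seed = i))))
sprintf("mean threshold %.2f dB -> detection probability %.3f",
        thr, obs$psychometric(thr))
#> "mean threshold -10.96 dB -> detection probability 0.738"

## simulate 12 subjects and test hits vs false alarms (response-aligned)
gt <- default_ground_truth()
chans <- c("Fz","FCz","Cz","CPz","Pz","POz","CP1","CP2","P1","P2","C3","C4")
ds <- simulate_dataset(gt, n_subjects = 12, seed = 7,
                       n_trials = c(hit = 80, fa = 50), rate = 100,
                       window_resp = c(1.5, 0.5), stim_aligned = FALSE,
                       channels = chans)

ers <- lapply(ds, function(s)
  baseline_correct(average_erp(s$hit_resp), c(-1.4, -1.2)))
gm <- ers[[1]]
gm$mean <- apply(simplify2array(lapply(ers, `[[`, "mean")), c(1, 2), mean)
component_peak(gm, "Pz", c(-0.25, 0.25), "positive")
#> grand-average late positivity at Pz: 7.78 uV at -30 ms
#> (the generator plants +7.5 uV at -25 ms)

pos <- montage_1010()
adj <- build_adjacency(pos[pos$label %in% chans, ], 0.4)
maps_a <- list(); maps_b <- list()
for (s in seq_along(ds)) {
  eq <- equalize_trials(ds[[s]]$hit_resp, ds[[s]]$fa, seed = s)
  maps_a[[s]] <- baseline_correct(average_erp(eq$a), c(-1.4, -1.2))$mean
  maps_b[[s]] <- baseline_correct(average_erp(eq$b), c(-1.4, -1.2))$mean
}
permutation_test(maps_a, maps_b, adj, n_permutations = 500, seed = 1)
#> <cluster_result> 12 subjects, 500 permutations, t_crit 2.201
#>   cluster 1: sign +1, 82 samples, sum t = 260.28, p = 0.01597 *
#>   cluster 2: sign +1, 34 samples, sum t = 105.86, p = 0.09182
#>   cluster 3: sign +1, 17 samples, sum t = 58.98, p = 0.2076
#>   ...
```

The significant positive cluster around the response is the planted
hit-minus-false-alarm late-positivity difference (7.5 vs 4.2 µV at the
centro-parietal electrodes); its Monte-Carlo p-value is the fraction of
per-subject condition swaps whose maximum absolute cluster sum reaches
the observed one.

`run_pipeline(default_config())` chains all stages — simulate, classify,
screen, average, contrast — and writes trial counts, component peaks
and cluster results to TSV/JSON.

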