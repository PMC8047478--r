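---
title: "Models and methods behind illusioneeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind illusioneeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(illusioneeg)
```

`illusioneeg` implements the analysis chain of a continuous-design
auditory signal-detection EEG experiment in which listeners report
barely audible speech snippets embedded in speech-shaped masking noise,
and sometimes report speech that was never presented — experimentally
induced auditory illusions. This vignette explains the models, the
tunable parameters, the synthetic-data generator that stands in for the
(non-deposited) participant recordings, and the numerical and design
choices that were genuinely open.

## The experimental model

A session is a continuous noise stream with speech snippets inserted at
pseudo-random inter-stimulus intervals (ISIs). In the default
configuration three 10-minute blocks are each tiled by twelve 50 s
sub-blocks that share one onset pattern of five stimuli with ISIs
between 3 and 19 s, short at the start of a sub-block and long at its
end (180 onsets in total). The repeating short-to-long pattern
manipulates the listener's expectation of hearing a voice, which is
what elicits false alarms. `build_isi_schedule()` draws the pattern
once per session (seeded): five gaps uniform on [3, 19] s are rescaled
by rejection until they sum to 50 s, sorted ascending, and the smallest
gap doubles as the boundary gap between sub-blocks, which keeps every
ISI — including across sub-block boundaries — inside the range.

Stimulus levels are titrated per subject in two stages:

* `estimate_ihl()` brackets the individual hearing level with 2 dB
  descending/ascending tracks around a 10 dB drop, repeated three
  times; all six report levels are pooled into the mean (a literal
  reading of the procedure — both "not hearing anymore" and "hearing
  again" reports enter the average).
* `run_staircase()` is a transformed 1-up/2-down staircase: the level
  steps down after two consecutive detections and up after every miss,
  so it converges where the probability of two consecutive detections
  is 1/2, i.e. a detection probability of sqrt(0.5) = 70.7%. The step
  starts at 1 dB, halves to 0.5 dB after the fourth reversal, the run
  stops at the ninth reversal, and the threshold is the mean level of
  the last five reversals. The two-down counter resets whenever the
  level changes (standard transformed up-down bookkeeping). The
  starting level defaults to the threshold region + 6 dB and a
  200-trial guard aborts a non-converging run — the source procedure
  states neither, and neither affects the converged estimate.

The main session presents each snippet at the threshold ± 1.5 dB
(uniform); the button-press control presents 60 clearly audible
snippets (+5 to 6 dB) at 10 ± 1 s intervals. Speech-shaped noise
(`make_ssn()`) is built by averaging the magnitude spectra of the
snippet ensemble (zero-padded to a common length), drawing fresh
uniform phases per segment with Hermitian symmetry, and inverting to
the time domain; averaging the ensemble spectra is one reading of
"the Fourier transform of all the snippets" and matches the stated
purpose of maximal spectral overlap with speech.

## Trial categorization in a continuous design

There are no trial bins, so responses and stimuli are categorized by
timing rules (defaults in `classification_params()`):

* hit — a response 300–1800 ms after a stimulus onset (first response
  wins; a response eligible for two stimuli goes to the closer one);
* miss — no response within 3600 ms of an onset;
* false alarm — a response with no onset in the preceding 3600 ms;
* everything between the hit window and the horizons is an intentional
  margin and stays unlabeled;
* correct rejections are event-free stretches, tiled greedily on a
  10 ms grid by `extract_cr_anchors()` with a guard (default 1 s beyond
  the epoch half-width) so no stimulus or response bleeds into a CR
  epoch. The source design leaves CR placement ambiguous; greedy tiling
  of the clean remainder is our reading, and the guard is configurable.

The 42 ms response-time histogram with a 420 ms Gaussian-weighted
moving average (`smoothed_rt_histogram()`) is the diagnostic that
motivated the 300–1800 ms window; it is normalized to a probability
density by its trapezoidal integral. The smoothing kernel length is
rounded up to an odd number of bins so the moving average is symmetric.

## Preprocessing

All filters are one-pass zero-phase Hamming windowed-sinc FIR designs
(`design_windowed_sinc()`): an ideal sinc truncated to `order + 1`
taps, Hamming-tapered, normalized to exactly unit DC gain; highpass by
spectral inversion, which makes the DC null exact. When only a
transition width is given the order follows the Hamming rule
`3.3 * rate / transition`, which reproduces the study's printed orders
(0.3 Hz HP/0.6 Hz/order 1100; 45 Hz LP/8 Hz/84; 30 Hz LP/7.5 Hz/88 at
200 Hz). A single forward convolution is compensated by the integer
group delay `order/2`, so an impulse stays at its sample
(`filter_zero_phase()`). Downsampling (1000 → 200 Hz) applies an
anti-alias lowpass at 0.8 × the target Nyquist before decimating; the
source chain does not name an anti-alias step, but broadband synthetic
noise would alias without one.

Epochs take −4.6 to +1.9 s around responses and −2.8 to +3.7 s around
stimulus onsets, both endpoints included on the sample grid with the
anchor at t = 0 (at 200 Hz a response-aligned epoch is 1301 samples).
Trials whose maximum peak-to-peak amplitude across channels exceeds
300 µV are dropped — strictly "higher than", so a trial at exactly the
threshold survives. A 400 µV screen with the frontal row excluded
(`frontal_channels()`) is available for the stage preceding artifact
decomposition; the excluded set is configurable because none is
printed. The independent-component artifact-removal stage itself
involves visual inspection and is out of scope; `apply_artifact_hook()`
accepts any recording-to-recording cleaner and defaults to the
identity.

## ERP analysis

`average_erp()` returns the trial mean and SEM; `baseline_correct()`
subtracts per-channel baseline means (−200 to 0 ms for stimulus-aligned,
−3.1 to −2.9 s for response-aligned ERPs). A figure caption elsewhere
suggests −1.3 to −1.1 s for the stimulus-aligned baseline; both windows
are plain configuration values, the methods-text values are the
defaults, and no intent is guessed. Component peaks are raw sample
extrema inside the printed windows (stimulus-aligned: positivity
400–1300 ms, negativity 100–600 ms; response-aligned: −250 to 250 ms
and −900 to −100 ms), ties breaking to the earliest sample —
deterministic and order-independent, with no sub-sample interpolation.
Topographies are per-channel time averages over an interval, and
`spatial_correlation()` is the Pearson correlation of two topographies
across channels.

The bundled montage (`montage_1010()`) is a schematic 64-channel 10-10
layout: rows and columns on an angular grid of 15° per grid unit
projected on the unit sphere. It is deliberately a schematic head — it
feeds neighbor construction and topography templates, not source
analysis; at the default 0.4 neighbor threshold it yields a connected
graph with about six neighbors per channel, the typical density for
such caps.

## Time–frequency analysis

Complex Morlet wavelets `exp(i 2 pi f t) * exp(-t^2 / (2 sigma_t^2))`
with `sigma_t = n / (2 pi f)` and cycle counts rising linearly from 3
at 1 Hz to 10 at 45 Hz give the closed-form widths

* temporal FDHM `n sqrt(2 ln 2) / (pi f)`: 1124 ms at 1 Hz to 83 ms at
  45 Hz,
* spectral FWHM `2 sqrt(2 ln 2) f / n`: 0.78 Hz to 10.60 Hz,

whose product is the Gaussian time-bandwidth constant `4 ln 2 / pi`.
Wavelets are truncated at ±4 sigma_t and scaled to unit energy so power
is comparable across frequencies (the source is silent on
normalization). The transform evaluates wavelets directly on the
0.2 Hz / 10 ms output grid rather than interpolating a coarser
spectrum — same grid, no interpolation artifacts. Samples within half a
wavelet length of an epoch edge are flagged invalid per frequency and
excluded from every downstream statistic.

The ERSP is the trial average of squared coefficient magnitudes.
The narrative phrase "absolute values … averaged" conflicts with the
cited ERSP definition and with every downstream use of "power"; power
is therefore the default and magnitude is available via
`ersp(..., measure = "magnitude")`. Relative baseline normalization
`(P - B(f)) / B(f)` uses a per-frequency baseline window that must end
at least one FDHM before the activation start, because the FDHM bounds
the temporal smearing of power; a frequency whose margin cannot be
honored raises an error naming it. Band traces average frequency bins
(slow cortical potentials 1–4 Hz, alpha 8–12 Hz, beta 15–25 Hz).

## Cluster-based permutation statistics

Paired designs — condition A vs condition B, or activation samples vs
the subject's time-averaged baseline (`actvsbl_subject_maps()`) — are
tested with the nonparametric cluster permutation scheme: the paired t
map (N − 1 df) is thresholded at the 2.5th/97.5th quantiles *of the t
distribution* (sample quantiles of the map itself would select 5% of
samples even under the null, which cannot be what a threshold is for);
supra-threshold samples cluster by spatial adjacency (channel graph),
temporal adjacency, and spectral adjacency for time–frequency maps,
positive and negative separately, singletons allowed. The observed
statistic is each cluster's summed t; the null is the distribution of
the maximum absolute cluster sum under per-subject condition swaps
(equivalently sign flips of subject difference maps — "independently
for each participant"), and every observed cluster is compared to that
same max-statistic null, which is what controls the family-wise error.
Monte-Carlo p-values use `(1 + #(null >= obs)) / (1 + B)` so they are
never zero; when `2^N <= B` all sign assignments are enumerated and the
p-value is exact. The tie comparison carries a relative tolerance of
1e-9 because the observed and permuted statistics travel different
floating-point paths and the identity permutation must always count.
Permutation happens on the paired subject maps, i.e. after baseline
time-averaging — the standard reading. Before a paired contrast the
larger condition is subsampled without replacement to the smaller one's
trial count (`equalize_trials()`, seeded).

## The synthetic generator

Because the participant recordings are not publicly deposited, every
end-to-end property is demonstrated on synthetic data with known ground
truth. The generator emulates:

* spatially correlated 1/f background noise (`pink_noise()`): spectra
  drawn directly in the frequency domain, one shared source mixed into
  all channels (shared variance fraction 0.3) plus independent
  per-channel sources, each channel scaled to the trial noise SD;
* an early centro-parietal negativity (EN) and a late centro-parietal
  positivity (LP) as Gaussian-windowed deflections weighted by a
  raised-cosine topography centered on Pz/CPz;
* a slow (1–4 Hz) power enhancement and alpha/beta desynchronizations
  over C3/C4 as multiplicative band-power modulations: the band-limited
  noise component is scaled by `sqrt(1 + change)` under a smooth
  plateau envelope, so the planted *power* change equals the nominal
  relative change; the spectral edges of the modulation roll off over
  0.5 Hz raised-cosine shoulders, because physiological band
  modulations are not brick-wall and hard edges would bias wavelet
  band-power estimates low at the band boundaries;
* a simulated observer (`simulate_observer_session()`) producing hits,
  misses and spontaneous false alarms under the session's ISI schedule,
  with truncated log-normal response times on [0.3, 1.8] s.

Default effect parameters take the reported group values where printed:
hits carry EN −2.7 µV at −250 ms and LP +7.5 µV at −25 ms
(response-aligned), a +50% slow-band enhancement, and −40%/−30%
alpha/beta desynchronizations; false alarms carry the same pattern with
the LP and slow-band effects scaled by 4.2/7.5 = 0.56 (the reported FA
positivity is 4.2 µV at −15 ms) and EN at −415 ms; misses and correct
rejections are background only; button presses carry only the motor
desynchronizations. Stimulus-aligned hit epochs shift every component
by a per-trial response time, which reproduces the smeared,
lower-amplitude stimulus-aligned positivity that results from
response-time variability.

Two generator parameters are not printed anywhere and were fixed once
by design:

* **Component widths** (EN SD 0.12 s, LP SD 0.08 s). The widths must
  make the generator self-consistent: with a broad LP its left tail
  lifts the EN trough and the noiseless compound waveform's minimum
  moves tens of milliseconds away from the nominal EN latency — the
  declared ground truth would not be the extremum of the generator's
  own mean waveform. A sharp LP is also the only configuration
  consistent with a −2.7 µV trough at −250 ms coexisting with a
  +7.5 µV peak at −25 ms. Recovery tests compare against the extremum
  of `ground_truth_waveform()`, the noiseless compound mean — the exact
  quantity ERP averaging estimates.
* **Trial noise SD** (14 µV). The generator's defaults are required by
  design to make the planted condition differences detectable by the
  cluster tests at the study's sample size (16 subjects, ~100/67
  trials); pilot replicates put the hit-vs-FA detection rate near 40%
  at 20 µV and at ceiling at 14 µV, which is also a realistic SD for
  band-limited scalp EEG. The ERP parameter-recovery check keeps its
  own harsher 20 µV noise, which is stated explicitly for that check.

What the generator does **not** emulate: ocular and cardiac artifacts
(the artifact-decomposition stage is out of scope), electrode drift and
impedance changes, realistic volume-conduction mixing beyond the single
shared noise source, latency/amplitude correlations across subjects,
and any non-stationarity of the background across a session. Passing
recovery tests therefore demonstrate that the analysis chain is
faithful to its own model of the data, not that it would be robust to
every artifact structure of real recordings.

## Problem sizes in the test suite

The validation suite chooses sizes that keep each property measurable
at desk scale: the staircase convergence check uses 1000 runs; the
family-wise error calibration uses 200 null datasets of 16 subjects
with 2 channels × 40 activation bins and 500 permutations per test;
ERP recovery uses three replicate 16-subject datasets of 100 trials at
200 Hz on a 9-channel centro-parietal subset (median across replicates,
since a single peak-picking experiment at the stated noise level has
meaningful wander); band-power recovery uses 300 trials on the two
full-weight channels; the hit-vs-FA detection-rate check uses 50
datasets of 16 subjects on a 16-channel subset at 100 Hz with short
response-aligned epochs. Spatial resolution and epoch length affect
compute, not the tested effects, and the reduced grids keep the whole
suite within a desktop run.

## Known limitations

* The BrainVision reader covers the common core format (binary float32
  / int16 and ASCII, multiplexed or vectorized); EDF ingest is not
  implemented.
* Epoch containers serialize to TSV + JSON text; large datasets are
  better regenerated from seeds than stored.
* The montage is schematic; users with digitized positions should pass
  their own data frame to `build_adjacency()` and
  `topography_template()`.
* `run_pipeline()` orchestrates the synthetic end-to-end analysis; for
  real recordings the stage functions are called individually (read,
  filter, classify, epoch, reject, average, transform, test).
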