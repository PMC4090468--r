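---
title: "Dynamic-update seizure prediction: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic-update seizure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(seizpred)
```

## The problem and the model

Epileptic seizures are preceded, in many patients, by a gradual increase in
the phase synchronization of intracranial EEG channels. `seizpred` turns
this into an online, per-patient alarm system in four stages.

**1. Phase extraction (HHT).** Each 10-s window of each channel is
decomposed by empirical mode decomposition into at most 3 intrinsic mode
functions (IMFs): locally narrowband components obtained by iteratively
subtracting the mean of the cubic-spline envelopes through the local maxima
and minima. The Hilbert transform of each IMF gives a well-defined
instantaneous phase. Unlike a bandpass–Hilbert pipeline, EMD adapts its
bands to the data, which matters for nonstationary EEG.

**2. Phase-interaction features (ELM regression).** The per-window phase
matrix (samples × `d·3` columns) is regressed one sample ahead by an
extreme learning machine with 10 hidden sigmoid neurons. The hidden layer is
random and *fixed for the entire run*; only the output weights **B** are
solved, in closed form, by Moore–Penrose pseudo-inverse. The flattened
**B** (length `10 · d · 3`, 180 for 6 channels) is the feature vector.
Sharing one hidden layer across windows is essential: output weights from
different random bases would not be comparable, and the feature space would
be meaningless. For the same reason features are deterministic given the
run seed.

**3. Classification and alarms.** A second ELM (1000 hidden neurons, ridge
`1e-6` for conditioning) is trained on the two sample pools (preictal
target 1, interictal target 0) and thresholded at 0.5. Raw decisions
chatter, so the preictal density over a trailing 1.5-min observation window
(17 overlapping windows) is compared against `gamma = 0.7`; the alarm rule
is strictly `Den > gamma`, and a new alarm cannot be raised while one is
pending (refractoriness prevents alarm floods during a long preictal
episode).

**4. Dynamic update.** The pools have fixed capacities (`N1`, `N2`). When
an alarm's 110-min horizon lapses without a seizure, the 17
observation-window feature vectors form `S_obs`; if they are *normal* —
strictly farther (in mean Mahalanobis point distance) from the preictal pool
than `lambda` times their distance from the interictal pool — they are
pooled with the interictal samples, all candidates are sorted by distance to
the *opposite* (preictal) pool, and the first `N2` are retained. A missed
seizure symmetrically refreshes the preictal pool from the windows 30–40 min
before onset. After an update, the classifier output weights are refit with
the same fixed hidden layer.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| window length / overlap | 10 / 50% | s / – | feature windows (2560 samples at 256 Hz) |
| `max_imf` | 3 | – | IMFs per channel kept for phases |
| feature ELM `L` | 10 | neurons | one-step phase regressor |
| classifier ELM `L` | 1000 | neurons | preictal/interictal decision |
| `win_os` | 1.5 | min | density observation window |
| `gamma` | 0.7 | – | alarm threshold on the preictal density |
| `H_time` | 110 | min | prediction horizon |
| `lambda` | 1 | – | abnormality multiplier |
| pre-onset span | 30–40 | min | Condition-B harvest before a missed onset |
| `postictal` | 10 | min | skip after each seizure offset (unquantified in the source design; configurable) |

Pool construction mirrors the evaluation design: 37.6 min preceding each of
the first two seizures at 10 s / 50% overlap (450 windows each) and 150 min
of interictal recording at 10 s without overlap (900 windows).

## Numerical choices

* **Sifting stop.** A sift ends when the relative envelope-mean energy
  `SD = sum(m^2)/sum(d^2)` falls below 0.25 *and* the IMF criteria hold
  (|#maxima − #minima| ≤ 1; zero crossings within 1 of the extrema count),
  capped at 100 passes. The SD bound alone stops after 1–2 passes on noisy
  EEG and leaves strong riding waves; the criteria-conjunction is the
  tightest rule that terminates reliably.
* **Envelope boundaries.** Two extrema are mirror-reflected about each end
  of the window before the natural cubic spline is fit, suppressing end
  swings that would otherwise contaminate short windows.
* **Phases** are wrapped to `(-pi, pi]` (the `-pi` branch value of `atan2`
  is mapped to `+pi`); unwrapping is used only to compute instantaneous
  frequency. Phases are fed to the regressor raw — no sin/cos embedding —
  so the features stay in the space the one-step model defines.
* **Pseudo-inverse.** SVD with relative cutoff `1e-12` for the feature ELM;
  ridge `1e-6` normal equations for the 1000-neuron classifier, where the
  SVD of a 1800×1000 matrix would be wasteful and the ridge stabilizes a
  near-rank-deficient hidden matrix.
* **Covariance regularization.** Pool covariances (sample, `n−1`) are
  inverted after adding `eps = 1e-6 · trace/dim` to the diagonal; an
  all-identical pool (zero trace) falls back to the pseudo-inverse, giving
  distance 0 to the common point rather than an error.
* **Distances.** The square root of the quadratic form is reported so the
  quantity is a metric; every comparison and sort in the update rules is
  monotone in either convention.
* **Sort direction.** Keeping the candidates *closest* to the opposite pool
  (ascending) retains boundary-informative samples, in the spirit of
  replacing the sample farthest from the support vectors; the direction is a
  configuration switch (`sort_order`) because the convention is genuinely
  open, and the enumerated small-case tests cover both.
* **Ties** in the retention sort are broken by sample age (older first) so
  updates are deterministic.
* **Degenerate inputs.** Constant channels yield zero IMFs and zero phase
  columns (zero-padding keeps the feature length fixed); a constant series
  is "monotonic-like" for the sifter; an all-zero window produces the zero
  feature vector exactly.
* **End-of-stream alarms.** An alarm whose horizon extends past the end of
  the recording is closed as a false alarm for counting purposes but does
  *not* trigger a Condition-A update — the observation is censored, and
  updating on it would inject unverified samples.

## What the synthetic generator emulates

Each channel is a narrowband phase oscillator (6–12 Hz, amplitude 50 µV)
pulled toward a common reference oscillator by a coupling gain
`kappa(t) = coupling × 2π × 5 Hz` rad/s, plus a weaker secondary oscillator
at 2.3× the base frequency, 50 Hz line contamination (10 µV) and white
noise (5 µV). Baseline coupling 0.05 leaves the channels effectively
unsynchronized (the pull is far below the 0–3 Hz detunings); over the 30-min
preictal ramp the coupling rises linearly to 0.8, whose pull exceeds every
detuning, so the channels phase-lock — mean pairwise phase-locking value
rises from ≈0.01 to ≈0.87. Ictal periods emit a common 4 Hz rhythm at 4×
amplitude. `drift_rate` shifts all oscillator frequencies linearly in time
(Hz per hour), emulating slowly changing interictal spectral content.

The generator does **not** emulate artifacts, electrode noise, true neural
mass dynamics, patient heterogeneity, or preictal signatures other than
phase synchronization. Passing tests therefore show that the pipeline
detects a synchronization ramp embedded in realistic noise and adapts to
spectral drift — not that it predicts clinical seizures.

## Scenario sizes used by the test suite

* *End-to-end*: per seed, five single-seizure recordings (onset at 40 min,
  45-min interictal tail) plus a 155-min interictal recording at 256 Hz and
  6 channels (~10 h simulated). Seizures 1–2 build the pools, 3–5 are
  streamed; sensitivity and false-positive rate are averaged over 5 seeds.
  The 45-min tails exist so the false-positive denominator (~1.75
  interictal hours per seed, after excluding 50 min preictal, ictal and
  postictal spans) is meaningful.
* *Drift comparison*: pools trained on stationary 128 Hz data; ten
  100-min interictal streams with `drift_rate = 10` Hz/h are processed with
  updates on and off from identical initial pools. The horizon is shortened
  to 5 min in this scenario so false alarms lapse — and Condition A can
  retrain — well inside the stream; with the 110-min horizon a lapse would
  fall beyond the recording and the comparison would be vacuous.

## Known limitations

* The Condition-B resume point (`ictal end + postictal + H_time`) suspends
  observation for ~2 h after a missed seizure; seizures clustered more
  tightly than that are not evaluated.
* Set-to-pool distance is defined as the mean of point distances; other
  conventions (e.g. distance between means) would change `lambda`'s
  effective scale.
* Interictal hours exclude a fixed 50-min preictal span per seizure plus
  ictal and postictal skips; with very short recordings the denominator can
  vanish, in which case the evaluation refuses to report a rate.
* The EDF reader handles continuous files with one sampling rate across
  signals (the layout of digitized intracranial EEG); EDF+ annotations,
  discontinuous files and mixed-rate signals are out of scope — seizure
  annotations travel in the sidecar CSV.
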