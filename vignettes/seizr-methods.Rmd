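---
title: "Methods: seizure detection and typing from scalp EEG with seizr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seizure detection and typing from scalp EEG with seizr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

seizr implements a complete pipeline for detecting epileptic seizures in
multichannel scalp EEG and classifying them into the eight clinical types
annotated in seizure corpora (`fnsz`, `gnsz`, `spsz`, `cpsz`, `absz`,
`tnsz`, `tcsz`, `mysz`), together with the acquisition-setting experiments
(sampling-rate sweep, electrode-count ablation) and an interpretability
layer (mutual-information electrode ranking, activation maximization,
dSPM source reconstruction). Clinical seizure corpora are
access-restricted, so the package ships a synthetic cohort generator that
emulates their structure; every stage of the pipeline is exercised on it
by the test suite.

## The processing chain

A recording is an ordered channels-by-samples matrix in microvolts on the
21-electrode 10/20 montage (including the A1/A2 ear references), with
interval annotations in a TSE-style text dialect (`start stop label
confidence`, half-open seconds). Preprocessing applies, in order:

1. **Zero-phase FIR low-pass at 40 Hz.** A Hamming-window FIR of order
   `4 * rate / cutoff` (rounded odd, DC gain normalized to exactly 1),
   applied forward-backward so no group delay shifts the annotations.
2. **Polyphase resampling** to the working rate (250 Hz by default; the
   sweep experiment revisits 50–250 Hz in 50 Hz steps).
3. **Non-overlapping 1-second windows**, labeled by majority overlap with
   the annotations. Ties go to the seizure label: at a boundary a window
   half-covered by a seizure counts as seizure, which favors sensitivity.
   Annotation boundaries are the only place the rule matters, and the
   choice is ours — corpora only annotate intervals.
4. **64-point short-time Fourier tensor.** Each window is cut into 8
   equal non-overlapping segments (31 samples at 250 Hz), Hann-tapered,
   zero-padded (or truncated) to 64 points, and reduced to the one-sided
   magnitude spectrum. The result is the channels × 33 frequencies × 8
   timesteps tensor both models consume. This segmentation keeps the
   8-timestep axis identical at every sampling rate in the sweep, which
   is why it was chosen over hop-based conventions. A caveat it implies:
   at 250 Hz a segment is 124 ms, so rhythms below ~8 Hz complete less
   than one cycle per segment and their spectral peak can shift by one
   3.9 Hz bin depending on phase. The tests assert exact bin recovery
   only for tones with at least one cycle per segment.

Magnitude (not power, not log) spectra are used; inputs are then
standardized inside the model (below).

## Models

Both classifiers consume the same tensor, so they compose into a single
pipeline: every window passes the binary detector, and only windows
flagged as seizure reach the type classifier.

The **binary detector** treats the electrodes as input channels and the
33 × 8 frequency-time plane as the 2-D image: three 3×3 convolutions of
16, 32 and 64 feature maps (padding 1), each followed by ReLU, 2×2 max
pooling and batch normalization, then dense layers of 256 and 2 units
with softmax. The plane contracts 33×8 → 16×4 → 8×2 → 4×1, so the
flattened width is exactly 64·4·1 = 256.

The **type classifier** treats the 8 timesteps as a sequence whose frames
are single-feature electrode × frequency maps: two modules of a
convolutional LSTM (16 then 32 filters, 3×3, same padding; the first
returns the full sequence, the second its final state), each followed by
batch normalization, per-step 2×2 pooling and dropout (0.3), then dense
layers of 256 and 8 units.

Training minimizes class-weighted cross-entropy (`w_c = N / (K n_c)`, so
that `sum_c w_c n_c = N`) with Adam at learning rate 1e-3, batch 32.
Learning rate, batch size, dropout and the ConvLSTM filter counts are
conventional defaults and configurable. The forward/backward passes are
implemented in the package itself (im2col-free 3×3 convolution kernels in
C++ calling BLAS, ConvLSTM backpropagation through time in R); every
layer's gradient is verified against numerical differentiation in the
development checks, and training is deterministic given the seed on a
single thread.

**Input standardization.** Raw magnitude tensors span four orders of
magnitude across frequency bins (tens of microvolts at 3 Hz, nearly zero
above the 40 Hz cutoff). Each model therefore standardizes its input per
tensor element with training-set means and standard deviations (the sd
floored at 1% of its mean so empty bins cannot blow up). This both
conditions training and anchors activation maximization: gradient ascent
then measures deviations in data standard deviations, so prototypes
cannot drift into spectral regions no real input occupies — without this,
ascent reliably exploited the never-constrained high-frequency bins.

## Synthetic cohorts: what they emulate and what they do not

The generator writes per-subject EDF recordings (16-bit) with TSE
annotations and a JSON manifest. Background EEG is per-channel pink
(1/f) noise at 15 µV RMS plus a 10 Hz alpha rhythm whose gain decays with
scalp distance from the occipital pole (20 µV RMS at O1/O2). Seizures
are synthetic waveforms with unit-RMS envelopes, scaled by a per-electrode
spatial gain profile and an RMS amplitude:

| label | waveform | frequency | amplitude | topography |
|-------|----------|-----------|-----------|------------|
| absz | spike-wave harmonic stack | 3 Hz | 90 µV | generalized, Fz/Pz emphasis |
| gnsz | rhythmic sine | 2–5 Hz | 70 µV | generalized, flat |
| tcsz | chirp 10→3 Hz | — | 110 µV | generalized, flat |
| mysz | polyspike bursts (0.4 s) | 18 Hz | 80 µV | generalized, flat |
| tnsz | low-voltage fast | 15–25 Hz | 35 µV | generalized, fronto-central |
| fnsz | rhythmic sine | 4–8 Hz | 60 µV | focal, focus T3 |
| spsz | rhythmic sine | 6–9 Hz | 55 µV | focal, focus T4 |
| cpsz | rhythmic sine | 4–7 Hz | 55 µV | focal, focus T5 |

Classes with a frequency band draw each injected seizure's frequency
uniformly from it. The three focal bands overlap on purpose: within the
overlap only the spatial profile separates the classes, so seizure typing
genuinely requires scalp coverage, and two of the three foci (T4, T5)
lie off the reduced 8-electrode montage — this is what makes the
electrode-count contrast meaningful rather than a side effect of
distinct carrier frequencies.

Focal profiles decay as a Gaussian of geodesic scalp distance from the
focus (width 0.40 rad, so a focus projects under a third of its
amplitude to electrodes one ring away); generalized profiles stay at or above 0.7
everywhere. Frequencies and topographies follow the physiological
descriptions that motivate the interpretability outputs (absence
discharges over paramedial fronto-parietal midline, tonic activity over
fronto-central cortex, partial seizures over temporal foci), so
topoplots and source maps are meaningful. The default class mix is
imbalanced with focal and generalized non-specific seizures most
frequent, so class weighting is actually exercised; the exact proportions
are our choice since no quantitative mix is published.

Class separability is certified, not assumed: a matched-filter oracle
that knows the generative model (expected channel × frequency power
patterns across each class's band and envelope position, with reduced
onset/offset-ramp variants, the background spectrum regressed out)
reaches at least 95%
eight-class accuracy on generated seizure windows, so the learning task
given to the networks is solvable. The oracle also serves as an
independent check on trained models.

What the generator does **not** emulate: biophysical head-model
propagation (scalp mixing is a static gain profile), artifacts (EMG,
blink, electrode pops), inter-subject spectral variability, and the
annotation noise of clinical corpora. Passing tests therefore demonstrate
that the pipeline's machinery is correct and can recover planted
structure — not that the reported clinical performance transfers.

## Electrode importance and ablation

Electrode informativeness is the mutual information between an
electrode's raw time-domain sample value and the window label, estimated
with an equal-frequency 8-bin histogram at each time index, averaged over
time indices, over draws of windows, and over repeated runs. Quantile
binning makes the score invariant to per-electrode affine rescaling. The
estimator is checked against an analytic value (a planted two-valued
dependence with MI = ln 2, recovered within 10%), against permutation
nulls, and against a planted-offset construction that must rank the
planted electrode first in 100 of 100 seeds. "Runs" resample windows;
the reference estimator settings are 1000 windows and 100 runs.

The ablation experiment retrains the binary detector while greedily
removing the electrode with the minimum MI score, from 21 down to 8
electrodes; the fixed comparison contrasts the full montage with the
standard reduced set {F7, T3, C3, Cz, Fp2, F8, O2, P4} under
event-grouped, stratified 5-fold cross-validation, comparing per-fold
metrics with Welch's t-test and the Mann-Whitney U test, with the
D'Agostino-Pearson omnibus test describing the metric distributions (it
needs n ≥ 8, so with 5 folds it is reported as NA with a warning; the
implementation is verified to 10 decimals against an independent
reference on larger samples). On focal-heavy synthetic cohorts the type
classifier loses macro recall when restricted to 8 electrodes — the T4
and T5 foci of `spsz` and `cpsz` have no sensor in the reduced set —
mirroring the
clinical observation that typing needs scalp coverage while detection
does not.

## Data splits

All splits are grouped by annotation event: every window of one seizure
(or background stretch) lands in the same partition, which is a stronger
leakage guarantee than window non-overlap alone. Stratification is by
label with largest-remainder quotas; remainder ties go to the split
furthest below its global target, so exact fractions are honored when
they divide evenly. The k-fold splitter deals each class's events
round-robin with a per-class offset so fold sizes balance.

## Activation maximization

For a target class, AM ascends the pre-softmax logit (softmax saturates
gradients) minus an L2 penalty (1e-3), starting from small Gaussian noise
in standardized units, with a fixed step (0.1) halved up to 10 times
whenever a step fails to improve the objective — so the accepted
objective sequence is non-decreasing by construction. The published
procedure conflates "iterations" and "runs"; we fix the reading as 100
independent restarts of a 256-step ascent, averaged. On cohort-trained
models the per-class prototypes concentrate in the generator's frequency
bands (at the 3.9 Hz resolution of the spectral grid) for at least six of
the eight classes — burst and chirp classes legitimately straddle — and
the absence-seizure prototype peaks on the Fz/Pz midline emphasis.
Per-electrode energies of a prototype are rendered as topographic maps:
azimuthal-equidistant projection, Gaussian radial-basis interpolation on
a 64×64 disc, masked outside the head circle.

## dSPM source reconstruction

The inverse machinery is exact dSPM: noise covariance from the 100 ms
pre-onset baseline (sample covariance plus 5% diagonal loading, which
guarantees positive definiteness; the quoted "200 ms after" the onset is
used only for baseline mean subtraction, since mixing ictal data into a
noise estimate would be unconventional), whitening of data and leadfield,
the regularized minimum-norm operator `M = Lw'(Lw Lw' + λ²I)⁻¹` with
`λ² = 1/snr²` (snr 3 by default), and per-source normalization by the
noise-projected standard deviation. Source activity at seizure onset is
averaged over the first two seconds; a lateralization index
`(ΣL − ΣR)/(ΣL + ΣR)` over hemisphere sums and a concentration score
(activation share of the top 10% of sources) summarize focal versus
generalized patterns.

The anatomical forward model is deliberately a toy: 64 sources on a
Fibonacci lattice over the spherical cap (radius 0.9, z ≥ 0.25 — the
montage has almost no sensors below its circumferential ring) with
Gaussian distance-decay gains (σ = 0.95) and unit-norm columns. An
MRI-template boundary-element solution would add anatomy but make the
inverse computation unverifiable; with the toy model the resolution of
the operator is checked by brute force — every planted source is
recovered exactly (argmax over the grid) from noiseless data at snr 100,
and within one grid-neighbor spacing at the snr 3 default. σ was chosen
on the plateau where exact recovery holds; note the smooth Gaussian
leadfield is numerically rank-deficient, so the regularization must stay
at or above that cutoff (λ² ≈ 1e-4) — both weaker and stronger
regularization lose exact recovery, which is a property of minimum-norm
resolution, not of the implementation.

## Reference problem sizes

The package's desk-scale reference conditions, used by the test suite and
the reproduction script: a 10-subject cohort of 180 s records at 250 Hz
with 6 seizures of 6–10 s per record for general use; a 6-subject cohort
for parameter recovery (binary detector trained 10 epochs, type classifier
12 epochs, event-grouped 70/15/15 splits); a 5-subject focal-heavy cohort
(2-fold cross-validation, 14 epochs so both montages train close to
convergence) for the electrode-count contrast; 50
planted-electrode seeds for the MI oracle. Reference training lengths of
20 epochs (binary) and 50 (multigroup) remain the configuration defaults
in `experiment_config()`. Under these conditions the binary detector
reaches held-out sensitivity and specificity above 0.9 and the type
classifier macro recall above 0.85, the thresholds the test suite
asserts; these certify the pipeline's learnability contract on synthetic
data, not clinical performance.

## Known limitations

* The synthetic cohort's simplifications listed above; in particular
  amplitude is a class cue for the oracle (chirp vs sine at the same
  instantaneous frequency), which a clinical cohort would not provide so
  cleanly.
* The STFT's 31-sample segments cannot resolve sub-8 Hz rhythms to a
  single bin per timestep (the tensor shape contract forces this).
* The networks are trained on a single thread for determinism; the
  engine is vectorized but deliberately dependency-free, so wall-clock
  cost grows quickly beyond desk-scale cohorts.
* EDF support covers the plain 16-bit continuous flavor with a shared
  sampling rate across signals; EDF+ discontinuous records and bipolar
  re-referencing are out of scope.
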