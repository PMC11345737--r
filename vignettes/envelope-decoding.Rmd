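---
title: "Decoding the speech envelope from EEG: models, simulation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding the speech envelope from EEG: models, simulation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During continuous listening, low-frequency cortical activity tracks the
slow amplitude fluctuations of speech — the *speech envelope*. The strength
of this tracking can be read out from EEG with a *backward* (stimulus
reconstruction) model: a linear map from the lagged multichannel neural
response back to the envelope,

$$\hat s(t) = \sum_{n}\sum_{\tau} r(t + \tau, n)\, g(\tau, n),$$

where $r(t, n)$ is channel $n$ of the EEG, $\tau$ ranges over post-stimulus
lags (here $-50$ to $400$ ms), and $g$ holds the decoder weights. Decoding
accuracy is the Pearson correlation between $\hat s$ and the true envelope
on held-out data. This package implements that measurement chain end to
end — envelope extraction, cochlear-implant-like spectral degradation of
stimuli, ridge-regression decoding with cross-validated regularization,
segment-shuffle permutation significance, and the descriptive statistics
used to compare subject-specific against group-level decoding — plus a
forward-model simulator so that every stage can be validated by parameter
recovery without access to human recordings.

## Envelope extraction

`extract_envelope()` follows the standard auditory-model chain: a gammatone
filterbank (28 filters, 4th order, equally spaced on the ERB-rate scale
between 50 and 5000 Hz), absolute-value rectification, power-law
compression, averaging across bands, a zero-phase 8th-order Butterworth
lowpass at 10 Hz, and resampling to 100 Hz.

Three choices deserve comment:

* **Power-law exponent** (default 0.6, argument `power_exponent`). The
  exponent of the compressive nonlinearity is a convention of the envelope
  modelling lineage rather than a measured constant; downstream decoding is
  insensitive to modest changes. It is exposed as a parameter so
  sensitivity analyses can vary it.
* **Rectification** is absolute value, not half-wave: it preserves energy
  and makes the envelope invariant to carrier sign.
* **Zero-phase filtering** is used everywhere (the Butterworth stages are
  applied forward and backward), because any group delay between stimulus
  and response would shift the decoder's lag axis. Quoted orders refer to
  the one-pass design; the effective magnitude response is squared, so a
  −3 dB design corner is a −6 dB point of the effective filter.

Numerically, high-order Butterworth transfer functions are unstable at
very low normalized cutoffs (10 Hz at a 16 kHz audio rate is 0.00125 of
Nyquist), so all Butterworth filters are realized as cascaded second-order
sections derived from the analog prototype poles. The band-averaged
envelope is first polyphase-resampled to an intermediate 400 Hz before the
10 Hz lowpass; the anti-alias stage at 200 Hz cannot alter a signal that
is subsequently lowpassed at 10 Hz, and the high-order filter then
operates at a benign normalized cutoff. Rational resampling is implemented
as the textbook upfirdn construction (zero-stuffing, Hamming windowed-sinc
anti-alias filter normalized to exactly unit DC gain, delay-compensated
downsampling).

`detect_landmarks()` is a deliberately simple stand-in for published
vowel-onset detectors: it finds peaks of the rate-of-rise of a 10
Hz-smoothed rectified envelope, thresholded within consecutive 2 s windows
at 30% of the window maximum, with an 80 ms minimum separation. Only its
summary statistics matter here: `ioi_stats()` reports windowed inter-onset
intervals whose mean (~200 ms) and coefficient of variation (~0.55, using
the population SD) characterize syllable timing.

## Spectral degradation

`vocode()` reduces a cochlear-implant simulation to the two parameters
that define its listening conditions: the number of analysis channels
(default 16) and, for the "vocoded + blurring" condition, a current-spread
decay slope in dB per octave of channel separation (default −16).
Per-band envelopes (rectified, 300 Hz lowpass) modulate band-limited noise
carriers and the bands are summed at the input RMS. Current spread is a
row-normalized mixing matrix with gains $10^{s\,|\log_2(f_j/f_i)|/20}$;
row normalization conserves total envelope energy so that blurring does
not confound loudness with spectral smearing. The analysis bands are
highpass∘lowpass Butterworth cascades sharing interior corners: after
zero-phase application adjacent bands cross at half amplitude and the
summed magnitude stays within ±3 dB of flat across the 100–8000 Hz range
(capped just below Nyquist for lower-rate audio).

The deliberate simplification: internal details of published
cochlear-implant vocoders (spiral-ganglion carrier models, electrode
geometry) are out of scope; what is reproduced is the channel-count and
spread-slope abstraction, which is sufficient to generate the two degraded
conditions and to verify that the broadband envelope — the decoded
feature — survives vocoding nearly unchanged (the test suite checks
pairwise envelope correlations above 0.95 on synthetic stimuli).

## The decoder

`prepare_eeg()` applies the standard preprocessing: average reference,
resample to 256 Hz, zero-phase 4th-order Butterworth highpass at 0.5 Hz
and lowpass at 40 Hz, 5 s trims at both ends, and resampling to 100 Hz.
Artifact-removal steps that require human judgment or external tooling
(bad-channel marking, ICA, line-noise removal) are intentionally outside
the package.

`build_lag_matrix()` expands the EEG into a samples × (channels·lags + 1)
design with zero-padded edges and an unpenalized intercept column.
`fit_ridge()` solves the normal equations with an identity penalty —
**no eigenvalue normalization of λ** — a convention that toolboxes differ
on and that is therefore fixed and documented rather than guessed; the
test suite pins the solver to an augmented least-squares oracle at 1e-8.
Edge handling by zero padding (rather than row deletion) affects only
0.45 s of context per boundary.

Cross-validation (`cross_validate()`) uses contiguous time folds, never
shuffled samples: the signals are strongly autocorrelated and sample-level
folding would leak. The penalty grid spans $10^{-7}$–$10^{7}$ in 15
logarithmic steps; ties in mean validation correlation break toward the
*larger* penalty, a conservative choice under near-flat validation curves.
Subject-specific decoders use 4 folds; group decoders pool the training
subjects and use one fold per subject, so the penalty is selected by
leave-one-subject-out generalization, then refit on all pooled data.

`evaluate()` reconstructs over the first 60 s (configurable) of the
held-out trial. A constant reconstruction (e.g. an all-zero decoder)
yields r = 0 with a warning rather than an error, keeping permutation
loops total.

## Permutation significance

The null hypothesis — no temporal correspondence between envelope and
EEG — is simulated by cutting the envelope into ~3 s segments, permuting
them, and re-training/re-testing the decoder against the *unmodified*
EEG, 1000 times at full scale. Implementation choices where the procedure
is underdetermined:

* **Cut points.** "Zero-crossings" of a nonnegative envelope is read as
  crossings of the envelope's own mean nearest each multiple of the chunk
  length: low-amplitude points that allow artifact-free joins.
* **Derangement.** "No coincidental true pairings" is implemented in its
  strongest well-defined form: the segment order is a uniform random
  derangement (no segment keeps its index; with two segments the swap is
  forced). A weaker mode excluding only the identity permutation sits
  behind `shuffle_spec(derange = FALSE)`.
* **Joins.** Junctions are bridged by monotone cubic interpolation over a
  50 ms span: continuous, nonnegative by construction, and the output
  length equals the input length exactly. Outside the join windows the
  sample values are untouched, so the shuffled envelope has the original
  amplitude distribution.
* **The test-window envelope is shuffled too**, with the same scheme, so
  the null decoder is scored against a stimulus with matched marginal
  statistics.
* **The observed penalty is reused** for all null fits rather than
  re-running cross-validation per permutation: λ is driven by the response
  covariance, which the shuffle does not touch, and the lagged covariance
  is computed and Cholesky-factorized once per cell, making each
  permutation a single cross-product and triangular solve. This fast path
  is what makes calibration experiments with hundreds of cells feasible.

Significance follows the percentile rule: an observed accuracy above the
95th/99th/99.9th percentile of its null is significant at
p < .05/.01/.001; `significance()` reports the midrank percentile.

## The simulator

The generator's defaults mirror the emulated study design: 38 subjects,
~10 min of training and a 60 s held-out trial per condition, a 2
(language) × 3 (degradation) condition set, syllable-like stimulus timing
(gamma-distributed inter-onset intervals, mean 200 ms, CV 0.55 — the
right-skewed regime of natural narrative speech), and EEG at a 2–8 Hz
band-limited SNR of 0 dB with $1/f$ background noise, 30% of whose power
is shared across channels (EEG background is spatially correlated, and a
shared component stresses the decoder realistically).

Because the emulated study never fits forward models, the kernel family is
a free design choice, flagged as such: each subject's temporal response
function is a smooth biphasic profile (main peak drawn in 80–180 ms,
negative rebound ~100 ms later) times a smooth channel topography. Two
structural parameters matter:

* **`subject_variability` (default 0.3)** mixes a population kernel shared
  by the cohort with a subject-specific component. Real listeners share
  response morphology — that shared structure is the only reason
  leave-one-subject-out group decoding works at all. At the default,
  group decoders consistently lag subject-specific ones while remaining
  far above chance, and within-subject condition rankings of the two
  modes agree (mean Kendall's W above 0.5). The size of the scaled loss
  grows with `subject_variability` and shrinks with the amount of pooled
  training data.
* **Condition effects** are encoded exactly where the design wants them:
  intelligibility as a kernel *gain* (`language_gain`, default 1.2, for
  the language-A analogue) and spectral degradation as a kernel *shape*
  perturbation (`degradation_shape_jitter`, default 0.3, scaled 0/1/2
  across the three degradation levels). Gain produces a consistent
  accuracy offset; shape perturbation produces a train/test-mismatch
  penalty — the two signatures the pipeline must recover.

One interaction needs care: the noise level of each cell is anchored to
the subject's *baseline* kernel (language B, unprocessed) rather than to
the cell's own kernel. Per-cell SNR normalization would silently cancel
the gain effect — a louder response with rescaled noise decodes no better.
When a kernel is passed to `synthesize_eeg()` without a reference, the
realized 2–8 Hz SNR equals the request exactly (the contract the unit
tests verify to ±1 dB); in cohorts with effects enabled, condition effects
intentionally shift realized SNR around the baseline.

Training and test trials are generated as *separate recordings* —
distinct story segments and independent noise realizations — matching
designs that train on one trial and test on another. This matters: with a
single split recording, the long-range correlations of $1/f$ noise leak
from training into test and bias matched-condition cells upward.

A second kernel family, `kernel_family = "impulse"` (a single-lag kernel
at 100 ms), exists for diagnostics: unlike smooth physiological kernels,
an impulse kernel can be inverted exactly within the decoder's finite lag
window, which is what noiseless perfect-recovery checks require. Smooth
biphasic kernels leave a few percent of irreducible reconstruction error
even without noise — a property of finite-window deconvolution, not a
solver defect.

What the simulator does **not** emulate: eye-blink and muscle artifacts,
line noise, non-stationary listener states, electrode drift, the
spectro-temporal fine structure of real speech, or any behavioral
response. Passing tests therefore demonstrate that the analysis chain
recovers what it is designed to recover under a known forward model — not
that real recordings are free of the confounds the excluded preprocessing
steps address.

## Comparison statistics

The descriptive layer mirrors the emulated study's comparisons:
`kendalls_w()` (with midrank ties and the standard tie correction) for
within-subject concordance between subject-specific and group condition
rankings; `scaled_difference()` for losses expressed as a fraction of the
reference accuracy; `mad_raw()` — the *unscaled* median absolute
deviation, no 1.4826 consistency factor, because percentile-rank
dispersion is reported in percentile units; and `bootstrap_ci()` with
percentile intervals (the plain reading of "bootstrapped sampling with
replacement", 1000 iterations). Inferential mixed-effects modelling is
intentionally excluded: those are standard package fits in any stats
environment, and this package's job is to emit the tidy tables they
consume.

## Problem sizes in the test suite

The validation experiments run at deliberately reduced scale, chosen so
that each property is still statistically decisive: audio at 4 kHz with a
12-band, 50–1800 Hz envelope filterbank for simulation-heavy checks
(full-scale 16 kHz / 28-band extraction is exercised where the envelope
itself is under test); 30–120 s of training data per cell; 4–6 EEG
channels; 200-permutation nulls (the full-scale convention is 1000);
null calibration over 200 stimulus-independent cells; effect-recovery
contrasts over 20 simulation seeds; and a 10-subject cohort for the
group-versus-subject comparison. The acceptance script
(`scripts/acceptance.R`) re-runs the same chain at comparable sizes and
reports its computed quantities as JSON.

## Known limitations

* The landmark detector is a statistical stand-in; its onset times should
  not be compared against phonetic annotations.
* The vocoder abstracts away carrier physiology; it produces the right
  envelope statistics, not auditory-nerve-faithful stimulation patterns.
* Decoder conventions (λ scaling, zero-padded edges, contiguous folds,
  ties toward heavier regularization) are fixed and documented; other
  toolboxes make different choices and will produce slightly different
  absolute accuracies on the same data.
* Group decoding quality depends on cross-subject kernel similarity; the
  simulator's `subject_variability` controls this directly, and real
  cohorts need not sit at the default.
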