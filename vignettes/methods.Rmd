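---
title: "Models and methods behind nirsdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nirsdecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nirsdecode)
```

`nirsdecode` implements a complete analysis chain for block-design
functional near-infrared spectroscopy (fNIRS) studies of emotional face
processing: simulation of ground-truthed recordings, conversion between
optical density and hemoglobin concentration, denoising, channel-wise
statistical inference, and decoding of emotional condition from
single-subject contrast matrices. This vignette explains the models the
package implements, the parameters that matter, and the design decisions
taken where more than one reasonable choice existed.

## The experimental paradigm

The paradigm alternates dynamic (A) and static (B) presentations of facial
or control stimuli with baseline fixation (X), by default in the repeating
pattern `ABXBAX`. Every task block lasts 13.5 s, contains 8 stimuli at a
1.5 s inter-stimulus interval, and is preceded by a 1 s fixation cross; the
run starts and ends with 16 s of fixation. `build_block_design()` cycles the
pattern until each modality-content condition (three contents: anger,
happiness, neutral; two modalities) has received its quota of blocks,
assigning contents to blocks at random under a seed. Both block quotas in
common use are supported: 4 blocks per condition for the activation (GLM)
analysis and 3 for decoding, where three 13.5 s blocks at 10 Hz concatenate
to the 38 x 405 trial matrix (3 x 135 = 405 is the only arithmetic
consistent with the stated sampling rate and block length; a per-block
38 x 135 mode exists for sensitivity checks). Attention star probes are
generated inside task blocks but carry no regressor: they exist to keep
participants engaged, not to model.

The montage maps 38 measurement channels (20 sources, 16 detectors, 3 cm
separation) onto six bilateral regions: FPA, DLPFC, VLPFC, PM&SMA, S1, V1.
No published table ties individual channels to regions, so the package
ships a plausible default assignment (`inst/extdata/default_montage.csv`)
that users can replace; region membership only steers simulation effect
maps and reporting, never the estimation itself.

## The generative model of a recording

`simulate_subject()` implements exactly the signal model the downstream GLM
assumes, so that parameter recovery is a meaningful test. Per channel, the
oxy-hemoglobin signal is

  HbO(t) = sum over conditions of amplitude x (boxcar (x) HRF)(t - lag)
           + physiological oscillations + drift + AR(1) + white noise
           + motion artifacts,

with the canonical double-gamma HRF (`canonical_hrf()`: positive lobe
peaking at 6 s, undershoot at 16 s, peak-to-undershoot ratio 6, 32 s
support, unit peak). Deoxy-hemoglobin is -0.3 times the HbO task component
plus its own independent noise; the antagonistic ratio is conventional and
has no bearing on the decoding arithmetic. Physiological noise comprises
cardiac (1.1 Hz), respiratory (0.25 Hz) and Mayer-wave (0.1 Hz) sinusoids
with channel-random phases, a random per-channel linear drift, and an AR(1)
plus white measurement-noise process. Motion artifacts are Gaussian-shaped
transients of 0.2-0.8 s and Heaviside baseline steps, applied identically
to both chromophores (head movement is common-mode). Amplitudes default to
a realistic uM scale (e.g. cardiac 0.15 uM, white noise 0.05 uM against
task responses of 0.2-1 uM).

The forward modified Beer-Lambert law maps hemoglobin to optical density at
730 and 850 nm: dOD(l) = (eHbO(l) dHbO + eHbR(l) dHbR) x L x DPF(l), with
literature-typical extinction coefficients and the general age- and
wavelength-dependent differential pathlength factor formula of Scholkmann &
Wolf (2013), defaulting to age 5.2 years. `mbll_inverse()` solves the 2 x 2
system per channel and sample; round-tripping forward and inverse is exact
to numerical precision, which the tests assert at full recording scale.

What the simulator does *not* emulate: photon transport through layered
tissue, scalp/skull partial-volume effects, optode-coupling drift, or
stimulus-correlated motion. Passing tests on synthetic cohorts therefore
demonstrates that the estimation chain is correct under its own
assumptions — not that those assumptions hold in any particular dataset.

## Preprocessing

The denoising chain runs in a fixed order: Beer-Lambert inversion, motion
correction, band-stop filtering, DCT high-pass. Motion correction operates
on hemoglobin by default (configurable), since no convention fixes whether
it precedes or follows the inversion.

**Motion correction** (`correct_motion()`) flags samples whose 1 s
moving-window standard deviation exceeds 3 x the channel's median window
deviation — the median is the robust reference that makes the threshold
scale-free. Flagged fragments are padded by two windows and merged, because
detection fires on an artifact's steep flanks rather than its body. Each
segment is corrected by subtracting a smoothing-spline fit (the artifact
trend; `smooth.spline` with `spar = smoothing_factor / 10`, so the
conventional factor 5 maps to spar 0.5) and re-anchoring the segment onto a
local linear baseline extrapolated from just before it. A persisting
baseline step is then estimated from long (8 s) windows on either side —
long enough that slow physiological oscillation averages out — and removed
from all subsequent samples when it exceeds 3 standard errors. A channel
flagged in its entirety is marked unusable rather than corrected; it is
excluded from model fitting downstream.

**Temporal filtering** (`temporal_filter()`) applies forward-backward
(zero-phase) Butterworth band-stop filters of order 4 over 0.12-0.35 Hz
(respiration, Mayer) and 0.7-2.0 Hz (cardiac), then projects out a
discrete-cosine-transform basis restricted to frequencies below 0.01 Hz
(constant included), the SPM drift convention. Zero-phase filtering is
non-negotiable here: hemodynamic response timing carries information the
decoder uses. Band edges are validated against Nyquist at 10 Hz.

**Pre-whitening** (`prewhiten_ar1()`) estimates the AR(1) coefficient from
the lag-1 autocorrelation of OLS residuals, then transforms response and
design (`y_t - phi y_{t-1}`, first sample scaled by sqrt(1 - phi^2)). The
coefficient is estimated per channel, not globally, because serial
correlation differs across scalp locations.

## Channel-wise GLM and group inference

`build_design_matrix()` constructs one regressor per task condition (boxcar
convolved with the canonical HRF, no temporal or dispersion derivatives)
plus a constant; baseline fixation is the implicit reference. First-level
fits are pre-whitened OLS per channel, recording coefficients, residual
variance, degrees of freedom and the whitened `(X'X)^-1` for contrast
variances (`c' beta` with variance `c'(X'X)^-1 c sigma^2`).

Group inference (`permutation_group_test()`) consumes an array of
per-subject, per-channel condition summaries and computes a
repeated-measures two-way ANOVA per channel — factors face category and
stimulus state, subjects as the random blocking factor, each effect tested
against its effect-by-subject interaction. The implementation is a general
S x T factorial (default 3 x 2) because the category factor has three
levels; any 2 x 2 sub-design can be analysed by subsetting the cells.
Family-wise error across the 38 channels is controlled by max-statistic
permutation: cell labels are shuffled within subject (exchangeable under
the null of no condition effect — the scheme chosen because nothing
stronger is identifiable from within-subject data), the maximum F across
channels is recorded per effect, and corrected p-values are
`(1 + #{max >= F_obs}) / (1 + n_perm)`, which keeps them valid at finite
permutation counts and never below the uncorrected permutation p. Simple
effects are available as paired contrasts with sign-flipping and max-|t|
correction; both t and F routes exist because either may be wanted for
directional questions. Default 10,000 permutations at alpha 0.05; the
calibration tests use 500 permutations and 200 replicate null cohorts,
drawing the per-subject condition summaries directly from a null with
subject-specific channel baselines (simulating 4,000 full recordings
through the GLM would test the same exchangeability at absurd cost).

## From recordings to decoder samples

`extract_condition_matrix()` enforces the 38 x 405 contract (three
concatenated 135-sample blocks at 10 Hz) and errors on any other sampling
rate. `normalize_and_clean()` replaces samples beyond 3 channel standard
deviations by linear interpolation of their retained neighbours *before*
min-max scaling each channel to [0, 1]; cleaning first keeps the [0, 1]
contract intact (the order is otherwise ambiguous). Scaling is per channel
because channel gains differ physically. `build_contrast_samples()` forms
the four emotion-minus-matched-neutral difference matrices per subject,
labelled 0 for anger and 1 for happiness; dynamic and static pools are kept
separate downstream.

`split_and_fold()` performs the stratified 4:1 train/test split and
partitions the training pool into 5 folds, all deterministic under a seed.
Two grouping policies are first-class: `"subject"` (default) keeps all of a
subject's samples on one side of every boundary — the leakage-safe choice —
and `"sample"` randomises individual samples, mirroring protocols that
split at the sample level. Results under the two policies answer different
questions and are worth reporting side by side.

## The decoder and its baselines

The hybrid network follows the published layer table literally: input
(38 x 405), Conv1D with 1-wide kernels mixing the 38 channel values at each
time step into 64 feature maps, sigmoid, global max-pool whose kernel spans
all 405 steps, dropout p = 0.001, one bidirectional LSTM layer (32 hidden
units per direction), ReLU, and a linear read-out (2 units for binary
anger/happiness; 3 supported). Taken literally, the global pool collapses
time *before* the LSTM, which therefore sees a length-1 sequence; the
package implements this faithfully as the default and offers a
pool-after-LSTM variant (`pool_after_lstm = TRUE`) for ablation. Filter and
hidden counts are not published; 64 and 32 are the defaults, exposed in
`model_spec()`. The default network has on the order of 6 x 10^4
parameters, comfortably desk-scale.

No deep-learning framework is involved: the layers, analytic gradients, and
Adam optimiser are implemented in the package (the LSTM recurrence and its
backpropagation-through-time in C++ via Rcpp/Armadillo), and every
architecture's gradients are verified against finite differences in the
test suite. Training minimises cross-entropy with Adam (default learning
rate 1e-3; the documented tuning grid is `learning_rate_grid()`), batch
size 16, at most 500 epochs, early stopping after 25 epochs without
validation improvement (the midpoint of the conventional 20-30 range), with
best-epoch weights restored. `crossvalidate_and_test()` trains one model
per fold — the held-out fold is that model's validation set — evaluates
each on the fixed test partition, and averages the five test evaluations.
Class weighting is off by default because contrast-pair construction yields
balanced classes.

Baselines share the protocol exactly: a radial-kernel SVM on the vectorised
38 x 405 input (the same representation the networks consume; a
channel-mean variant is available), the convolution/pool front end alone
(`cnn_only`), and a bidirectional LSTM over the raw 405-step, 38-feature
sequence (`lstm_only`). Metrics are accuracy, macro-averaged recall and
precision, and the F1 harmonic mean, per fold and averaged.

## The decoding benchmark

`decoding_benchmark()` is the package's standing synthetic cohort for
decoder validation: 60 subjects whose anger response activates bilateral
DLPFC and whose happiness response activates bilateral VLPFC — disjoint
region sets, because per-channel min-max scaling preserves response shape
but not amplitude, so overlapping sets with merely different amplitudes
would converge to near-identical inputs — with the happiness response
peaking 1.5 s later, a neutral (visual-only) response in V1, and
between-subject amplitude variability of 0.2 uM. On top of the usual
physiological and measurement noise the benchmark carries a strong systemic
Mayer wave (0.1 Hz, 0.4 uM, one phase shared by all channels with
channel-specific coupling gains): blood-pressure oscillation is the
physiological nuisance that passes through the band-stop filters, and being
common-mode it rewards models that learn spatial combinations of channels.
An optional per-subject hemodynamic latency jitter (`latency_jitter_s`) is
available but off by default. The benchmark is the package's test of
decoder sanity and of the qualitative model comparison, not of any
published accuracy number, which belongs to a clinical dataset no
simulation can stand in for.

## Numerical choices and degenerate inputs

* HRF gammas are parameterised by their mode with unit rate, so the peak
  lands exactly on the 6 s grid point and kernels sampled at different
  rates agree exactly at shared time points.
* Convolution is FFT-based (`stats::convolve`) truncated to recording
  length; block onsets snap to the sample grid to keep boxcars on-grid.
  Condition regressors are scaled to unit peak and shared verbatim between
  the simulator and the design matrix, so effect amplitudes and fitted
  coefficients are both true peak responses in uM.
* `rowsum`-based sums of squares make the permutation ANOVA loop pure
  matrix arithmetic; its F values are verified against `aov()` with
  error strata to 1e-10.
* F statistics with a numerator sum of squares below 1e-24 are defined as
  0 (identical cell values give F = 0, corrected p = 1, rather than 0/0).
* An estimated |phi| >= 1 is clipped to 0.99 with a warning; a zero-residual
  (noise-free) channel gets phi = 0.
* Constant channels cannot be min-max scaled and map to zeros with a
  warning; constant (DC) input to the temporal filter returns ~0 because
  the drift basis contains the constant.
* Max-pool argmax ties break to the first index, keeping forward passes
  and gradients deterministic; evaluation-mode forward passes disable
  dropout and are bit-reproducible.
* All randomness flows through explicit integer seeds; child seeds derive
  from a master seed below 2^31.

## Problem sizes used in the shipped checks

The test suite exercises the chain at the scale the methods are meant for:
full 38-channel recordings (about 4,000 samples at 10 Hz) for round-trip,
filtering and GLM recovery; 50 replicate subjects for the noisy-GLM bias
check; 200 replicate 20-subject null cohorts at 500 permutations for the
family-wise error calibration; and five 60-subject benchmark cohorts
(seeds 0-4) for decoder validation. The acceptance script reports the same
quantities at matching or slightly reduced replicate counts.

## What the benchmark shows about the architectures

On the shipped benchmark (seeds 0-4, mean five-fold test accuracy) the
hybrid reaches about 0.98, the convolution-only and LSTM-only baselines
about 0.97, and the channel-mean SVM about 0.83 — the qualitative ranking
one expects when the discriminative signal is a spatio-temporal pattern
buried under common-mode physiological nuisance. Two caveats temper the
headline. First, with the layer table read literally, the global max-pool
collapses the time axis before the recurrent layer, so the hybrid is
effectively a convolutional feature extractor with a small nonlinear head;
its margin over the single-route models is real but modest, and on
individual seeds the LSTM baseline can draw level. Second, the ranking of
the SVM depends on its feature convention: on per-channel summary features
(the shallow-classifier convention in this field, and the package default)
it trails the networks clearly, whereas an RBF kernel on the full flattened
38 x 405 input is at ceiling on cohorts this clean — raw-space class
geometry is simply separable there, and only messier nuisance structure
than this generator produces would break it. Both variants are exposed and
reported.

## Known limitations

* The channel-region table is a stand-in; analyses that interpret region
  labels on real data must supply the true montage.
* The AR(1) pre-whitening is a single-pass estimate, not iterated
  (Cochrane-Orcutt style); at fNIRS series lengths the difference is
  negligible against the reported tolerances.
* The motion-correction step estimator assumes slow physiology is
  approximately zero-mean over 8 s; extremely slow, high-amplitude drifts
  partially alias into step estimates.
* The SVM baseline uses a fixed radial kernel without hyperparameter
  search; it is a reference point, not a tuned competitor.
* Simulated artifacts and noise are stationary within a run; real
  recordings drift in coupling quality over minutes.
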