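---
title: "Complexity and entropy features for motor-imagery EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity and entropy features for motor-imagery EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micompen)
```

## The problem

Motor imagery (MI) — the mental rehearsal of a limb movement without
executing it — produces decodable changes in sensorimotor EEG, most
prominently event-related desynchronization (ERD): an attenuation of mu-band
(~10 Hz) oscillatory power over the cortical representation of the imagined
effector. Brain–computer interfaces built on four-class MI (left hand, right
hand, foot, tongue) must recover these weak, artifact-contaminated
signatures from multichannel recordings, typically 22 EEG plus 3 EOG
channels sampled at 250 Hz.

`micompen` implements a complete analysis chain for this problem:

1. conventional filtering (50 Hz notch, 8–30 Hz band-pass),
2. SOBI blind source separation with cross-correlation-driven zeroing of
   ocular artifact components,
3. a nonlinear per-channel feature set ("CompEn"): Higuchi fractal
   dimension (FD), rescaled-range Hurst exponent (Hur), Tsallis entropy in
   Sneddon's critical-point approximation (TsEn), and dispersion entropy
   (DispEn),
4. two-way ANOVA screening of each feature over class and channel factors,
5. Laplacian Eigenmap (LE) dimensionality reduction, and
6. stratified 10-fold cross-validated classification with KNN, RBF-SVM and
   random forest.

Because the canonical public four-class dataset cannot be bundled, the
package ships a synthetic generator whose ground truth (Hurst exponents,
mixing matrix, artifact locations, class labels) is known analytically, so
every stage is testable end to end.

## The synthetic generator

`simulateRecording()` emulates the standard cued-trial paradigm: fixation
0–2 s, cue at 2 s, imagery 2–6 s, then an inter-trial gap (1.5 s by
default; the paradigm's published timing specifies the trial but not the
gap, so it is a parameter). Its signal model is:

* **Background activity.** Each EEG channel carries an independent white
  Gaussian source at 10 µV RMS — a deliberately simple stand-in for
  ongoing EEG.
* **Class signatures.** Each class owns a disjoint group of channels and a
  Hurst exponent (defaults 0.35/0.5/0.65/0.8). During a trial's imagery
  window, the trial class's channels carry fractional Gaussian noise (fGn)
  with that exponent *in place of* the white background (equal RMS).
  Replacement rather than addition is intentional: summing a long-memory
  source with equal-power white noise would dilute the planted exponent
  that the estimator tests must recover.
* **ERD.** The same channels carry a 10 Hz oscillation (5 µV) whose
  amplitude drops by the signature's `erdDepth` (default 0.5) during
  own-class imagery.
* **Artifacts.** Blinks are Gaussian-windowed biphasic pulses of 300 ms
  width and 100 µV peak (ocular artifact morphology; the smooth waveform
  keeps some energy above the band edge), generated as a Poisson train
  (12/min), written to the EOG channels and propagated into EEG channels
  with an exponentially decaying frontal gain profile. A 50 Hz sinusoid
  (5 µV) is added to every channel.
* **Mixing.** Neural sources are mixed into the EEG channels by a random
  diagonally dominant full-rank matrix (identity plus 0.05-scaled Gaussian
  off-diagonals); the blink source enters as an extra mixing column. The
  full matrix is recorded in the returned `GroundTruth`.

fGn is synthesized by exact-autocovariance circulant embedding
(Davies–Harte): the target autocovariance
$\gamma(k) = \tfrac12(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})$ is embedded in
a circulant matrix diagonalized by the FFT, so the generated series has the
exact fGn covariance rather than an autoregressive approximation. This
gives analytically known ground truth: $\gamma(1) = 2^{2H-1}-1$, and the
integrated track (`fbmSim()`, fractional Brownian motion) has fractal
dimension $2 - H$.

**What the generator does not emulate:** volume conduction from a head
model, non-stationary artifact types (chewing, electrode pops), 1/f
background spectra, inter-subject variability. Passing tests on this
generator therefore demonstrates that the estimators and the harness
recover *planted* structure under controlled conditions — not that the
pipeline attains any particular accuracy on real recordings.

## Preprocessing

**Filters.** The notch is a biquad IIR at 50 Hz with Q = 30; the band-pass
is a 4th-order Butterworth. Both run forward–backward (zero phase) with
odd-reflection padding to suppress edge transients. Attenuation contracts
(≥ 40 dB at the notch frequency, ≥ 20 dB an octave outside the band) refer
to the steady-state response; the first/last fraction of a second of a
filtered segment still shows the residual settling any finite IIR
implementation has.

**SOBI.** Sources are estimated by whitening followed by joint approximate
diagonalization (Jacobi rotations with closed-form Givens angles) of
symmetrized lagged covariance matrices at lags 1..100 (4–400 ms at 250 Hz —
standard practice covering EEG autocorrelation structure; the method
itself fixes no lag set). SOBI identifies sources by their temporal
coloration; on temporally white sources the lagged covariances vanish and
the decomposition is flagged low-confidence rather than silently returned.

**Artifact rejection.** Each component is scored by the maximum absolute
zero-lag Pearson correlation against the EOG channels; components at or
above the threshold (default 0.5; the criterion is standard, the cutoff is
a free parameter) are zeroed and the recording is rebuilt as
$\hat x = A \hat s$. Flags are monotone in the threshold, and an operation
that would zero *every* component refuses to run.

**Order of operations.** The pipeline notches first, then runs SOBI and
zeroing, and band-passes afterwards. Running ICA after the 8–30 Hz
band-pass would be self-defeating: blink energy lies almost entirely below
8 Hz, so no component of band-passed data can correlate appreciably with
an EOG reference — measured on the generator, the best component
correlation drops from ≈ 0.8 (notch-only) to ≈ 0.17 (band-passed), making
the rejection criterion inoperable. Ocular cleanup must see the
unfiltered low frequencies; the mu/beta restriction belongs after it.

## The CompEn features

All four features are computed per trial and channel on fixed windows
(1500 samples = 6 s at 250 Hz for full-trial windows; the classification
default uses the 2–6 s cue-to-end window, the only part of a trial carrying
class information in the generator, giving 1000-sample windows).

**Higuchi FD** (`higuchiFD()`, kmax = 20). Curve lengths $L(k)$ over
decimated sub-series are regressed on $\ln(1/k)$; kmax = 20 is the
saturation point (estimates at kmax 20 vs 40 differ by < 0.05 on fBm
tracks, which the tests verify). A straight line gives exactly 1; white
noise gives 2. The FD–Hurst relation FD = 2 − H holds for *self-affine
tracks* (fBm), not for their increments (fGn), whose FD saturates near 2;
the consistency tests therefore pair `hurstRS()` on fGn with `higuchiFD()`
on the integrated track. Estimates marginally outside [1, 2] (sampling
noise on non-fractal windows) are returned with a warning, never clipped.

**Rescaled-range Hurst** (`hurstRS()`). Block lengths run over a dyadic
grid; each block is demeaned, cumulated, and scored by range/SD; the
log–log slope of mean R/S against block length is the estimate. The grid's
default minimum is 64 samples: short blocks carry the well-documented
small-sample upward transient of R/S (the Anis–Lloyd bias), and on
1500-sample fGn windows the 64..512 grid roughly halves the bias at
H = 0.3 relative to a 16..512 grid while keeping four grid points. A
log-return pre-transform is available (`useLogReturns`) for strictly
positive series; band-passed EEG crosses zero, so it is off by default.
The textbook expression $(2^{2H-1}-1)\,n^H$ sometimes quoted as a
"rescaled-range formula" mixes the lag-1 autocovariance identity (zero at
H = 0.5) into the scaling law and is provided only as a documented
reference (`rescaledRangeFormula()`), never used in estimation.

**Tsallis entropy** (`tsallisQ()`, `tsallisSneddon()`). The q-form
$(1-\sum p_i^q)/(q-1)$ dispatches to Shannon entropy at q = 1. The Sneddon
approximation for q = 2 partitions the window at critical points of the
discrete derivative (zero or sign change; $\Delta t$ cancels since only
the sign pattern matters) and computes $1 - \frac1N \sum s_i^2/\sigma^2$
with population variances. Bin boundary convention: a sign flip closes the
bin at the extremum sample; a zero derivative closes it after the flat
pair, so a staircase signal consists of internally constant bins and
attains the upper bound 1 exactly, while a monotone window is a single bin
and yields exactly 0. The result is bounded above by 1; histogram-mode
Tsallis (`tsallisHistogram()`) is provided separately because reported
values in parts of the literature exceed that bound and are only
consistent with a binned amplitude distribution.

**Dispersion entropy** (`dispersionEntropy()`, m = 2, c = 2, d = 1). The
signal is mapped through the normal CDF of its own standardization into
integer classes `round(c·y + 0.5)` (the originating method's NCDF rule; a
concrete rule is required and this one makes the feature invariant to
positive affine transforms), embedded at delay d, and the Shannon entropy
of pattern frequencies (denominator $N-(m-1)d$) is returned, bounded by
$\ln(c^m)$. The defaults give a 4-pattern alphabet with upper bound
$\ln 4 \approx 1.386$, the scale on which reported four-class MI values
cluster; m, c, d are all configurable.

## Screening

`twoWayAnova()` computes the classical balanced fixed-effects
decomposition (class × channel with interaction) directly from cell means
— no model-fitting machinery — so its sums of squares are checkable against
closed forms and against `stats::aov` (agreement to 1e−8 is a test).
Unbalanced tables are balanced by seeded down-sampling before analysis;
the classical decomposition is ambiguous otherwise and the targeted
experimental design is balanced anyway. Screening is descriptive: all four
features always proceed to classification regardless of significance, and
no multiple-testing correction is applied. Within a class-specific-channel
design, a planted per-class Hurst difference loads mainly on the
class × channel interaction; the per-feature summary reports class,
channel and interaction p-values plus the class with the largest
standardized mean deviation.

## Laplacian Eigenmap

`buildNeighborGraph()` builds an OR-symmetrized kNN graph (k = 5, binary
weights by default; heat-kernel weights optional) on standardized
features — standardization first, because FD ∈ [1,2] and raw-scale
entropies would otherwise dominate Euclidean distances.
`laplacianEmbed()` solves $Ly = \lambda D y$ through the symmetric form
$D^{-1/2} L D^{-1/2}$, discards exactly one trivial eigenvector, and
returns the next r eigenvectors rescaled by $D^{-1/2}$, which satisfy
$Y^\top D Y = I$ and minimize $\mathrm{tr}(Y^\top L Y)$ (both asserted to
1e−6/1e−8 in tests). On a disconnected graph (warned, or an error in
strict mode) the remaining zero-eigenvalue eigenvectors encode component
membership and are deliberately retained: they are the discriminative
coordinates when clusters separate completely. Because the eigensolver
returns an arbitrary basis of a degenerate eigenspace, the zero subspace
is first rotated so that the discarded vector is exactly the constant
direction and the retained ones are honest component indicators. Out-of-sample trials are
mapped by a Nyström-style weighted average over the k nearest training
points, so cross-validation never refits the eigenproblem on test data.

## Classification harness

Stratified 10-fold cross-validation; per fold, standardization statistics
and the LE embedding are computed on training trials only. Classifiers:
KNN with k = 5 and Euclidean distance; SVM with RBF kernel, C = 10 and
$k(x,y) = \exp(-\lVert x-y\rVert^2 / (2\sigma^2))$ with σ = 0.5 — the
width convention is stated explicitly because "smoothing value" names
none; and a seeded random forest with 100 trees (a conventional size; the
method prescribes none). An optional grid search over
$C \in 10^{-4}..10^4$ (`tuneSvmCost()`) reproduces the usual tuning
protocol; default runs use C = 10 directly to stay deterministic. A master
seed fans out to stages via `stageSeed()` (documented affine map mod
$2^{31}-1$) so any stage can be re-run in isolation.

Metrics are accuracy, macro precision and macro recall in percent, plus a
4×4 confusion matrix in fixed class order (LH, RH, F, T; rows = truth); a
class never predicted contributes precision 0 with a warning.

## Problem sizes and numerical tolerances

The test-suite and verification-script sizes are chosen as the smallest
that make the statistical contracts sharp: Hurst/FD recovery uses
1500-sample windows averaged over 20 seeds (recovery within 0.1; FD–Hurst
consistency within 0.15); SOBI uses 3 AR(1) sources at n = 20 000 over 10
seeds (Amari index < 0.1); artifact rejection uses 8-trial recordings on
an 8 EEG + 1 EOG montage over 10 seeds; the end-to-end run uses 160 trials
(40 per class) on the same montage. Eigen-solver and ANOVA exactness are
asserted at 1e−6–1e−8; probability-vector inputs must sum to 1 within
1e−9; near-zero Laplacian eigenvalues are classified as trivial below
1e−8. EDF I/O quantizes to the full 16-bit range per channel, so round
trips are exact to one digitization step of the per-channel amplitude.

## Known limitations

* The generator's linear instantaneous mixing and white backgrounds are
  far simpler than real EEG; accuracies on synthetic data say nothing
  quantitative about real four-class MI performance.
* GDF input is not supported (no reader available in this stack; convert
  to EDF).
* R/S and Higuchi estimators assume within-window stationarity; the 6-s
  windows follow the usual practice for making that assumption tenable,
  not a test of it.
* The band-pass-then-feature path weakens long-memory structure (the
  filter's autocorrelation dominates at short lags), which is why planted
  Hurst effects appear more strongly in FD/entropy features after
  filtering; the epoch window and band edges are configurable where a
  different trade-off is wanted.
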