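---
title: "Methods: hybrid seek optimization and ensemble seizure prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid seek optimization and ensemble seizure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridseek)
```

## The problem

Epileptic seizures are preceded, in many patients, by a *preictal* state in
which the scalp EEG drifts away from its seizure-free (*interictal*)
baseline, typically starting 60--90 minutes before onset. Seizure
*prediction* is therefore cast as a binary classification of short EEG
analysis windows: preictal versus interictal, with ictal (during-seizure)
data excluded. hybridseek implements one complete pipeline for this task:
preprocessing, band decomposition, feature extraction, metaheuristic
feature selection, a three-member weighted ensemble, and protocol-based
evaluation.

## Preprocessing and window labelling

Records are optionally downsampled (anti-aliased with a zero-phase
Butterworth low-pass at 45% of the target rate, then decimated) and
band-pass filtered to 0--75 Hz with a 4th-order Butterworth applied
forward--backward, so the filter is zero-phase and waveform morphology is
preserved. With a lower edge of 0 Hz the high-pass stage is omitted. No
further artifact handling (ICA, notch filtering, re-referencing) is
attempted.

Windows are non-overlapping, 4 s by default. A window is **preictal** iff
it lies fully inside `[onset - horizon, onset)`; the horizon defaults to
3600 s, the lower end of the conventional 60--90 min preictal range, and is
configurable. Windows overlapping an ictal span are discarded, as are
windows inside a postictal guard after the seizure offset (default 1800 s,
chosen to keep postictal slowing out of the interictal class; the guard is
configurable because no standard value exists). Everything else is
interictal. Intervals are half-open `[start, end)` in seconds from record
start; a window straddling the preictal boundary is deliberately labelled
interictal rather than dropped, which slightly dilutes the interictal class
but keeps the labelling rule simple and conservative.

## Frequency bands and features

Each window is filtered into the five classical EEG bands -- delta (0--4
Hz), theta (4--8), alpha (8--13), beta (13--22) and gamma (22--30) -- with
the same 4th-order zero-phase Butterworth design (delta is a plain low-pass
at 4 Hz). The beta/gamma split at 22 Hz is narrower than some conventions
(13--30/>30 Hz); it is the package default and overridable via the band
table. Filter transition bands make the edges approximate; tests therefore
assert at least 20 dB of stop-band attenuation rather than brick-wall
separation.

Per band and channel, eight features are computed:

* **FMN, FVR, FSDN, FSKW, FKRT** -- mean, unbiased variance, standard
  deviation, and the moment-ratio skewness and kurtosis
  $\sum (A_r-\bar A)^3 / (q d^3)$ and $\sum (A_r-\bar A)^4 / (q d^4)$ with
  $d$ the sample standard deviation (kurtosis is not excess-corrected, so a
  Gaussian scores about 3). A constant window has $d = 0$; skewness and
  kurtosis are then 0 by convention, with a warning rather than an error so
  batch extraction never aborts mid-record.
* **FWEY, FWEN** -- relative wavelet sub-band energies and their Shannon
  entropy. The window is decomposed with a periodized Daubechies-4 (8-tap)
  DWT to level 5, chosen so that at 256 Hz the deepest approximation band
  covers 0--4 Hz, aligning the coarsest scale with the delta band. The DWT
  is implemented in the package (pyramid algorithm, periodic boundaries)
  and its coefficients are validated in the tests against reference values
  from an independent wavelet implementation. Since the scalar feature
  vector needs one energy number per band, `FWEY` defaults to the total
  *detail* relative energy, i.e. one minus the approximation band's share;
  the full per-sub-band vector is available via `wavelet_config(per_subband
  = TRUE)`.
* **FHEN** -- amplitude entropy: the window's amplitudes are binned into 16
  equal-width histogram bins spanning their range and the Shannon entropy
  of the bin frequencies is taken. A count of "unique amplitude values" is
  meaningless for continuous data, hence the histogram discretization; 16
  bins keeps the estimate stable for 1024-sample windows.

All entropies use base-2 logarithms (bits) and carry the conventional minus
sign, so they are nonnegative; zero-energy and single-bin degenerate inputs
yield 0 by convention. The feature vector is ordered band-major, then
channel, then feature, with names `<band>.ch<k>.<feature>`.

## The hybrid seek optimizer

The optimizer maximizes a fitness function over a box. Each of the $m$
agents keeps a memory $Z_e$ of the best position it has held. Per
iteration, each agent forms two proposals that are averaged into one:

* **Corvid move** (crow-search style): follow a uniformly drawn flock-mate
  $f \ne e$ toward its memory, $J_e + \lambda_1 a (Z_f - J_e)$ with
  $\lambda_1 \sim U(0,1)$ and flight length $a = 2$. With probability
  $P_{aw} = 0.1$ the mate is "aware" and the follower instead relocates
  uniformly within the bounds -- the standard crow-search evasion rule,
  adopted because the awareness probability is a declared parameter of the
  algorithm but appears in no update equation.
* **Gregarious move** (sparrow-search style): the current best agent
  explores relative to the worst, $J_e + \chi\,|J_e - J_{worst}| /
  ((j_e - j_{ws}) + \varsigma)$ with $\chi \sim U(-1,1)$ and guard
  $\varsigma = 10^{-12}$; every other agent moves around the global best
  with a velocity augmentation, $J_{best} + \theta\,|J_e - J_{best}(1 +
  \nu_1 \varpi) + V|$, $\theta, \nu_1, \varpi \sim U(0,1)$. The published
  branch condition ("if $j_e > j_{gl}$") can never hold for a maximized
  global best; it is implemented as the best/non-best split of the parent
  sparrow-search algorithm, and the best-agent denominator is the repaired
  quotient form of that parent. The shared velocity is advanced once per
  iteration as $V \leftarrow V + \nu_1 \varpi J_{best}$ from its zero
  initialization.

The hybrid proposal is the exact midpoint of the two moves. Bound handling
is reject-only: an out-of-bounds proposal leaves the agent where it was (no
clipping), and the agent is re-evaluated either way so the evaluation count
is exactly $m(I_{max}+1)$. Memories update only on *strict* fitness
improvement, which makes the best-so-far history non-decreasing and
trajectories stable under ties. All draws come from one seeded stream, so a
`(config, seed, fitness)` triple reproduces its trajectory bit for bit.
The distributions of $\theta, \chi, \nu_1, \varpi$ are not prescribed
anywhere; uniform choices on the natural supports are used.

## The ensemble

Three base classifiers are trained from scratch on the selected features:

* **AdaBoost** over depth-1 decision stumps: each round picks the stump
  minimizing the weighted error $\phi_c$, weights it by $\tau_c = \frac12
  \ln((1-\phi_c)/\phi_c)$, and reweights samples multiplicatively
  ($p \leftarrow p\,e^{-\tau_c t_s u_c(v_s)}$, renormalized) -- the unique
  update consistent with that $\tau_c$. Training halts when no stump beats
  error 0.5. The class-1 score is the margin squashed to $[0,1]$ by the
  total stump weight.
* **Random forest**: 50 unpruned Gini trees on bootstrap samples of size
  $n$, with $h = \lfloor\sqrt{D}\rfloor$ candidate features redrawn at
  every node ($h < D$ enforced). Score = fraction of trees voting class 1.
* **Decision tree**: greedy binary splitting by largest Gini impurity
  decrease, $1 - \sum_\chi V_\chi^2$, ties broken deterministically by
  lowest feature index then lowest threshold; leaves store class
  proportions, which serve as scores.

The fused score is the convex combination $E_c = \tau E_{AB} + \rho E_{RF}
+ \varepsilon E_{DT}$ with $(\tau, \rho, \varepsilon)$ on the unit simplex,
and the label is 1 iff $E_c \ge 0.5$. Whether labels or scores are fused is
ambiguous in the underlying formulation; scores are used so the convex
combination is well-defined and the simplex constraint is meaningful.

## Wrapper selection and fusion tuning

**Feature selection** runs the optimizer over $[0,1]^D$; a feature is
included iff its coordinate is $\ge 0.5$. Candidate masks are scored by the
mean stratified 3-fold validation accuracy of a *boosted decision-stump*
surrogate (8 rounds), with column sort orders precomputed once so each
evaluation costs only cumulative sums over the masked columns. A greedy
depth-limited tree was evaluated first as the surrogate and rejected: on
datasets whose signal is spread additively over several informative
features, a shallow tree's accuracy saturates after about three of them --
dropping an informative feature can even raise its cross-validated accuracy
-- so its fitness landscape cannot reward full recovery of the informative
set. Boosted stumps are additive in the features, so each retained
informative feature strictly raises the surrogate's accuracy. Empty masks
receive a fitness below any attainable accuracy and therefore never win.
The full-ensemble fitness remains available by scoring masks manually, but
is far too expensive inside the optimizer loop at these budgets.

**Fusion tuning** runs the optimizer over $[0,1]^3$; every candidate is
projected onto the simplex by flooring at $10^{-6}$ and normalizing
(projection by normalization, not clipping, so the constraint holds exactly
for every candidate, not only the final one), and the fitness is the fused
accuracy on a validation split. If all base scores are constant on the
validation set, equal weights are returned with a warning.

Within each training part, base models are fit on a stratified 75% portion
and the fusion weights are tuned on the held-back 25%, so the weights are
not tuned on data the bases memorized. If either portion would lose a
class, the whole training part is reused for both steps.

## Evaluation protocols and metrics

Metrics are accuracy $(T_{pos}+T_{neg})/(R_{pos}+R_{neg})$, sensitivity
$T_{pos}/R_{pos}$ and specificity $T_{neg}/R_{neg}$, with preictal as the
positive class; a metric whose reference class is absent is reported `NA`
with a warning. Two protocols exist: stratified training-percentage splits
(defaults 40/50/60/80/90%) and stratified k-fold (defaults
2/4/6/8/10/12), each protocol point an independent run with its own
deterministically derived sub-seed and no model reuse across points. K-fold
rows report fold means; folds missing a class are excluded with a warning.
Metrics reports are versioned, tab-separated and deterministic -- identical
config and seed reproduce them byte for byte.

## The synthetic generator

`generate_record()` builds records as one sinusoid per EEG band (delta 2
Hz down to gamma 26 Hz, amplitudes decreasing with frequency) plus
$1/f^\beta$ Gaussian background noise with $\beta = 1$, the typical EEG
spectral slope. Inside each preictal horizon the delta and theta components
are scaled by `preictal_delta_gain` (default 3) and 3 Hz biphasic sawtooth
spike--wave bursts of 1--2 s are added; bursts also fill ictal spans. This
emulates the *spectral* signature the pipeline exploits -- elevated
low-frequency relative energy before onset -- and deliberately nothing
else: there are no neural mass dynamics, no inter-channel coherence
structure, no EMG/eye-blink artifacts, and the preictal change is abrupt
rather than gradual. Passing tests on these records demonstrates that the
pipeline detects a planted band-power shift through the full preprocessing,
feature, selection and fusion stack; it does not demonstrate clinical-grade
prediction on real scalp EEG. `generate_feature_dataset()` plants `k`
informative columns shifted by a configurable effect size (in within-class
SD units) among standard normal noise columns and returns the ground-truth
index set for recovery tests.

## Problem sizes and numerical choices

The bundled evaluations use a 20-minute two-channel 256 Hz record with one
60 s seizure, a 600 s horizon and 120 s guard (255 four-second windows);
selection benchmarks use $n = 400$, $D = 40$, $k = 5$ at effect size 3 with
optimizer budgets $m = 20$, $I_{max} = 40$; the sphere benchmark uses $m =
30$, $I_{max} = 200$ in five dimensions. These sizes exercise every stage
while keeping a full run in minutes on one core. Degenerate inputs follow
the conventions above (zero-variance windows, zero-energy wavelet input,
single-bin histograms, flat fitness landscapes all return defined values
rather than erroring). EDF quantization is 16-bit over each channel's
physical range, so round-trips are exact to half a quantization step.

## Known limitations

Real EDF recordings vary in ways the reader does not cover (per-signal
sampling rates, EDF+ discontinuous records, embedded annotation channels --
annotations come from a sidecar CSV instead). The synthetic preictal
signature is far stronger and cleaner than real preictal dynamics, so
reported synthetic accuracies are upper bounds, not clinical estimates.
The optimizer treats only box constraints; the feature-selection encoding
is a simple 0.5 threshold with no cardinality control, so selected masks
are typically larger than the informative set (recovery, not parsimony, is
the tested property).
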