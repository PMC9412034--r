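---
title: "Site-of-origin classification of outflow-tract arrhythmias: models and design choices"
author: "ecgsoo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-of-origin classification of outflow-tract arrhythmias: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgsoo)
```

## Scope and model

`ecgsoo` implements an offline pipeline for one clinical question: given a
single ectopic 12-lead QRS complex, does the beat originate in the left or
the right ventricular outflow tract? The classifier is a support vector
machine with a radial-basis kernel; its inputs are either the "raw10"
representation (each lead's normalized QRS reduced to 10 bin means) or a
381-entry battery of signal, wavelet and spectral features. Because large
labelled OTVA cohorts are not publicly available, the package ships a
synthetic beat generator that plays the role of the simulated training
population, and a noisy "clinical-like" sampler that emulates the domain
shift of real cohorts. Every stage is deterministic given its seed.

## The synthetic beat generator

Each lead of a beat is a sum of three Gaussian lobes (Q−, R+, S−) on a
300 ms window at 1 kHz. The chamber label controls the *precordial
amplitude profiles*: RVOT beats carry large S and small R amplitudes in
V1–V2 (dominantly negative early precordials) with the R/S balance
flipping at V3 or later, while LVOT beats have larger early-precordial R
waves and transition at or before V3. This is the standard
electrophysiological signature of the two origins and is what the
classifier should (and does) exploit; both chambers share an inferior limb
axis with only a weak chamber tilt.

Morphological diversity comes from three deterministic factors, all hashed
from the configuration seed:

* **anatomy** (`anatomyId`): lobe width multiplier U(0.80, 1.25), global
  timing shift U(−12, 12) ms, global gain U(0.85, 1.15), per-lead gains
  U(0.90, 1.10);
* **electrode placement** (`electrodeConfigId`): per-precordial-lead gains
  U(0.75, 1.25) and latencies U(−8, 8) ms, emulating shifted chest
  electrodes;
* **sublocation**: each of the nine sites has fixed planar coordinates
  laid out like the outflow-tract anatomy (the aortic cusps in a chain,
  NCC/AMC/LV-summit around them, the three RVOT sites in a separate
  cluster); a site's chamber-relative position maps linearly into small
  per-lead amplitude offsets. Neighboring sites are therefore
  morphologically closer than distant ones, which the adjacency-constrained
  mixup mode and the neighbor-coherence test rely on.

`classSeparation` (default 1) linearly scales both chamber profiles away
from their midpoint: 0 makes the chambers indistinguishable, 2 roughly
doubles the textbook gap. The default was chosen so that chamber
classification is clearly learnable but not trivial — a one-feature
threshold on the V2 late-window mean reaches a balanced accuracy of about
0.94, not 1.0 — mirroring the accuracy regime reported for real
transition-zone algorithms. The amplitude perturbation ranges above were
widened from an initial, narrower design for the same reason: with
near-disjoint classes every downstream comparison saturates at 1.0 and
carries no information.

Ground-truth fiducials are part of the generator contract: onset/offset
bracket the region where the across-lead amplitude envelope exceeds 2% of
its maximum (half-open window, 1-based indices), and the R peak is the
R-lobe center known from construction. An earlier draft used the envelope
argmax as the R ground truth; that definition jumps to the S lobe on
S-dominant (RVOT) beats and misaligns the late-QRS window, so the
construction-based definition is the one shipped.

The clinical-like sampler draws chamber (LVOT probability defaulting to
77/334, the published imbalance of the largest public OTVA cohort),
sublocation, anatomy and placement at random, then applies a per-record
gain U(0.8, 1.25), a low-frequency sinusoidal baseline wander (amplitude
bounded by `wanderAmplitude`, frequency U(0.5, 2) Hz) and additive
Gaussian noise of standard deviation `noiseSd` (normalized units). With
all three distortions at zero the sampler reduces exactly to generator
output, which the tests exploit.

What the generator does *not* emulate: biophysical activation sequences,
torso geometry, pathological tissue, rate dependence, P/T waves,
inter-beat variability within a patient, or measurement artifacts beyond
stationary noise/wander/gain. Passing tests therefore demonstrate that the
pipeline recovers the morphological class structure it was pointed at —
not that it would reach any particular accuracy on real patients.

## Preprocessing

Delineation uses scale-2 coefficients of the quadratic-spline wavelet
(below), combined across leads by root-mean-square modulus: the QRS core
is where the combined modulus exceeds 25% of its maximum, and the
onset/offset are the nearest sub-5% samples on either side. On generated
beats this lands within 10 ms of the ground truth; for synthetic data the
stored true fiducials can be used directly (`useTrueFiducials = TRUE`,
the default in the representation builders).

Normalization subtracts a per-lead baseline (mean of the 10 ms before
onset), centers a fixed 160 ms window on the R peak (zero-padding outside
the QRS window) and divides by the *global* across-lead max-abs. Global
rather than per-lead scaling is deliberate: the comparative features and
the R/S logic depend on inter-lead amplitude ratios, which per-lead
scaling would destroy. A `perLead` flag exists for sensitivity analysis.
The operation is idempotent and gain-invariant.

Downsampling is bin-mean (not decimation): each lead's window is split
into 10 contiguous near-equal bins — any remainder goes to the leading
bins, a deterministic tie-break — and averaged, so each pseudo-feature is
the mean electrical potential over a time interval.

## Transforms

The wavelet transform is the undecimated (à-trous) filter bank of the
derivative-of-smoothing quadratic spline that is standard for QRS work. It
is applied exactly in the frequency domain on a mirror-extended signal
(lowpass `H(ω) = e^{iω/2} cos³(ω/2)`, highpass `G(ω) = 4i e^{iω/2}
sin(ω/2)`, dyadic dilation), and the accumulated `(2^j − 1)/2`-sample
group delay of scale `j` is compensated with a phase ramp so zero-crossing
positions are comparable across scales — the property the fiducial
detector depends on. Residual alignment error is half a sample.

Fiducials: the dominant opposite-sign modulus-maxima pair at scale 4 near
the R hint is propagated down to scale 1; the R peak is the zero crossing
between the pair (for a negative-dominant lead this is the main negative
wave, flagged `polarity = -1`). Q and S come from flanking opposite-sign
maxima whose scale-1 modulus exceeds 12.5% of the maximum (configurable
via `qsFrac`; the threshold is a convention, not a measured constant), and
are reported absent on monophasic beats.

The Welch estimator averages Hann-tapered, mean-removed, 50%-overlapping
segments of length `min(256, L)`, zero-padded to 256 samples so that the
frequency grid is `fs/256` regardless of window length — at 1 kHz that is
3.9 Hz, fine enough that each of the six analysis bands \[0,3), \[3,6),
\[6,9), \[9,12), \[12,25), \[25,50) Hz contains at least one grid point.
One-sided density scaling makes the integrated density match the signal
variance (verified by a Parseval-style test on white noise).

## The feature battery

Three families, 381 canonical names
(`<family>.<feature>[.<lead>|.<leadA>_<leadB>]`):

* **signal** (161): QRS duration (ms) and precordial transition; per lead
  the polarity, max, min, signed/unsigned absolute maxima, amplitude, raw
  and absolute trapezoidal areas; per lead pair the signed maximum and
  area of the difference and the zero-lag normalized cross-correlation.
* **wavelet** (136): the same transition code on scale-1 signed maxima;
  per lead the scale-1 max/min/mean, area, fragmentation (raw/absolute
  area ratio, bounded in \[−1, 1\]) and the R/S amplitude ratio from the
  fiducials; the three comparative features on scale-1 coefficients.
* **spectral** (84): per lead the fundamental frequency (argmax of the
  density) and the six band-averaged powers.

Comparative features are restricted to the three within-group pairings —
limb (3), augmented (3), precordial (15), 21 pairs in total — to limit
dimensionality. The precordial transition is coded as `k/5` where `k` is
the 0-based index of the first lead V2…V6 whose signed-maximum polarity
differs from V1's, with 1.0 doubling as the no-change sentinel; a
zero-amplitude lead counts as positive, a deterministic tie-break.
Comparable batteries in the clinical ECG literature sometimes quote
slightly smaller totals after pruning redundant members; this package
keeps the full literal enumeration (2 + 8×12 + 3×21, 1 + 6×12 + 3×21,
7×12) so every documented feature is present and testable.

Vectors are NaN-free by contract. When a lead has no detectable S wave the
R/S ratio is imputed with an S amplitude floored at 1e-3 — the amplitude
resolution of a max-abs-normalized segment — rather than a machine-epsilon
floor, which would produce O(1e8) outliers that dominate variance-scaled
kernels. Cross-correlation of two constant (zero-variance) leads is 1 if
they are identical and 0 otherwise.

## Mixup augmentation

Augmented beats are convex combinations of two parents,
`x̂ = λ xᵢ + (1 − λ) xⱼ` with `λ ~ Beta(5, 1.5)` (mean ≈ 0.77); the
dominant parent's label is adopted (`yᵢ` iff `λ > 0.5`) and `λ` itself is
stored as the sample weight, following the convention of the mixup
literature for this task. The default ratio of three augmented samples per
original turns the 2,496-beat database into 7,488 augmented complexes.

In `sublocation` mode the second parent must share the first parent's site
or be one of its anatomical neighbors, preventing mixtures of distant
sites (e.g. an anteroseptal-RV/AMC blend) that would carry a meaningless
label. The default graph follows standard outflow-tract anatomy — the
cusp chain LCC–commissure–RCC, NCC adjacent to LCC and RCC, AMC to LCC
and NCC, the LV summit to LCC and RCC, and the three RVOT sites mutually
adjacent, with no cross-chamber edges; it is an explicit `data.frame`
argument, so users can substitute their own. In `chamber` mode pairing is
unconstrained (standard mixup), including across chambers.

## Classification

`trainSvm` delegates unweighted fits to libsvm (`e1071`). Per-sample
weights — required to carry the mixup λ into training — are supported by
no installed R SVM front-end, so the weighted C-SVM is solved exactly as
its dual quadratic program (box constraints `0 ≤ αᵢ ≤ C wᵢ`) with
`kernlab::ipop`. The two routes agree at unit weights, and duplicating
every sample at half weight reproduces the unweighted decision function,
both verified in the suite. Defaults: `C = 1` and the variance-scaled
kernel width `γ = 1/(p · mean feature variance)`; neither value is
special, and both are exposed.

Cross-validation is stratified 5-fold with plain fold accuracy — balanced
accuracy (the unweighted mean of per-class recalls) is reserved for the
imbalanced clinical-like test sets. CV in hybrid scenarios pools both
sources into every fold (stratified by class only), the simplest reading
consistent with a single training domain.

The exhaustive lead search trains one SVM per non-empty lead subset on the
concatenated raw10 columns (4,095 models for 12 leads) and pools, per
lead, the accuracies of the 2,048 subsets containing it; `fast = TRUE`
switches to a linear kernel to keep the full sweep cheap. Extra-trees
ranking fits `nTrees` single-tree ensembles on the whole training set (no
bootstrap, random split thresholds, `mtry = ⌊√p⌋`) so that per-tree
impurity-decrease importances are observable; their normalized mean and
per-tree dispersion are reported. PCA cumulative variance
(`pcaCumulativeVariance`) documents why 10 bin means per lead and the
top-10 features suffice: the raw10 block of a single lead has rank ≤ 10.

Chamber labels are encoded with LVOT as the first factor level (the
"positive" decision side) throughout.

## Scenarios and the study conditions used in tests

`runScenario` composes: sc1 = simulated (optionally + augmented, with λ
weights), sc2 = clinical-like only, sc3 = clinical-like + simulated.
Record identifiers are seed-qualified and any train/test overlap is an
error.

The test suite runs the statistical claims at reduced but fixed problem
sizes, chosen once as a compromise between statistical resolution and
suite runtime: training databases of 6 × 12 × 4 = 288 beats (4 × 12 × 3
held out), clinical-like cohorts of 60 (training, sc2/sc3) and 120–150
(testing) at `noiseSd` up to 0.2, three repeats per comparison, and the
full 2,496/7,488/4,095 counts wherever the claim is about structure rather
than accuracy. At these conditions simulated training recovers the chamber
of held-out noise-free beats essentially perfectly (≥ 0.95 required), the
noise sweep is flat near 1.0 until the strongest level — the raw10 bin
means average away most stationary noise — and the hybrid scenario is
never worse than small-cohort clinical-only training, the qualitative
ordering of interest.

## Numerical conventions

* 1-based, half-open QRS windows `[onset, offset)` everywhere; `offset`
  may be `T + 1`.
* Fixed lead order I, II, III, aVR, aVL, aVF, V1–V6; all matrices carry
  these rownames and all feature names reference them.
* Signed maximum = value of largest magnitude, first index on ties;
  all-zero signals have polarity +1.
* Bin remainders go to the leading bins; stage seeds derive from the
  global seed by a 31-bit polynomial hash, so stages are independently
  reproducible.
* Serialization writes numbers with 17 significant digits; save/load
  round trips are bit-exact.

## Known limitations

* The generator is phenomenological; its class structure is designed, so
  absolute accuracies on it say nothing about clinical performance (the
  scenario *orderings* are the meaningful output).
* The weighted-SVM dual solve is dense (O(n²) memory) and intended for
  the cohort sizes above, not for tens of thousands of samples.
* The wavelet delineator assumes a single QRS per window; there is no
  P/T-wave handling, rhythm analysis, or multi-beat averaging.
* Nine-class sublocation classification is supported by the labels and
  the mixup mode but is not evaluated as a headline task.
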