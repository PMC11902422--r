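---
title: "Methods and design notes for the semgcurl pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the semgcurl pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind `semgcurl`, the
assumptions they rest on, the parameters a user can turn, and the design
decisions taken where the workflow was genuinely underdetermined. It
states no empirical result that the package's tests and acceptance script
do not themselves compute.

## 1. The analysis problem

Eight sEMG channels are recorded at 1000 Hz while a subject performs six
alternating dumbbell curls (left arm first; one alternating cycle takes
4–5 s, a trial about 30 s). Channels C1, C2, C5, C6 cover the left
biceps, triceps, brachioradialis and flexor carpi; C3, C4, C8, C7 the
right arm in the same order. The analysis must (i) locate each curl in
time, (ii) summarize each located epoch with a fixed 63-value feature
vector, (iii) prune the feature bank to a compact discriminative subset,
and (iv) quantify how well the subset separates two training-level groups
under repeated stratified cross-validation.

## 2. Preprocessing

Every channel is band-pass filtered with a 4th-order Butterworth design
(MATLAB convention: an order-4 prototype yields an order-8 band-pass
transfer function), 20–250 Hz, applied forward and backward
(`signal::filtfilt`) for zero phase. No power-line notch is applied: the
pass band is assumed to have been notch-treated in hardware, and a second
digital notch would remove useful energy. The detection path additionally
half-wave rectifies the two biceps channels and smooths them with a
centred moving average of span 5; edge windows shrink symmetrically so
the output keeps the input length (shrinking windows avoid padding
bias). The
rectified/smoothed signal is used **only** for event detection — features
always come from the filtered, signed signal.

After detection, epoch amplitudes are normalized per (subject, channel)
by the maximum **absolute** sample over all of that subject's epochs on
that channel. The divisor is interpreted as the absolute maximum because
the filtered signal is signed; dividing by the signed maximum could
produce normalized values outside [−1, 1]. The divisor is stored, and the
operation is idempotent and scale-invariant.

## 3. Sample-entropy event detection

For a window `x` of length N, `SampEn(m, r, N) = −ln(A/B)` where B counts
ordered template pairs of length m within Chebyshev distance r, A the
same at length m+1; self-matches are excluded, and both counts use the
N−m templates that admit an extension, so A and B are comparable
(Richman–Moorman convention). Defaults: m = 2, r = 0.25·SD(X) with SD
taken over the **whole trial** — a global tolerance is what makes the
detector work: quiescent windows fluctuate well inside r, so nearly every
template matches and SampEn ≈ 0, while burst windows swing far beyond r
and score high.

The series is computed on windows of 64 samples stepped by 30. Onsets
need 3 consecutive values above the start threshold, offsets 2
consecutive below the end threshold (anti-shake). Thresholds default to
0.02 and 0.01 **times the series maximum**; the threshold factors can
equally be read as absolute levels, so both modes exist
(`threshold_mode`), with relative as default because it adapts to signal
scale. Relative thresholds are undefined on a flat
series, so a contrast guard declares a trial activity-free when
max(series) ≤ 4 × median(series); measured on the package's own
generator, activity-free noise stays below ~2.6 while genuine curl trials
exceed 25, so the guard at 4 has a wide margin on both sides.

Window indices map to samples conservatively: an epoch starts at the
window start of the first above-threshold window of its run and ends at
the window start of the first below-threshold window plus the window
length. This inclusive mapping biases boundaries slightly outward (up to
one window), which trades a little baseline contamination for never
truncating a burst. An onset still open at the trial end is closed at the
final sample and then subjected to the same filters. Accepted epochs must
exceed 1050 samples and have a maximum absolute filtered amplitude above
0.35 × the trial-wide maximum ("0.35·X" is read as 0.35·max|x| over the
trial — the only amplitude scale available at that point). When A or B is
zero the estimator is undefined; the value is capped at
`log((N−m)(N−m−1))` — the largest value a single matched pair among all
ordered pairs could produce — and flagged, never raised mid-pipeline.

Detected biceps intervals are propagated unchanged to the other three
channels of the same arm; only the biceps channels are ever scanned.

## 4. The 63-value feature bank

41 time-domain names and 9 frequency-domain names expand to 63 values:
the order-4 AR model gives 4 coefficients, the spectral moments give 4
values (SM0–SM3 — four moments are emitted because only four reconcile
the 63-value total), and the level-3 wavelet packet gives 8 node
energies. Decisions on the formula-defined features:

* **ASM / ASS** — fractional powers are applied to |xᵢ| (non-integer
  powers of negative samples are undefined); the exponent band
  0.25·N ≤ i ≤ 0.75·N is inclusive, with a single index running over the
  whole epoch. ASS treats "the analysis window" as the full epoch.
* **CARD** — implemented on the **sorted** sample sequence (count of
  adjacent sorted gaps > 0.01), because a literal random shuffle would
  make the feature non-deterministic; a shuffle mode exists behind
  `order = "shuffle"`.
* **LTKEO** — ln Σ(xᵢ² − xᵢ₋₁xᵢ₊₁); a nonpositive sum (e.g. any constant
  sequence) yields a flagged `NaN` sentinel.
* **Spectrum** — plain periodogram of the de-meaned epoch,
  P_j = |FFT|²/N at bins j = 1..⌊N/2⌋ (DC excluded), matching the
  j = 1..Fs/2 convention of the defining sums; MDF, MNF, FR (low/high
  band power ratio, default bands 20–100 / 100–250 Hz), PKF, PSR (power
  within ±10 Hz of the peak), MNP, SM0–SM3 and VCF all derive from this
  one spectrum.
* **AR** — Yule–Walker by default (Burg behind `method`), coefficients in
  the convention x_t = Σ a_k x_{t−k} + e_t.
* **Wavelet packet** — Haar (db1) filters down a full 3-level binary
  tree, zero-padding to even length at each split; the transform is
  orthonormal, so each node's reconstruction norm equals its coefficient
  norm, and the squared node norms sum to the squared epoch norm (an
  invariant the tests assert). Nodes are reported in natural order;
  node (3,4) is `WP5`.
* Features whose exact identity is not fixed by the published catalogs
  (AE, MAS, VARe, VO, LDMA, LDASDA, LCOV, FZC) follow common
  feature-toolbox conventions and are tagged `"interpretation"` in
  `feature_registry()`. Thresholded counters (ZC, SSC, WA, MYOP, CARD)
  default their thresholds to 0.01 on normalized amplitude; note that
  SSC thresholds a *product* of differences, so its threshold carries
  squared amplitude units.

Feature tables are z-scored per (feature, channel), pooled across groups;
zero-variance cells are centred only and flagged, and the stored
parameters make the transform invertible and idempotent.

## 5. Staged feature reduction

Per-channel pooled-variance two-sample t-tests (α = 0.05; Welch behind
`var_equal = FALSE`) give a 63 × 8 p/H matrix. For redundancy, features
are first averaged across the 8 channels within each epoch and every pair
is scored with a one-way single-rater ICC (epochs as targets), computed
from ANOVA mean squares. No multiple-testing correction is applied by
default (a Benjamini-Hochberg option is the natural extension but is
deliberately off, so the per-channel H matrix keeps its plain
per-test meaning).

The three reduction stages are configurable because more than one
reasonable rule exists for each; the defaults are:

1. **Stage 1** keeps features with H = 1 in at least `k_min` consulted
   channels (`k_min` defaults to half the consulted channels, rounded
   up). Method A consults all 8 channels, Method B all but C6 — in every
   stage, so Method B's output is provably invariant to C6's test
   results (a property the tests corrupt-and-check).
2. **Stage 2** groups survivors by **mutual** consistency: greedy
   grouping in registry order where a feature joins a group only if its
   ICC with *every* member exceeds 0.8. Mutual (clique-style) grouping
   was chosen over connected components because the consistency relation
   is explicitly pairwise; components chain together features that are
   not pairwise consistent and, on redundant banks like this one,
   collapse almost everything into one group. Components remain available
   via `group_mode = "component"`. Each group keeps the member with the
   lowest mean p across consulted channels (ties to the lower registry
   index).
3. **Stage 3** keeps the `target_size` (default 12) survivors with the
   lowest mean p.

All thresholds and removal sets (Z1, Z2, Z3) are recorded in the
`selection_result`, and the stages are strictly nested by construction.

## 6. Classification and statistics

Four families: LDA; a quadratic-kernel SVM ("SVM2": polynomial degree 2,
coef0 = 1, cost 1); an RBF SVM ("SVMcore"); and a subspace-discriminant
ensemble (30 LDA learners on random feature subspaces of ⌈d/2⌉, majority
vote). The kernel identities behind the "SVM2"/"SVMcore" names follow common
classifier-app conventions and are fully configurable. Features are already
standardized, so SVM-internal rescaling is disabled. Each of the 20
repeats reshuffles with a derived sub-seed, stratifies folds by class,
and scores accuracy as the mean over folds of (TP+TN)/(P+N); accuracies
are fractions internally, ×100 only at display. Where results are pooled
over channels, the aggregation mode (repeats vs channels × repeats) is
recorded in the report, since pooling conventions differ between
studies.

Accuracy comparisons use dB = |log₁₀ p| of a pooled two-sample t-test;
dB ≤ 1.301 (p ≥ 0.05) flags no significant difference; identical
zero-variance collections take the p = 1 path. The one-way ANOVA across a
feature set stacks epochs × features into long form, and Tukey HSD
pairwise p-values are reported as a symmetric matrix with a null
diagonal; in the two-column case Tukey's q = √2·|t| reduces the adjusted
p to the pooled t-test p, which the tests verify in closed form.

## 7. The synthetic cohort generator

The generator emulates the acquisition design: per trial, six cycles of
length uniform(4, 5) s; the left-arm burst opens each cycle, the
right-arm burst is offset by half a cycle; same-arm channels share
interval timing with muscle-specific amplitude factors (biceps 1.0,
triceps 0.55, brachioradialis 0.7, flexor carpi 0.5). A burst is
band-limited Gaussian noise (Butterworth band of ±35 Hz around the
spectral centre) shaped by a two-lobe raised-cosine envelope — a high
flexion peak followed by a 0.6-scaled extension peak, overlapping so the
inter-lobe dip stays above ~0.65 of the peak and one curl is never split
by the end threshold. Baseline is unit-variance white noise plus a slow
0.4 Hz drift that the band-pass removes. Units are arbitrary: the
normalization stage removes scale.

Default operating point, chosen once as a realistic clean recording and
not revisited: burst amplitude 20× the baseline noise SD (~26 dB, typical
of a well-prepared biceps electrode under load), amateur spectral centre
80 Hz (typical biceps median frequency), burst duration 1.8 s (1 s
flexion + 1 s extension, minus transitions), default class effects
amplitude ratio 1.5 and +15 Hz for the professional group.

Two generator choices deserve explanation because they are driven by the
statistics of the downstream pipeline rather than by physiology:

* **Recording gain vs SNR.** Inter-subject amplitude diversity is
  modelled as a per-(subject, channel) *gain* (lognormal, cv 0.3 between
  subjects, 0.1 between channels) that multiplies baseline noise and
  bursts alike — emulating electrode/skin coupling and amplifier
  differences — while the burst-to-noise ratio itself varies only mildly
  across subjects (cv 0.05). Gain is exactly cancelled by the
  per-subject max-normalization, which is precisely what that
  normalization exists to do.
* **Soft-limited burst peaks and jitter hierarchy.** Burst noise is
  soft-limited at 2.2 SD (tanh compression, as a preamplifier's limited
  range would act). Without it, the per-subject normalization divisor —
  the *maximum* over a subject's 30 epochs — is driven by Gaussian
  extremes and wobbles by several percent per subject, imprinting a
  persistent multiplicative signature on all of that subject's epochs.
  Epoch-level cross-validation then partially *memorizes subjects*
  rather than classes: epochs of a training subject identify their
  held-out siblings, and arbitrary subject-to-group assignments become
  learnable even when the groups are statistically identical. For the
  same reason, within-subject (per-burst) variability — amplitude jitter
  cv 0.05, duration jitter sd 0.15 s, spectral-centre jitter sd 8 Hz —
  is deliberately kept *larger* than between-subject trait variability
  (duration sd 0.01 s, spectral centre sd 0.5 Hz). Under these
  conditions identity class effects yield chance-level accuracy, which
  is what the null-effect checks assert.

  The converse is the important caveat for real data: real subjects
  *do* carry persistent signatures, so epoch-level (trial-shuffled)
  cross-validation on a 10-subject cohort overstates generalization to
  unseen subjects. Passing the package's null-effect tests shows the
  pipeline is statistically sound under exchangeability — it does not
  show that epoch-level CV is free of subject leakage on real
  recordings, where subject-wise validation would be the stricter
  standard.

The generator does not model motor-unit physiology, fatigue dynamics,
electrode motion artefacts, or cross-talk between arms; its jitter
distributions are package choices recorded in the cohort metadata, not
facts about any human population.

## 8. Problem sizes and numerical tolerances

The test suite validates sample entropy against an exhaustive O(N²)
pair-count oracle to 1e-12 on 64-sample windows; formula features against
independent direct-summation/DFT oracles to 1e-9 on ~100 random epochs;
the Haar packet against an explicit orthogonal-matrix construction to
1e-9; and the ICC against hand-coded mean squares to 1e-12. End-to-end
checks use the design's native sizes — 5 trials × 6 cycles per subject
(30 epochs/channel) and ten-subject cohorts (300 epochs/channel) — while
module-level fixtures use 2-trial cohorts (120 epochs/channel), which are
ample for the stage criteria and keep the default test run fast.
Null-effect and effect-strength classification checks run the full
20-repeat, 10-fold protocol on one channel's 300-epoch table, extracting
epochs at ground-truth intervals: criterion-wise they measure the
classification stage, and detection-based epoch accounting is verified
separately.

## 9. Known limitations

* Boundary placement is window-resolution at best: the inclusive mapping
  plus anti-shake adds up to ~2 windows of outward bias, and the shallow
  post-burst entropy decay can add a few steps of offset latency.
* The detector's thresholds were fixed for this protocol (1000 Hz,
  bursts ≳ 1 s, duty cycle ≈ 40%); nothing is claimed for other
  movements or sampling rates, and a low-duty or low-SNR recording can
  leave the global tolerance r too small for a quiet baseline.
* COV and LCOV divide by (near-)zero-mean quantities of filtered sEMG
  and are heavy-tailed; they are retained for catalog completeness and
  usually removed by the selection stages.
* The selection stage sizes depend on the data's redundancy structure;
  only the stage-3 target (12) is enforced, and a configuration that
  cannot reach it errors rather than silently shrinking.
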