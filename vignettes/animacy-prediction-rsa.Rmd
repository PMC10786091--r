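---
title: "Methods: simulating and detecting pre-noun animacy prediction with spatial RSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting pre-noun animacy prediction with spatial RSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(animacyRSA)
```

## Overview

`animacyRSA` studies a single scientific question end to end: can the
animacy constraint carried by a Chinese classifier pre-activate the
coarse-grained semantic category of an upcoming noun, visible as greater
similarity between multichannel EEG patterns following
animate-constraining than inanimate-constraining classifiers *before* the
noun appears? The package contains (i) the experimental design generator,
(ii) a synthetic EEG generator with known ground truth, (iii) the
preprocessing and amplitude statistics of a conventional ERP analysis, and
(iv) the time-resolved spatial representational similarity analysis (RSA)
with cluster-based permutation inference. Because no public data set
accompanies the paradigm, all validation is by construction: the generator
injects effects with known parameters and the analysis must recover them,
stay silent where nothing was injected, and be calibrated under the null.

## The experimental design

Twelve classifiers are split into four subgroups of three (human, animal,
natural object, artifact); human/animal classifiers are
animate-constraining, the others inanimate-constraining. Each classifier
has ten congruent nouns (120 plausible phrases). Incongruent phrases are
created by re-pairing: nouns move to classifiers of the *other subgroup of
the same animacy* (incongruent, animacy-matched; e.g. a human classifier
with an animal noun) or to the paired subgroup of the *opposite* animacy
(incongruent, animacy-mismatched; human ↔ natural object, animal ↔
artifact). This yields 240 distinct classifier–noun combinations — 120
congruent, 60 matched, 60 mismatched — with every noun used exactly twice,
presented in three blocks of 80 trials (40 congruent + 40 incongruent
each).

The pairing scheme fixes only subgroup-level flows; *which* noun goes to
which re-paired classifier is unspecified, so `build_design()` draws a
uniform random allocation under the seed, constrained so each noun is
reused exactly once. Designs scaled down to fewer subgroups or fewer nouns
are supported for testing; when the same-animacy partner subgroup is
absent all re-pairings cross the animacy boundary. Whether trial order is
fixed across participants or redrawn per participant is a configuration
choice: `assign_blocks()` is deterministic under its seed, so callers get
either behaviour by fixing or varying the seed.

Lexical properties of the synthetic items (stroke counts, log corpus
frequencies) are drawn from the same distribution in every subgroup, so
groups are matched in expectation — mirroring the matching checks the
design requires (`group_similarity_test()` on Wu–Palmer and
absolute-difference matrices).

## The generative model for epochs

`simulate_epochs()` builds `subjects × trials × channels × time` arrays
(µV). The default geometry is 25 subjects, 62 channels in an extended
10–20 montage, 500 Hz, and 3,500 ms epochs assembled from the trial
timeline — 500 ms pre-classifier display, 1,000 ms classifier, 1,000 ms
blank interval, 1,000 ms noun — so the axis runs from −2,500 ms to
+1,000 ms with noun onset at t = 0. Samples cover half-open intervals
`[start, end)` everywhere in the package; this convention is stated on
every window argument to avoid off-by-one ambiguity.

A trial's signal is the sum of three components:

1. **Pre-activated item pattern.** Every noun *i* in group *g* (animate /
   inanimate) has a spatial pattern
   `p_i = sqrt(rho_g) * shared_g + sqrt(1 - rho_g) * unique_i`, components
   i.i.d. standard normal per channel, so two patterns of the same group
   correlate at `rho_g` in expectation. During the prediction window
   (default [−240, 0) ms) the trial's noun pattern is raised under a Hann
   taper scaled by `pred_amplitude` (default 1.5 µV). Defaults
   `rho_animate = 0.5`, `rho_inanimate = 0.1` encode the assumption that
   animate concepts share more features; the true magnitude of the
   resulting similarity difference is not an observable of the paradigm,
   so it is treated as a free parameter and swept in tests. Patterns are
   drawn per subject (spatial expression of a concept is
   subject-specific); passing an explicit `patterns` matrix makes them
   common instead.
2. **Graded N400.** A negative deflection under a Hann taper across
   [300, 500) ms post-noun, over a fixed smooth centro-parietal topography
   peaking at CZ (`n400_topography()`), scaled by `n400_amplitude`
   (default 3 µV) times a condition weight: congruent 0, incongruent 1,
   plus an *additional* increment for animacy-mismatch only under
   animate-constraining classifiers (weights 0/1/2 animate, 0/1/1
   inanimate). The equal inanimate weights build in a true null for the
   inanimate mismatch contrast.
3. **Noise and artifacts.** I.i.d. Gaussian noise per channel-sample
   (default SD 10 µV — single-trial EEG scale, giving ≈ 2 µV residual
   noise on 20-trial item averages), optionally AR(1)-correlated along
   time (`ar1`), plus, with probability `artifact_prob` (default 0.046,
   the typical rejected fraction for this kind of recording), a 50 ms
   ±120 µV excursion on one channel that the ±70 µV rejection rule must
   catch.

Classifiers contribute no systematic group-shared pattern of their own:
the similarity effect is attached to noun-group patterns inside the
prediction window, implementing the pre-activation interpretation rather
than a classifier-form confound. Consequently the simulated classifier
interval (−2,000 to −1,000 ms) carries no condition difference, which the
recovery tests exploit as a negative control.

Behavioural latencies exist only for incongruent phrases (the task is to
reject implausible phrases):
`RT = rt_base − rt_mismatch_advantage·[mismatch] + N(0, rt_sd)`, defaults
674 ms base, 22 ms advantage, 195 ms SD, floored at 1 ms, with a 4.7%
incorrect-response rate. `rt_contrast()` reports the match-minus-mismatch
difference (positive = the extra animacy violation speeds the judgement).

What the generator deliberately does **not** emulate: volume-conducted
forward models, eye movement and muscle artifact morphology (so no ICA
stage is needed or provided), 1/f spectra, a net pre-stimulus negative
drift (the
prediction potential is modelled only through its pattern content, so
amplitude tests against zero are expected to be null on synthetic data),
and latency jitter. Passing tests therefore demonstrate the correctness
and calibration of the *analysis* under the stated statistical structure,
not realism of the waveforms.

## Preprocessing

`filter_epochs()` applies zero-phase (forward–backward) Butterworth
filtering — order-2 high-pass at 0.1 Hz cascaded with order-4 low-pass at
30 Hz by default — because ERP latencies are analysed and phase shifts
would bias window statistics. `baseline_correct()` subtracts per-trial,
per-channel window means; the baseline window is a per-analysis parameter
(the classifier-locked convention uses the 500 ms pre-classifier display,
the prediction-potential analysis uses [−300, −200) ms before noun onset)
rather than one hard-wired choice. `reject_artifacts()` drops trials
exceeding ±70 µV on any channel/sample and incongruent trials answered
incorrectly, after filtering and baseline correction — thresholding raw
drifting data would reject trials whose drift the 0.1 Hz high-pass
removes. A subject left without a single trial for some classifier makes
the data set degenerate (such subjects are excluded from studies of this
design) and raises an error rather than propagating empty averages.
Rejection never removes rows from the array; it updates a subjects ×
trials `keep` mask that all downstream reductions honour.

## Amplitude statistics

`mean_amplitude()` averages electrodes × window samples × kept trials into
subject × condition cells. The prediction-potential analysis uses nine
fronto-central electrodes (FC1, FCZ, FC2, C1, CZ, C2, CP1, CPZ, CP2) over
[−200, 0) ms; the N400 analysis uses nine scalp ROIs over [300, 500) ms.
`rm_anova()` is the standard fully-within-subject stratified decomposition
(`aov` with `Error(subject/(A*B*C))`); no sphericity correction is applied
by default. ROI contrasts are paired t tests BH-FDR corrected within each
contrast family (`fdr_bh()`, step-up). Degenerate zero-variance inputs are
flagged rather than silently propagated: a zero-variance, zero-mean
difference reports t = 0, p = 1.

## Time-resolved spatial RSA and cluster inference

For each subject, `item_erps()` averages surviving trials per classifier
(pre-noun analysis: all of the classifier's trials; after-noun analysis:
its ten congruent nouns). At every time point the analysis correlates
(Pearson) the channel vectors of all 15 within-group classifier pairs per
condition and averages raw r values into r̄(t) per subject and condition.
Raw averaging (not Fisher-z) is the primary definition; pairwise r values
at a time point with a zero-variance pattern are undefined and are
excluded from the pair mean and counted, never coerced to ±1. The EEG
vector is spatial only — 62 channels at one time point.

`condition_contrast_timecourse()` runs a paired t test across subjects at
each time point (df = n − 1); `find_critical_windows()` collects maximal
contiguous runs exceeding the uncorrected two-sided threshold (default
α = 0.05), each with its summed t. Degenerate time points are
sub-threshold and break runs; when several candidate windows emerge, all
are reported, each evaluated against its own null.

`permutation_cluster_test()` shuffles condition labels within participant,
which for a two-condition paired design is exactly a random sign flip of
each subject's difference timecourse. Two null constructions are offered:

* **`max_cluster` (default).** Each permutation re-runs cluster forming on
  the permuted t series over the whole analysis axis and contributes its
  maximum |summed t| (0 if no cluster forms). Observed windows are
  compared against this common maximum-statistic distribution. Because
  the null re-enacts the window *search*, this controls the family-wise
  error of the whole procedure — the package's experiment-level inference.
* **`within_window`.** Each permutation sums permuted t values inside the
  fixed observed window — the procedure as often described in the ERP
  literature. With the window location chosen by thresholding the
  *observed* contrast, this null ignores the selection step: under a
  global null some window almost always forms by chance and is then
  declared significant, so the variant is severely anti-conservative for
  unrestricted searches. It is exact only for windows fixed a priori (the
  test suite verifies its p values are uniform in that setting) and is
  retained for method-faithful comparison.

Significance is two-tailed: `p = (1 + #{null ≥ |observed|}) / (B + 1)`,
declared at p ≤ α ("outside the central 95% range" for α = 0.05), B =
1,000 label shuffles by default. All permutation draws derive from the
experiment seed, so inference is exactly reproducible.

## Taxonomy similarity

`wu_palmer()` implements `2·depth(LCS)/(depth(a)+depth(b))` with the
original counting convention root depth = 1 — stated explicitly because
the value depends on it. The concept hierarchy the original stimuli were
scored against is a proprietary lexical database, so the package ships a
small synthetic taxonomy (`toy_taxonomy()`, mirrored as a plain-text edge
list in `inst/extdata/toy_taxonomy_synthetic.tsv`) engineered to have the
two structural properties the design relies on: classifier concepts of
both constraints sit at symmetric depths (mean within-group similarities
are exactly equal, 0.6 each), while animate noun concepts share denser
ancestry than inanimate ones (each inanimate noun gets a private subtype
level; mean within-animate 0.529 vs within-inanimate 0.441). Validation of
this module is structural — oracle equivalence of the formula and of the
group comparison — not reproduction of any particular published matrix.
Within-group pairwise values share items and are not independent; the
two-sample comparison (Welch by default) is the conventional screening
check, flagged as such.

## Validation design and study sizes

The test suite validates three layers, with simulation sizes chosen to
keep the full suite at desk scale:

* **Oracle equivalence.** Every statistical primitive (Pearson r, paired
  t, summed cluster t, BH-FDR, Wu–Palmer, amplitude rejection) is checked
  against an independent brute-force or closed-form computation on small
  inputs, and the sign-flip permutation p for 4 subjects is checked
  against exhaustive enumeration of all 2⁴ label assignments.
* **Parameter recovery.** Twenty simulated experiments at the study's
  scale (25 subjects × 62 channels × 500 Hz over the [−2,000, 0) ms
  pre-noun axis, rho 0.5 vs 0.1, 10 µV noise) must yield a significant
  cluster overlapping the [−240, 0) ms prediction window in at least 80%
  of runs and a significant cluster in the classifier interval
  (−2,000 to −1,000 ms, where nothing was injected) in at most 10%. These
  runs omit the artifact/rejection stage, whose correctness is established
  separately by the exhaustive-scan oracle; this keeps the recovery runs
  focused on the inference chain.
* **Null calibration.** Two hundred replicate experiments with
  `rho_animate = rho_inanimate = 0.3` (25 subjects, 25 channels, 100 Hz
  over [−1,000, 0) ms — the inference machinery is size-agnostic, so the
  null study uses a reduced grid) must produce significant clusters at a
  rate inside the binomial 95% bounds around the nominal 0.05.
* **ERP pattern recovery.** One experiment at full defaults (with
  artifacts and rejection) must show the graded N400: the
  incongruent-minus-congruent contrast negative and FDR-significant at all
  nine ROIs, the additional animacy-mismatch effect significant under
  animate-constraining and non-significant under inanimate-constraining
  classifiers, and the corresponding ANOVA effects. Because the inanimate
  contrast is a true null tested at the 5% level, this check carries the
  usual 5% false-alarm risk by construction.

## Known limitations

* The generator's noise is white (optionally AR(1)); real EEG has 1/f
  structure and spatial correlation, which would lengthen chance cluster
  runs. The `max_cluster` null adapts to whatever autocorrelation the data
  have, but absolute power figures from these simulations do not transfer
  to real recordings.
* The similarity difference magnitude is a free parameter; recovery rates
  quantify sensitivity at the chosen setting, not the paradigm's real
  effect size.
* `within_window` permutation inference is valid only for pre-registered
  windows; results from data-selected windows should use the default
  `max_cluster` null.
* Wu–Palmer values depend on the packaged synthetic taxonomy's shape;
  they are reproducible bit-exactly but are not estimates of any real
  lexicon's similarities.
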