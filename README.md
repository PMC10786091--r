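# animacyRSA

Simulation and analysis tools for studying the **prediction of
coarse-grained semantic features** — specifically animacy — during language
comprehension with EEG.

## The scientific problem

Mandarin Chinese classifiers are obligatory morphemes between a numeral and
a noun, and many of them constrain the *animacy* of the noun they license
(some classifiers only modify humans or animals, others only natural
objects or artifacts). Because a bare numeral–classifier context does not
predict any specific word, it offers a clean test of whether comprehenders
pre-activate *coarse-grained* semantic features of upcoming nouns rather
than individual lexical items.

The experimental logic: animate concepts share more semantic features than
inanimate concepts, so spatial patterns of neural activity evoked in
association with animate items are more similar to one another than
patterns for inanimate items. If an animacy-constraining classifier makes
comprehenders pre-activate the animacy category of the upcoming noun, then
*before the noun appears* the multichannel EEG patterns following
animate-constraining classifiers should already be more similar to one
another than those following inanimate-constraining classifiers.

`animacyRSA` implements that full analysis chain, together with a
synthetic-data generator with known ground truth so every inferential step
can be validated by parameter recovery and null calibration:

1. **Stimulus design** (`synthetic_lexicon()`, `build_design()`,
   `assign_blocks()`): 12 classifiers (6 animate-constraining — 3 human, 3
   animal; 6 inanimate-constraining — 3 natural object, 3 artifact), each
   with 10 congruent nouns, re-paired into 60 incongruent animacy-matched
   and 60 incongruent animacy-mismatched combinations — 240 distinct
   classifier–noun trials in 3 blocks of 80.
2. **Synthetic epochs** (`sim_params()`, `simulate_epochs()`): subjects ×
   trials × channels × time arrays (default 25 × 240 × 62 × 500 Hz, 3,500 ms
   epochs with noun onset at t = 0) containing a pre-noun item-pattern
   signal with group-level similarity structure, a graded centro-parietal
   N400, behavioural latencies, noise and artifacts.
3. **Preprocessing** (`filter_epochs()`, `baseline_correct()`,
   `reject_artifacts()`): zero-phase 0.1–30 Hz band-pass, window-mean
   baseline subtraction, ±70 µV amplitude and incorrect-response rejection.
4. **Amplitude statistics** (`mean_amplitude()`, `erp_t_test()`,
   `rm_anova()`, `fdr_bh()`, `n400_roi_contrasts()`, `rt_contrast()`):
   prediction-potential window tests, the 2 × 3 × 9 repeated-measures ANOVA
   (classifier type × congruency × ROI) and FDR-corrected ROI contrasts.
5. **Time-resolved spatial RSA** (`similarity_timecourses()`,
   `rsa_cluster_analysis()`): per subject and time point, Pearson
   correlations between the 62-channel patterns of every within-group item
   pair (6·5/2 = 15 pairs per condition), averaged into a similarity
   timecourse r̄(t); a paired t contrast across subjects at each time point;
   maximal supra-threshold runs at uncorrected p < .05; and a within-subject
   sign-flip permutation test of each window's summed t statistic.
6. **Taxonomy similarity** (`wu_palmer()`, `pairwise_matrix()`,
   `group_similarity_test()`): Wu–Palmer similarity
   `2·depth(LCS(a,b)) / (depth(a) + depth(b))` (root depth 1) on a packaged
   synthetic concept taxonomy, used to verify that stimulus groups are
   matched on semantic and lexical similarity.

## Worked example

```r
library(animacyRSA)

lex    <- synthetic_lexicon(seed = 1)
design <- assign_blocks(build_design(lex$classifiers, lex$nouns, seed = 1),
                        seed = 1)
table(design$congruency)
#>                    congruent    incongruent_animacy_match
#>                          120                           60
#> incongruent_animacy_mismatch
#>                           60

## a scaled-down experiment: 15 subjects, 40 channels, 100 Hz, analysing
## the last second before noun onset
params <- sim_params(n_subjects = 15, n_channels = 40, fs = 100,
                     epoch_span = c(-1000, 0), n400_amplitude = 0,
                     artifact_prob = 0)
res <- simulate_rsa_experiment(params, design = design, seed = 7,
                               reject = FALSE, n_permutations = 1000)
subset(res$clusters, significant,
       c(start_ms, end_ms, n_points, summed_t, p_value))
#>   start_ms end_ms n_points summed_t     p_value
#> 5     -150    -80        8 28.58535 0.000999001
```

The generator injected a within-group pattern correlation of 0.5 for
animate versus 0.1 for inanimate noun groups inside the prediction window
[−240, 0) ms; the pipeline recovers a significant cluster of greater
animate-than-inanimate similarity inside that window (permutation
p ≈ 0.001 with 1,000 label shuffles) and none elsewhere.

Taxonomy similarity on the packaged synthetic concept tree:

```r
tax <- toy_taxonomy(lex)$tax
wu_palmer(tax, "cl_human_1", "cl_human_2")     # same subgroup
#> [1] 0.75
wu_palmer(tax, "cl_human_1", "cl_artifact_1")  # across animacy
#> [1] 0.25
```

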