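Package: animacyRSA
Title: Simulation and Representational Similarity Analysis of Pre-Noun
    Animacy Prediction in EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the pre-activation of coarse-grained semantic
    (animacy) features during language comprehension with
    electroencephalography. Generates classifier-noun experimental designs
    with congruent and incongruent (animacy-matched and animacy-mismatched)
    pairings, simulates epoched multichannel EEG with a known
    spatial-similarity structure, a pre-noun prediction potential, a graded
    centro-parietal N400 and behavioural response latencies, and analyses
    the result: amplitude statistics (prediction potential tests, repeated
    measures ANOVA across regions of interest, FDR-corrected contrasts),
    time-resolved spatial representational similarity analysis with
    cluster-forming and sign-flip permutation inference, and Wu-Palmer
    taxonomy similarity for stimulus matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
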