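# Shared fixtures, built in code at test time.

# the standard 12-classifier / 120-noun design
std_design <- function(seed = 1) {
  lex <- synthetic_lexicon(seed = seed)
  assign_blocks(build_design(lex$classifiers, lex$nouns, seed = seed),
                seed = seed)
}

# scaled design: one classifier per subgroup, two nouns each (16 trials)
small_design <- function(seed = 1) {
  lex <- synthetic_lexicon(n_per_subgroup = 1, nouns_per_classifier = 2,
                           seed = seed)
  build_design(lex$classifiers, lex$nouns, seed = seed)
}

# hand-built minimal design table for container-level tests that only need
# trial metadata (not a valid re-pairing scheme)
toy_design <- function(n, classifier = "clA", congruency = "congruent",
                       animacy = "animate") {
  d <- data.frame(
    trial_index = seq_len(n),
    classifier_id = rep_len(classifier, n),
    noun_id = paste0("n", seq_len(n)),
    animacy_constraint = rep_len(animacy, n),
    classifier_subgroup = "x", noun_subgroup = "x",
    noun_animacy = rep_len(animacy, n),
    congruency = rep_len(congruency, n),
    block = 1L, stringsAsFactors = FALSE
  )
  cls <- unique(data.frame(id = d$classifier_id,
                           animacy = d$animacy_constraint,
                           stringsAsFactors = FALSE))
  structure(d, classifiers = cls, class = c("design_table", "data.frame"))
}

# epoch_set around a hand-built subjects x trials x channels x time array
toy_epochs <- function(arr, fs = 100, t_start = 0, design = NULL) {
  d <- dim(arr)
  times <- seq(t_start, by = 1000 / fs, length.out = d[4])
  if (is.null(design)) design <- toy_design(d[2])
  epoch_set(arr, times, fs, montage_62(d[3]), design)
}
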