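#' Subgroup re-pairing scheme for incongruent trials
#'
#' Animacy-matched re-pairings swap nouns between the two subgroups of the
#' same animacy (human <-> animal, natural_object <-> artifact); mismatched
#' re-pairings cross the animacy boundary (human <-> natural_object,
#' animal <-> artifact).
#' @keywords internal
.match_partner <- c(
  human = "animal", animal = "human",
  natural_object = "artifact", artifact = "natural_object"
)

#' @keywords internal
.mismatch_partner <- c(
  human = "natural_object", natural_object = "human",
  animal = "artifact", artifact = "animal"
)

.subgroup_animacy <- c(
  human = "animate", animal = "animate",
  natural_object = "inanimate", artifact = "inanimate"
)

.congruency_levels <- c("congruent", "incongruent_animacy_match",
                        "incongruent_animacy_mismatch")

#' Generate a synthetic classifier-noun lexicon
#'
#' Creates lexical items for a classifier-noun phrase experiment: classifiers
#' split into four subgroups (human- and animal-modifying classifiers are
#' animate-constraining; natural-object- and artifact-modifying classifiers
#' are inanimate-constraining) and, for each classifier, its set of
#' semantically congruent nouns. Visual complexity (stroke counts) and corpus
#' log frequency are drawn from the same distribution in every subgroup, so
#' the groups are matched on these properties in expectation.
#'
#' @param n_per_subgroup classifiers per subgroup (default 3, giving 12).
#' @param nouns_per_classifier congruent nouns per classifier (default 10).
#' @param stroke_lambda Poisson mean of the (shifted) stroke-count
#'   distribution; stroke counts are `1 + Poisson(stroke_lambda - 1)`.
#' @param logfreq_mean,logfreq_sd Gaussian parameters of log10 corpus
#'   frequency per million.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return list with data.frames `classifiers` and `nouns`. Nouns carry a
#'   `classifier_id` column naming their congruent classifier.
#' @export
synthetic_lexicon <- function(n_per_subgroup = 3, nouns_per_classifier = 10,
                              stroke_lambda = 8, logfreq_mean = 2,
                              logfreq_sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subgroups <- names(.subgroup_animacy)
  draw_lex <- function(n) {
    data.frame(
      stroke_count = 1L + stats::rpois(n, stroke_lambda - 1),
      log_frequency = stats::rnorm(n, logfreq_mean, logfreq_sd)
    )
  }
  cls <- do.call(rbind, lapply(subgroups, function(g) {
    cbind(data.frame(
      id = sprintf("cl_%s_%d", g, seq_len(n_per_subgroup)),
      role = "classifier", animacy = .subgroup_animacy[[g]], subgroup = g,
      stringsAsFactors = FALSE
    ), draw_lex(n_per_subgroup))
  }))
  nouns <- do.call(rbind, lapply(seq_len(nrow(cls)), function(i) {
    cbind(data.frame(
      id = sprintf("noun_%s_%02d", sub("^cl_", "", cls$id[i]),
                   seq_len(nouns_per_classifier)),
      role = "noun", animacy = cls$animacy[i], subgroup = cls$subgroup[i],
      classifier_id = cls$id[i], stringsAsFactors = FALSE
    ), draw_lex(nouns_per_classifier))
  }))
  rownames(cls) <- rownames(nouns) <- NULL
  list(classifiers = cls, nouns = nouns)
}

.validate_lexicon <- function(classifiers, nouns) {
  need_c <- c("id", "animacy", "subgroup")
  if (!all(need_c %in% names(classifiers)))
    stop("classifiers must have columns: ", paste(need_c, collapse = ", "))
  if (!all(c(need_c, "classifier_id") %in% names(nouns)))
    stop("nouns must have columns id, animacy, subgroup, classifier_id")
  if (anyDuplicated(classifiers$id)) stop("duplicate classifier ids")
  if (anyDuplicated(nouns$id)) stop("duplicate noun ids")
  bad <- .subgroup_animacy[classifiers$subgroup] != classifiers$animacy
  if (any(is.na(bad)) || any(bad))
    stop("classifier subgroup/animacy inconsistent")
  bad <- .subgroup_animacy[nouns$subgroup] != nouns$animacy
  if (any(is.na(bad)) || any(bad)) stop("noun subgroup/animacy inconsistent")
  if (!all(nouns$classifier_id %in% classifiers$id))
    stop("nouns reference unknown classifiers")
  ns <- table(nouns$classifier_id)[classifiers$id]
  if (length(unique(as.integer(ns))) != 1L)
    stop("design error: every classifier needs the same number of nouns")
  cn <- merge(nouns, classifiers, by.x = "classifier_id", by.y = "id",
              suffixes = c("", ".cl"))
  if (any(cn$subgroup != cn$subgroup.cl))
    stop("design error: congruent noun subgroup must match its classifier")
  invisible(as.integer(ns[1]))
}

#' Build the full classifier-noun trial design
#'
#' Combines each classifier with its congruent nouns and then re-pairs every
#' noun once with a different classifier to create the incongruent trials:
#' half of each classifier's incongruent trials take nouns from the other
#' subgroup of the same animacy (incongruent, animacy-match) and half from
#' the paired subgroup of the opposite animacy (incongruent,
#' animacy-mismatch). With 12 classifiers and 10 nouns each this yields 240
#' distinct classifier-noun combinations: 120 congruent, 60 animacy-matched
#' incongruent and 60 animacy-mismatched incongruent, with every noun used
#' exactly twice (once congruent, once incongruent).
#'
#' Which noun goes to which re-paired classifier is not constrained beyond
#' the subgroup scheme; it is drawn as a uniform random allocation under the
#' seed. Designs scaled down to fewer subgroups are supported: if the
#' same-animacy partner subgroup has no classifiers, all re-pairings cross
#' the animacy boundary.
#'
#' @param classifiers,nouns lexicon data.frames as from [synthetic_lexicon()].
#' @param seed optional integer seed for the random re-pairing.
#' @return a `design_table`: data.frame with one row per trial (columns
#'   `trial_index`, `classifier_id`, `noun_id`, `animacy_constraint`,
#'   `classifier_subgroup`, `noun_subgroup`, `congruency`, `block`) and the
#'   lexicon attached as attributes `classifiers` and `nouns`.
#' @export
build_design <- function(classifiers, nouns, seed = NULL) {
  n <- .validate_lexicon(classifiers, nouns)
  if (!is.null(seed)) set.seed(seed)
  groups <- split(classifiers, classifiers$subgroup)
  sizes <- vapply(groups, nrow, 0L)
  if (length(unique(sizes)) != 1L)
    stop("design error: unequal classifier counts across subgroups")
  if (length(unique(.subgroup_animacy[names(groups)])) < 2L)
    stop("design error: both animacy constraints must be present")

  congruent <- data.frame(
    classifier_id = nouns$classifier_id, noun_id = nouns$id,
    congruency = "congruent", stringsAsFactors = FALSE
  )

  ## Decide, per recipient subgroup, how many nouns come from each donor.
  present <- names(groups)
  incong <- vector("list", length(present))
  names(incong) <- present
  for (g in present) {
    has_match <- .match_partner[[g]] %in% present
    n_match <- if (has_match) n %/% 2L else 0L
    if (has_match && n %% 2L != 0L)
      stop("design error: nouns per classifier must be even to split ",
           "re-pairings between match and mismatch subgroups")
    if (!(.mismatch_partner[[g]] %in% present))
      stop("design error: no opposite-animacy subgroup to re-pair with")
    incong[[g]] <- c(match = n_match, mismatch = n - n_match)
  }

  ## Allocate each donor subgroup's nouns: shuffled, then dealt to the
  ## classifiers of the two recipient subgroups.
  take <- function(donor_pool, recipients, per_cl, congruency) {
    if (per_cl == 0L) return(NULL)
    k <- length(recipients)
    ids <- donor_pool[seq_len(k * per_cl)]
    data.frame(
      classifier_id = rep(recipients, each = per_cl), noun_id = ids,
      congruency = congruency, stringsAsFactors = FALSE
    )
  }
  rows <- list(congruent)
  for (donor in present) {
    pool <- sample(nouns$id[nouns$subgroup == donor])
    mg <- .match_partner[[donor]]    # recipients using these as match nouns
    xg <- .mismatch_partner[[donor]] # recipients using these as mismatch
    n_match_used <- 0L
    if (mg %in% present && incong[[mg]][["match"]] > 0L) {
      rec <- groups[[mg]]$id
      n_match_used <- length(rec) * incong[[mg]][["match"]]
      rows[[length(rows) + 1L]] <-
        take(pool, rec, incong[[mg]][["match"]], "incongruent_animacy_match")
    }
    rec <- groups[[xg]]$id
    rows[[length(rows) + 1L]] <-
      take(pool[seq.int(n_match_used + 1L, length(pool))], rec,
           incong[[xg]][["mismatch"]], "incongruent_animacy_mismatch")
  }
  trials <- do.call(rbind, rows)

  cl_idx <- match(trials$classifier_id, classifiers$id)
  no_idx <- match(trials$noun_id, nouns$id)
  design <- data.frame(
    trial_index = seq_len(nrow(trials)),
    classifier_id = trials$classifier_id,
    noun_id = trials$noun_id,
    animacy_constraint = classifiers$animacy[cl_idx],
    classifier_subgroup = classifiers$subgroup[cl_idx],
    noun_subgroup = nouns$subgroup[no_idx],
    noun_animacy = nouns$animacy[no_idx],
    congruency = trials$congruency,
    block = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(design[, c("classifier_id", "noun_id")]))
    stop("design error: duplicate classifier-noun combination")
  if (any(table(design$noun_id) != 2L))
    stop("design error: every noun must be used exactly twice")
  structure(design, classifiers = classifiers, nouns = nouns,
            class = c("design_table", "data.frame"))
}

#' Assign trials to presentation blocks
#'
#' Splits the design into `n_blocks` blocks balanced on congruency (each
#' block receives equal numbers of congruent and incongruent trials; when the
#' two incongruent conditions divide evenly they are balanced as well) and
#' randomises presentation order within each block. The same seed reproduces
#' the identical assignment; the multiset of trials is preserved.
#'
#' @param design a `design_table` from [build_design()].
#' @param n_blocks number of blocks (default 3).
#' @param seed optional integer seed.
#' @return the design, rows reordered to presentation order, with `block`
#'   filled in.
#' @export
assign_blocks <- function(design, n_blocks = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(design)
  if (n %% n_blocks != 0L)
    stop("trial count ", n, " not divisible by ", n_blocks, " blocks")
  strata <- design$congruency
  if (any(table(strata) %% n_blocks != 0L)) {
    strata <- ifelse(design$congruency == "congruent", "congruent",
                     "incongruent")
    if (any(table(strata) %% n_blocks != 0L))
      stop("congruent/incongruent counts not divisible by n_blocks")
  }
  block <- integer(n)
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    block[idx] <- rep_len(seq_len(n_blocks), length(idx))
  }
  out <- design
  out$block <- block
  ord <- order(block, sample.int(n))  # random order within block
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, classifiers = attr(design, "classifiers"),
            nouns = attr(design, "nouns"),
            class = c("design_table", "data.frame"))
}

#' All unordered within-group item pairs
#'
#' Enumerates the C(n, 2) unordered pairs of distinct item ids in a
#' deterministic order (the order of first appearance), e.g. 6 items give
#' 6*5/2 = 15 pairs.
#'
#' @param item_ids vector of at least two distinct ids.
#' @return two-column character matrix, one row per pair.
#' @export
enumerate_within_pairs <- function(item_ids) {
  ids <- unique(as.character(item_ids))
  if (length(ids) < 2L) stop("need at least 2 distinct items")
  t(utils::combn(ids, 2L))
}

#' Write / read a design table as TSV
#'
#' @param design a `design_table`.
#' @param path file path.
#' @return `read_design_tsv` returns a data.frame with the trial columns
#'   (lexicon attributes are not round-tripped).
#' @export
write_design_tsv <- function(design, path) {
  cols <- c("classifier_id", "noun_id", "animacy_constraint",
            "classifier_subgroup", "noun_subgroup", "congruency", "block",
            "trial_index")
  utils::write.table(as.data.frame(design)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
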