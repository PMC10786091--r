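#' Electrode sets used by the amplitude analyses
#'
#' `pred_electrodes()` returns the nine fronto-central electrodes where the
#' prediction potential is measured. `default_rois()` returns the nine
#' regions of interest spanning the scalp used by the N400 analysis.
#'
#' @return character vector / named list of character vectors.
#' @export
pred_electrodes <- function() {
  c("FC1", "FCZ", "FC2", "C1", "CZ", "C2", "CP1", "CPZ", "CP2")
}

#' @rdname pred_electrodes
#' @export
default_rois <- function() {
  list(
    left_anterior = c("F3", "F5", "FC3"),
    middle_anterior = "FZ",
    right_anterior = c("F4", "F6", "FC4"),
    left_middle = c("C3", "C5"),
    middle_middle = "CZ",
    right_middle = c("C4", "C6"),
    left_posterior = c("P3", "P5"),
    middle_posterior = "PZ",
    right_posterior = c("P4", "P6")
  )
}

.electrode_idx <- function(epochs, electrodes) {
  idx <- match(toupper(electrodes), toupper(epochs$channels))
  if (anyNA(idx))
    stop("unknown electrode(s): ",
         paste(electrodes[is.na(idx)], collapse = ", "))
  idx
}

#' Mean amplitude per subject and condition cell
#'
#' Averages the signal over the listed electrodes and all samples in the
#' half-open window `[start, end)` ms, then averages over the kept trials of
#' each subject x condition cell.
#'
#' @param epochs an `epoch_set`.
#' @param window_ms `c(start, end)` in ms.
#' @param electrodes channel labels (case-insensitive).
#' @param group_by design columns defining the condition cells.
#' @return data.frame `subject`, grouping columns, `mean_uv`, `n_trials`.
#' @export
mean_amplitude <- function(epochs, window_ms, electrodes,
                           group_by = c("animacy_constraint", "congruency")) {
  ch <- .electrode_idx(epochs, electrodes)
  ti <- .window_idx(epochs$times, window_ms)
  if (!all(group_by %in% names(epochs$design)))
    stop("unknown design column(s) in group_by")
  ## per subject x trial scalar: mean over electrodes and window samples
  x <- epochs$data[, , ch, ti, drop = FALSE]
  stm <- rowMeans(x, dims = 2)
  d <- dim(epochs$keep)
  cells <- interaction(epochs$design[group_by], drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(seq_len(d[1]), function(s) {
    k <- epochs$keep[s, ]
    agg <- tapply(stm[s, k], cells[k], mean)
    n <- tapply(rep(1L, sum(k)), cells[k], sum)
    labs <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    df <- data.frame(subject = s, labs, mean_uv = as.numeric(agg),
                     n_trials = as.integer(n), stringsAsFactors = FALSE)
    names(df)[1 + seq_along(group_by)] <- group_by
    df
  }))
  rownames(out) <- NULL
  out
}

#' Student t test returning a tidy result
#'
#' One-sample test against zero or paired test of two equal-length vectors,
#' with `df = n - 1` and a two-sided p value. Zero variance is flagged as a
#' degenerate result instead of an error.
#'
#' @param values_a numeric vector.
#' @param values_b optional second vector for `mode = "paired"`.
#' @param mode `"one_sample_vs_zero"` or `"paired"`.
#' @return one-row data.frame: `statistic`, `df`, `p_value`, `estimate`
#'   (mean or mean difference), `direction` (-1/0/1), `degenerate`.
#' @export
erp_t_test <- function(values_a, values_b = NULL,
                       mode = c("one_sample_vs_zero", "paired")) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (is.null(values_b) || length(values_b) != length(values_a))
      stop("paired mode requires values_b of equal length")
    x <- values_a - values_b
  } else {
    x <- values_a
  }
  n <- length(x)
  if (n < 2L) stop("need n >= 2")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    ## zero variance: an exactly-zero effect gives t = 0, p = 1; a nonzero
    ## constant effect has no finite t -- both are flagged degenerate
    return(data.frame(statistic = if (m == 0) 0 else sign(m) * Inf,
                      df = n - 1,
                      p_value = if (m == 0) 1 else 0,
                      estimate = m, direction = sign(m), degenerate = TRUE))
  }
  tt <- m / (s / sqrt(n))
  data.frame(statistic = tt, df = n - 1,
             p_value = 2 * stats::pt(-abs(tt), n - 1),
             estimate = m, direction = sign(m), degenerate = FALSE)
}

#' Repeated-measures ANOVA on a subject x condition amplitude table
#'
#' Fully within-subject analysis of variance via the standard
#' `aov(dv ~ A*B*... + Error(subject/(A*B*...)))` stratified decomposition,
#' requiring a complete balanced design (exactly one observation per
#' subject x cell). No sphericity correction is applied.
#'
#' @param table data.frame as returned by [mean_amplitude()] (or any table
#'   with a subject column, factor columns and a numeric response).
#' @param factors character vector of within-subject factor column names.
#' @param dv response column name (default `"mean_uv"`).
#' @param subject subject column name.
#' @return data.frame with one row per main effect / interaction:
#'   `effect`, `df1`, `df2`, `F`, `p_value`.
#' @export
rm_anova <- function(table, factors, dv = "mean_uv", subject = "subject") {
  if (!all(c(factors, dv, subject) %in% names(table)))
    stop("missing columns in table")
  tab <- table
  tab[[subject]] <- factor(tab[[subject]])
  for (f in factors) tab[[f]] <- factor(tab[[f]])
  counts <- table(tab[c(subject, factors)])
  if (any(counts != 1L))
    stop("design not complete/balanced: need exactly one value per ",
         "subject x cell")
  rhs <- paste(factors, collapse = " * ")
  fml <- stats::as.formula(sprintf("%s ~ %s + Error(%s/(%s))",
                                   dv, rhs, subject, rhs))
  fit <- stats::aov(fml, data = tab)
  out <- list()
  for (stratum in summary(fit)) {
    st <- stratum[[1]]
    eff <- trimws(rownames(st))
    res <- eff == "Residuals"
    if (all(res)) next
    out[[length(out) + 1L]] <- data.frame(
      effect = gsub(":", " x ", eff[!res]),
      df1 = st[!res, "Df"], df2 = st[res, "Df"],
      F = st[!res, "F value"], p_value = st[!res, "Pr(>F)"],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment; a hypothesis is selected when its adjusted p
#' value is at most `q`.
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @param q target FDR level (default 0.05).
#' @return data.frame `p`, `p_adjusted`, `selected`, in input order.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  data.frame(p = p_values, p_adjusted = adj, selected = adj <= q)
}

#' Simulate and reduce one amplitude-analysis experiment
#'
#' Generates the experiment subject by subject, applies artifact /
#' incorrect-response rejection, and reduces each subject to the ROI
#' amplitude table before the next subject is drawn (memory stays bounded by
#' one subject's epochs). Returns the stacked amplitude table and the
#' behaviour table for downstream [rm_anova()], [n400_roi_contrasts()] and
#' [rt_contrast()].
#'
#' @param params a `sim_params` list (the epoch span must cover
#'   `window_ms`).
#' @param design optional `design_table`; default builds the standard
#'   design under the same seed.
#' @param seed integer seed for the whole experiment.
#' @param window_ms,rois passed to [roi_amplitude_table()].
#' @param reject apply rejection (default TRUE).
#' @return list: `amplitudes` (data.frame), `behavior` (data.frame),
#'   `design`.
#' @export
simulate_erp_experiment <- function(params, design = NULL, seed = 1,
                                    window_ms = c(300, 500),
                                    rois = default_rois(), reject = TRUE) {
  set.seed(seed)
  if (is.null(design)) {
    lex <- synthetic_lexicon()
    design <- assign_blocks(build_design(lex$classifiers, lex$nouns))
  }
  tabs <- vector("list", params$n_subjects)
  behs <- vector("list", params$n_subjects)
  for (s in seq_len(params$n_subjects)) {
    ep <- simulate_epochs(design, params, n_subjects = 1)
    beh <- simulate_behavior(design, params, n_subjects = 1)
    if (reject) ep <- reject_artifacts(ep, beh)$epochs
    tabs[[s]] <- roi_amplitude_table(ep, window_ms, rois,
                                     subject_offset = s - 1L)
    beh$subject <- s
    behs[[s]] <- beh
  }
  list(amplitudes = do.call(rbind, tabs), behavior = do.call(rbind, behs),
       design = design)
}

#' Behavioural response-latency contrast
#'
#' Compares response latencies of the two incongruent conditions on correct
#' trials. The reported difference is animacy-match minus animacy-mismatch,
#' so a positive value means the additional animacy violation speeded the
#' judgement.
#'
#' @param behavior behaviour table (see [simulate_behavior()]).
#' @param mode `"by_subject"` (paired t on subject means) or `"pooled"`
#'   (Welch t on trial latencies).
#' @return list: `mean_match`, `mean_mismatch`, `difference_ms`, `test`
#'   (a tidy test result).
#' @export
rt_contrast <- function(behavior, mode = c("by_subject", "pooled")) {
  mode <- match.arg(mode)
  b <- behavior[behavior$correct &
                  behavior$congruency != "congruent", , drop = FALSE]
  conds <- c("incongruent_animacy_match", "incongruent_animacy_mismatch")
  if (!all(conds %in% b$congruency))
    stop("both incongruent conditions must be present")
  m <- tapply(b$rt_ms, b$congruency, mean)[conds]
  if (mode == "by_subject") {
    sm <- tapply(b$rt_ms, list(b$subject, b$congruency), mean)
    if (anyNA(sm[, conds])) stop("some subjects lack a condition")
    test <- erp_t_test(sm[, conds[1]], sm[, conds[2]], mode = "paired")
  } else {
    x1 <- b$rt_ms[b$congruency == conds[1]]
    x2 <- b$rt_ms[b$congruency == conds[2]]
    est <- mean(x1) - mean(x2)
    if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
      ## deterministic latencies: no finite Welch statistic
      test <- data.frame(statistic = if (est == 0) 0 else sign(est) * Inf,
                         df = NA_real_,
                         p_value = if (est == 0) 1 else 0,
                         estimate = est, direction = sign(est),
                         degenerate = TRUE)
    } else {
      tt <- stats::t.test(x1, x2)
      test <- data.frame(statistic = unname(tt$statistic),
                         df = unname(tt$parameter),
                         p_value = tt$p.value,
                         estimate = est, direction = sign(est),
                         degenerate = FALSE)
    }
  }
  list(mean_match = unname(m[1]), mean_mismatch = unname(m[2]),
       difference_ms = unname(m[1] - m[2]), test = test)
}

#' Amplitude table over regions of interest
#'
#' Stacks [mean_amplitude()] over a list of ROIs, adding a `roi` column: one
#' row per subject x ROI x constraint x congruency cell. Suitable input for
#' [rm_anova()] with factors `c("animacy_constraint", "congruency", "roi")`
#' and for [n400_roi_contrasts()].
#'
#' @param epochs an `epoch_set`.
#' @param window_ms analysis window (ms).
#' @param rois named list of electrode vectors.
#' @param subject_offset added to the subject ids (for assembling tables
#'   from subject-by-subject simulation).
#' @return data.frame `subject`, `roi`, `animacy_constraint`, `congruency`,
#'   `mean_uv`, `n_trials`.
#' @export
roi_amplitude_table <- function(epochs, window_ms = c(300, 500),
                                rois = default_rois(), subject_offset = 0) {
  out <- do.call(rbind, lapply(names(rois), function(rn) {
    amp <- mean_amplitude(epochs, window_ms, rois[[rn]],
                          group_by = c("animacy_constraint", "congruency"))
    cbind(roi = rn, amp)
  }))
  out$subject <- out$subject + subject_offset
  out[, c("subject", "roi", "animacy_constraint", "congruency", "mean_uv",
          "n_trials")]
}

#' N400 contrasts per region of interest
#'
#' For each ROI, computes subject-level mean amplitudes in the N400 window
#' and tests (a) the overall incongruency effect (average of the two
#' incongruent conditions minus congruent) and (b) the additional
#' animacy-mismatch effect (mismatch minus match) separately for animate-
#' and inanimate-constraining classifiers, all as paired t tests across
#' subjects with BH-FDR correction within each contrast family.
#'
#' @param x an `epoch_set`, or a data.frame from [roi_amplitude_table()].
#' @param window_ms N400 window (default `c(300, 500)` ms); ignored when `x`
#'   is already an amplitude table.
#' @param rois named list of electrode vectors (default [default_rois()]);
#'   ignored when `x` is a table.
#' @param q FDR level.
#' @return list of data.frames: `incongruency` (one row per ROI) and
#'   `mismatch` (one row per ROI x constraint).
#' @export
n400_roi_contrasts <- function(x, window_ms = c(300, 500),
                               rois = default_rois(), q = 0.05) {
  tab <- if (inherits(x, "epoch_set"))
    roi_amplitude_table(x, window_ms, rois) else x
  per_roi <- lapply(unique(tab$roi), function(rn) {
    amp <- tab[tab$roi == rn, , drop = FALSE]
    cell <- function(constraint, congr) {
      sel <- amp$congruency == congr
      if (!is.null(constraint))
        sel <- sel & amp$animacy_constraint == constraint
      tapply(amp$mean_uv[sel] * amp$n_trials[sel], amp$subject[sel], sum) /
        tapply(amp$n_trials[sel], amp$subject[sel], sum)
    }
    cong <- cell(NULL, "congruent")
    match_a <- cell("animate", "incongruent_animacy_match")
    mism_a <- cell("animate", "incongruent_animacy_mismatch")
    match_i <- cell("inanimate", "incongruent_animacy_match")
    mism_i <- cell("inanimate", "incongruent_animacy_mismatch")
    incong <- (match_a + mism_a + match_i + mism_i) / 4
    list(
      incong = cbind(roi = rn, erp_t_test(incong, cong, mode = "paired")),
      mm = rbind(
        cbind(roi = rn, constraint = "animate",
              erp_t_test(mism_a, match_a, mode = "paired")),
        cbind(roi = rn, constraint = "inanimate",
              erp_t_test(mism_i, match_i, mode = "paired"))
      )
    )
  })
  incong <- do.call(rbind, lapply(per_roi, `[[`, "incong"))
  mm <- do.call(rbind, lapply(per_roi, `[[`, "mm"))
  incong <- cbind(incong, fdr_bh(incong$p_value, q)[, c("p_adjusted",
                                                        "selected")])
  mm <- do.call(rbind, lapply(split(mm, mm$constraint), function(g) {
    cbind(g, fdr_bh(g$p_value, q)[, c("p_adjusted", "selected")])
  }))
  rownames(incong) <- rownames(mm) <- NULL
  list(incongruency = incong, mismatch = mm)
}
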