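#' Standard 62-channel montage
#'
#' Channel labels for a 62-electrode extended 10-20 cap (a 64-channel
#' Neuroscan-style cap minus the two mastoid reference electrodes), in a
#' fixed order. `n` may select a prefix of the montage for scaled-down
#' simulations; the fronto-central electrodes and nine regions of interest
#' used by the analyses are placed first, so `n >= 25` keeps all of them.
#'
#' @param n number of channels (default all 62).
#' @return character vector of channel labels.
#' @export
montage_62 <- function(n = 62) {
  labs <- c(
    "FC1", "FCZ", "FC2", "C1", "CZ", "C2", "CP1", "CPZ", "CP2",
    "F3", "F5", "FC3", "FZ", "F4", "F6", "FC4", "C3", "C5", "C4", "C6",
    "P3", "P5", "PZ", "P4", "P6",
    "FP1", "FPZ", "FP2", "AF3", "AF4", "F7", "F1", "F2", "F8",
    "FT7", "FC5", "FC6", "FT8", "T7", "T8", "TP7", "CP5", "CP3",
    "CP4", "CP6", "TP8", "P7", "P1", "P2", "P8",
    "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
    "CB1", "O1", "OZ", "O2", "CB2"
  )
  stopifnot(length(labs) == 62L, !anyDuplicated(labs))
  if (n < 1L || n > length(labs)) stop("n must be in 1..62")
  labs[seq_len(n)]
}

## Crude planar coordinates from a 10-20 label: row letter -> y (anterior
## positive), digit -> x (odd left, even right, Z midline). Used only to
## shape the smooth centro-parietal N400 topography.
.channel_xy <- function(labels) {
  rows <- c(FP = 4, AF = 3.2, F = 2.4, FT = 1.2, FC = 1.2, T = 0, C = 0,
            TP = -1.2, CP = -1.2, P = -2.4, PO = -3.2, CB = -4, O = -4)
  labels <- toupper(labels)
  prefix <- sub("[0-9Z]+$", "", labels)
  num <- substring(labels, nchar(prefix) + 1L)
  y <- rows[prefix]
  x <- ifelse(num == "Z", 0,
              ifelse(as.integer(chartr("Z", "0", num)) %% 2L == 1L,
                     -(as.integer(chartr("Z", "0", num)) + 1) / 2,
                     as.integer(chartr("Z", "0", num)) / 2))
  if (any(is.na(y))) stop("unrecognised channel label(s): ",
                          paste(labels[is.na(y)], collapse = ", "))
  cbind(x = as.numeric(x), y = as.numeric(y))
}

#' Smooth centro-parietal topography
#'
#' Gaussian spatial weighting peaking between the central and
#' centro-parietal rows (maximum at CZ/CPZ), scaled to peak 1. This is the
#' fixed scalp distribution given to the injected N400.
#'
#' @param channels channel labels.
#' @param sigma spatial spread in row units.
#' @return numeric weights in (0, 1], one per channel.
#' @export
n400_topography <- function(channels, sigma = 2) {
  xy <- .channel_xy(channels)
  w <- exp(-((xy[, "x"])^2 + (xy[, "y"] + 0.6)^2) / (2 * sigma^2))
  w / max(w)
}

#' Default epoch segments and span
#'
#' The trial timeline segments the epoch emulates: a 500 ms pre-classifier
#' baseline display, a 1,000 ms classifier display, a 1,000 ms blank
#' interval, and a 1,000 ms noun display (3,500 ms in total, noun onset at
#' t = 0 so the epoch spans -2,500 to +1,000 ms).
#'
#' @return `epoch_segments()`: named numeric vector of segment durations in
#'   ms; `epoch_span_from_segments()`: the `c(start, end)` span in ms
#'   relative to noun onset.
#' @export
epoch_segments <- function() {
  c(pre_classifier = 500, classifier = 1000, interval = 1000, noun = 1000)
}

#' @rdname epoch_segments
#' @param segments named vector as returned by [epoch_segments()].
#' @export
epoch_span_from_segments <- function(segments = epoch_segments()) {
  total <- sum(segments)
  end <- segments[["noun"]]
  c(end - total, end)
}

#' Simulation parameters
#'
#' Ground-truth parameters of the synthetic experiment. Defaults follow the
#' emulated study: 25 subjects, 62 channels, 500 Hz sampling, 3,500 ms
#' epochs with noun onset at t = 0. The two condition-level knobs are the
#' within-group spatial pattern correlations (`rho_animate`,
#' `rho_inanimate`) expressed during the pre-noun prediction window, and the
#' N400 weights per animacy constraint and congruency (the animacy-mismatch
#' condition carries an additional N400 increment only under
#' animate-constraining classifiers; under inanimate-constraining
#' classifiers it equals the animacy-match weight, i.e. a true null).
#'
#' @param n_subjects,n_channels,fs design size and sampling rate (Hz).
#' @param epoch_span `c(start, end)` in ms relative to noun onset; samples
#'   cover the half-open interval `[start, end)`.
#' @param rho_animate,rho_inanimate within-group pattern correlation in
#'   `[0, 1)` for animate / inanimate noun groups.
#' @param pred_window,pred_amplitude prediction-potential window (ms) and
#'   peak amplitude (uV) of the item-pattern signal raised within it.
#' @param n400_window,n400_amplitude N400 window (ms) and peak magnitude
#'   (uV); the deflection is injected negative over the centro-parietal
#'   topography.
#' @param n400_weights 2 x 3 numeric matrix, rows `animate`/`inanimate`
#'   (classifier constraint), columns the three congruency conditions.
#' @param noise_sd additive Gaussian noise SD per channel-sample (uV).
#' @param ar1 optional AR(1) coefficient for temporally correlated noise
#'   (0 = white).
#' @param artifact_prob,artifact_amplitude per-trial probability and size
#'   (uV) of an injected high-amplitude artifact excursion.
#' @param rt_base,rt_mismatch_advantage,rt_sd behavioural response latency
#'   model (ms): the animacy-mismatch condition is faster by
#'   `rt_mismatch_advantage`.
#' @param p_incorrect per-trial probability of an incorrect judgement on
#'   incongruent trials.
#' @param seed optional integer seed consumed by the simulators.
#' @return a validated `sim_params` list.
#' @export
sim_params <- function(n_subjects = 25, n_channels = 62, fs = 500,
                       epoch_span = epoch_span_from_segments(),
                       rho_animate = 0.5, rho_inanimate = 0.1,
                       pred_window = c(-240, 0), pred_amplitude = 1.5,
                       n400_window = c(300, 500), n400_amplitude = 3,
                       n400_weights = rbind(animate = c(0, 1, 2),
                                            inanimate = c(0, 1, 1)),
                       noise_sd = 10, ar1 = 0,
                       artifact_prob = 0.046, artifact_amplitude = 120,
                       rt_base = 674, rt_mismatch_advantage = 22,
                       rt_sd = 195, p_incorrect = 0.047, seed = NULL) {
  p <- as.list(environment())
  colnames(p$n400_weights) <- .congruency_levels
  if (p$fs <= 0) stop("fs must be positive")
  if (p$rho_animate < 0 || p$rho_animate >= 1 ||
      p$rho_inanimate < 0 || p$rho_inanimate >= 1)
    stop("pattern correlations rho must lie in [0, 1)")
  if (diff(p$epoch_span) <= 0) stop("epoch_span must be increasing")
  ## an effect window must lie inside the epoch, but only when the effect
  ## is actually injected (a zero amplitude disables it, e.g. no N400 in a
  ## pre-noun-only simulation)
  active <- list(p$pred_window, p$n400_window)[
    c(p$pred_amplitude != 0, p$n400_amplitude != 0)]
  for (w in active) {
    if (w[1] < p$epoch_span[1] || w[2] > p$epoch_span[2])
      stop("effect window outside epoch span")
  }
  if (p$noise_sd < 0 || p$rt_sd < 0) stop("noise SDs must be non-negative")
  if (abs(p$ar1) >= 1) stop("ar1 must lie in (-1, 1)")
  class(p) <- "sim_params"
  p
}

#' Time axis of an epoch
#' @param params a `sim_params` list.
#' @return numeric vector of sample times (ms), half-open `[start, end)`.
#' @export
epoch_times <- function(params) {
  dt <- 1000 / params$fs
  seq(params$epoch_span[1], params$epoch_span[2] - dt / 2, by = dt)
}

## one subject's trials x (channels*time) matrix; zero-stride reshape when
## the set holds a single subject
.subject_matrix <- function(data, s) {
  d <- dim(data)
  if (d[1] == 1L && s == 1L) {
    dim(data) <- c(d[2], d[3] * d[4])
    data
  } else {
    matrix(data[s, , , , drop = FALSE], d[2], d[3] * d[4])
  }
}

## indices of samples in the half-open window [w1, w2)
.window_idx <- function(times, window) {
  idx <- which(times >= window[1] & times < window[2])
  if (length(idx) == 0L) stop("window [", window[1], ", ", window[2],
                              ") contains no samples")
  idx
}

## Hann taper over a window, evaluated on the full time axis (0 outside)
.hann_on_axis <- function(times, window) {
  h <- numeric(length(times))
  idx <- .window_idx(times, window)
  u <- (times[idx] - window[1]) / (window[2] - window[1])
  h[idx] <- 0.5 * (1 - cos(2 * pi * u))
  h
}

#' Generate item-level spatial patterns
#'
#' For every noun, draws the 62-channel spatial pattern whose pre-activation
#' the simulated prediction potential expresses. Within noun group g
#' (animate / inanimate) the pattern is
#' `sqrt(rho_g) * shared_g + sqrt(1 - rho_g) * unique_i`, with the shared
#' and unique components i.i.d. standard normal per channel, so the expected
#' pairwise correlation of two patterns within a group is `rho_g`.
#'
#' @param design a `design_table`.
#' @param params a `sim_params` list.
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream (used when a caller manages one stream for a whole experiment).
#' @return numeric matrix channels x nouns with noun ids as column names.
#' @export
generate_item_patterns <- function(design, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nouns <- attr(design, "nouns")
  if (is.null(nouns)) stop("design lacks its noun lexicon attribute")
  C <- params$n_channels
  pat <- matrix(NA_real_, C, nrow(nouns), dimnames = list(NULL, nouns$id))
  for (g in c("animate", "inanimate")) {
    rho <- if (g == "animate") params$rho_animate else params$rho_inanimate
    ids <- nouns$id[nouns$animacy == g]
    if (length(ids) == 0L) next
    shared <- stats::rnorm(C)
    uniq <- matrix(stats::rnorm(C * length(ids)), C)
    pat[, ids] <- sqrt(rho) * shared + sqrt(1 - rho) * uniq
  }
  pat
}

#' Simulate an epoched multichannel EEG data set
#'
#' Builds `subjects x trials x channels x time` epochs (uV) with three
#' generative ingredients per trial: (1) the trial noun's spatial pattern,
#' raised under a Hann taper across the pre-noun prediction window and
#' scaled by `pred_amplitude`; (2) a negative N400 deflection under a Hann
#' taper across the N400 window, over a fixed centro-parietal topography,
#' scaled by `n400_amplitude` and the condition weight for the trial's
#' constraint x congruency cell; (3) additive Gaussian noise (optionally
#' AR(1) along time), plus occasional high-amplitude artifact excursions.
#'
#' @param design a `design_table`.
#' @param params a `sim_params` list.
#' @param patterns optional channels x nouns pattern matrix shared by all
#'   subjects (as from [generate_item_patterns()]); the default `NULL` draws
#'   an independent pattern set per subject, treating spatial patterns as
#'   subject-specific.
#' @param n_subjects number of subjects to simulate (default
#'   `params$n_subjects`).
#' @param seed optional integer seed; `NULL` continues the current stream.
#' @return an `epoch_set`: list with `data` (4-d array), `times` (ms),
#'   `fs`, `channels`, `design`, `subjects`, and a logical `keep`
#'   subjects x trials matrix (all `TRUE` until artifact rejection).
#' @export
simulate_epochs <- function(design, params, patterns = NULL,
                            n_subjects = params$n_subjects, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- epoch_times(params)
  Tn <- length(times)
  C <- params$n_channels
  Tr <- nrow(design)
  channels <- montage_62(C)

  hp <- if (params$pred_amplitude != 0)
    .hann_on_axis(times, params$pred_window) else numeric(Tn)
  hn <- if (params$n400_amplitude != 0)
    .hann_on_axis(times, params$n400_window) else numeric(Tn)
  ip <- which(hp > 0)
  in4 <- which(hn > 0)
  topo <- n400_topography(channels)
  w <- params$n400_weights[cbind(design$animacy_constraint,
                                 design$congruency)]

  data <- if (n_subjects > 1L) array(NA_real_, c(n_subjects, Tr, C, Tn))
  for (s in seq_len(n_subjects)) {
    pat <- if (is.null(patterns)) generate_item_patterns(design, params)
           else patterns
    noise <- stats::rnorm(Tr * C * Tn, sd = params$noise_sd)
    if (params$ar1 != 0) {
      noise <- matrix(noise * sqrt(1 - params$ar1^2), nrow = Tn)
      noise <- stats::filter(noise, params$ar1, method = "recursive")
      x <- aperm(array(as.numeric(noise), c(Tn, C, Tr)), c(3, 2, 1))
    } else {
      x <- array(noise, c(Tr, C, Tn))
    }
    if (length(ip)) {
      pa <- params$pred_amplitude *
        t(pat[, design$noun_id, drop = FALSE])        # trials x channels
      x[, , ip] <- x[, , ip] + outer(pa, hp[ip])
    }
    if (length(in4) && any(w != 0)) {
      nw <- outer(w, -params$n400_amplitude * topo)   # trials x channels
      x[, , in4] <- x[, , in4] + outer(nw, hn[in4])
    }
    if (params$artifact_prob > 0) {
      hit <- which(stats::runif(Tr) < params$artifact_prob)
      half <- max(1L, round(0.025 * params$fs))  # 50 ms excursion
      for (j in hit) {
        ch <- sample.int(C, 1L)
        t0 <- sample.int(Tn, 1L)
        span <- max(1L, t0 - half):min(Tn, t0 + half)
        x[j, ch, span] <- x[j, ch, span] +
          sample(c(-1, 1), 1L) * params$artifact_amplitude
      }
    }
    if (n_subjects == 1L) {
      ## leading unit dimension does not permute memory: no strided copy
      dim(x) <- c(1L, Tr, C, Tn)
      data <- x
    } else {
      data[s, , , ] <- x
    }
  }
  structure(list(
    data = data, times = times, fs = params$fs, channels = channels,
    design = design, subjects = seq_len(n_subjects),
    keep = matrix(TRUE, n_subjects, Tr)
  ), class = "epoch_set")
}

#' Construct an epoch set from components
#'
#' Low-level constructor validating the container invariants: a strictly
#' increasing, uniformly spaced time axis with spacing `1000/fs` ms and a
#' trial dimension matching the design length.
#'
#' @param data numeric array subjects x trials x channels x time (uV).
#' @param times time axis in ms, 0 = noun onset.
#' @param fs sampling rate, Hz.
#' @param channels channel labels (length = dim 3).
#' @param design a `design_table` with one row per trial.
#' @param keep optional logical subjects x trials matrix.
#' @return an `epoch_set`.
#' @export
epoch_set <- function(data, times, fs, channels, design, keep = NULL) {
  d <- dim(data)
  if (length(d) != 4L) stop("data must be a 4-d array")
  if (length(times) != d[4]) stop("time axis length mismatch")
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - 1000 / fs)) > 1e-6)
    stop("time axis must increase uniformly with spacing 1000/fs ms")
  if (length(channels) != d[3]) stop("channel label length mismatch")
  if (nrow(design) != d[2]) stop("trial dimension does not match design")
  if (is.null(keep)) keep <- matrix(TRUE, d[1], d[2])
  structure(list(data = data, times = times, fs = fs,
                 channels = channels, design = design,
                 subjects = seq_len(d[1]), keep = keep),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d subjects x %d trials x %d channels x %d samples\n",
    d[1], d[2], d[3], d[4]))
  cat(sprintf("  fs = %g Hz, t = [%g, %g) ms (0 = noun onset), %d%% kept\n",
              x$fs, x$times[1], x$times[length(x$times)] + 1000 / x$fs,
              round(100 * mean(x$keep))))
  invisible(x)
}

#' Simulate behavioural responses
#'
#' Plausibility judgements are only made to incongruent phrases, so response
#' latencies exist for incongruent trials only. Latency is
#' `rt_base - rt_mismatch_advantage * [animacy mismatch] + N(0, rt_sd)`,
#' floored at 1 ms; correctness is Bernoulli with error rate `p_incorrect`.
#'
#' @param design a `design_table`.
#' @param params a `sim_params` list.
#' @param n_subjects number of subjects (default `params$n_subjects`).
#' @param seed optional integer seed; `NULL` continues the current stream.
#' @return data.frame `subject`, `trial_index`, `congruency`, `rt_ms`,
#'   `correct` with one row per subject x incongruent trial.
#' @export
simulate_behavior <- function(design, params,
                              n_subjects = params$n_subjects, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  inc <- design[design$congruency != "congruent", , drop = FALSE]
  n <- nrow(inc) * n_subjects
  mism <- rep(inc$congruency == "incongruent_animacy_mismatch", n_subjects)
  rt <- params$rt_base - params$rt_mismatch_advantage * mism +
    stats::rnorm(n, 0, params$rt_sd)
  data.frame(
    subject = rep(seq_len(n_subjects), each = nrow(inc)),
    trial_index = rep(inc$trial_index, n_subjects),
    congruency = rep(inc$congruency, n_subjects),
    rt_ms = pmax(rt, 1),
    correct = stats::runif(n) >= params$p_incorrect
  )
}
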