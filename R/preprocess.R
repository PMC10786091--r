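#' Zero-phase band-pass filter epochs
#'
#' Applies forward-backward (zero-phase) Butterworth filtering to every
#' subject/trial/channel trace: a high-pass stage at `low_hz` (skipped when
#' `low_hz <= 0`) cascaded with a low-pass stage at `high_hz`. Zero-phase
#' filtering is used so component latencies are not shifted. Dimensions,
#' time axis and channel labels are unchanged.
#'
#' @param epochs an `epoch_set`.
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 <= low_hz < high_hz < fs/2`.
#' @param order_high,order_low Butterworth orders of the two stages.
#' @return the filtered `epoch_set`.
#' @export
filter_epochs <- function(epochs, low_hz = 0.1, high_hz = 30,
                          order_high = 2, order_low = 4) {
  fs <- epochs$fs
  if (low_hz < 0 || low_hz >= high_hz || high_hz >= fs / 2)
    stop("cutoffs must satisfy 0 <= low < high < fs/2 (Nyquist)")
  hp <- if (low_hz > 0) signal::butter(order_high, 2 * low_hz / fs, "high")
  lp <- signal::butter(order_low, 2 * high_hz / fs, "low")
  d <- dim(epochs$data)
  out <- epochs
  for (s in seq_len(d[1])) for (j in seq_len(d[2])) {
    x <- matrix(epochs$data[s, j, , ], d[3], d[4])
    for (c in seq_len(d[3])) {
      y <- x[c, ]
      if (!is.null(hp)) y <- signal::filtfilt(hp, y)
      x[c, ] <- signal::filtfilt(lp, y)
    }
    out$data[s, j, , ] <- x
  }
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per subject, trial and channel, the mean over the baseline
#' window (half-open `[start, end)` ms) from the whole epoch.
#'
#' @param epochs an `epoch_set`.
#' @param window_ms `c(start, end)` baseline window in ms.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window_ms) {
  idx <- .window_idx(epochs$times, window_ms)
  d <- dim(epochs$data)
  bl <- rowMeans(epochs$data[, , , idx, drop = FALSE], dims = 3)
  out <- epochs
  out$data <- epochs$data - array(bl, d)  # bl recycled along time
  out
}

#' Reject artifactual and incorrectly answered trials
#'
#' Flags as dropped every trial whose absolute amplitude exceeds
#' `threshold_uv` on any channel at any time point, and (when a behaviour
#' table is supplied) every incongruent trial answered incorrectly. Trials
#' are not removed from the array; the `keep` mask is updated and all
#' downstream analyses honour it. If any subject is left without a single
#' kept trial for some classifier the data set is degenerate and an error is
#' raised (such subjects would be excluded from the study).
#'
#' @param epochs an `epoch_set`.
#' @param behavior optional behaviour table from [simulate_behavior()].
#' @param threshold_uv rejection threshold in uV (default 70).
#' @return list with `epochs` (updated `keep`) and `log`, a data.frame of
#'   `subject`, `trial_index`, `keep`, `reason` with the overall dropped
#'   proportion in attribute `proportion_dropped`.
#' @export
reject_artifacts <- function(epochs, behavior = NULL, threshold_uv = 70) {
  if (threshold_uv <= 0) stop("threshold_uv must be positive")
  d <- dim(epochs$data)
  amax <- matrix(NA_real_, d[1], d[2])
  for (s in seq_len(d[1])) {
    m <- abs(.subject_matrix(epochs$data, s))
    amax[s, ] <- m[cbind(seq_len(d[2]), max.col(m, ties.method = "first"))]
  }
  keep <- amax <= threshold_uv
  reason <- matrix(NA_character_, d[1], d[2])
  reason[!keep] <- "amplitude"
  if (!is.null(behavior)) {
    wrong <- behavior[!behavior$correct, , drop = FALSE]
    if (nrow(wrong)) {
      j <- match(wrong$trial_index, epochs$design$trial_index)
      bad <- cbind(wrong$subject, j)
      reason[bad][keep[bad]] <- "incorrect_response"
      keep[bad] <- FALSE
    }
  }
  new_keep <- epochs$keep & keep
  reason[!epochs$keep] <- NA_character_  # already-dropped trials unchanged
  for (s in seq_len(d[1])) {
    left <- table(epochs$design$classifier_id[new_keep[s, ]])
    all_cl <- unique(epochs$design$classifier_id)
    if (!all(all_cl %in% names(left)))
      stop("degenerate data set: subject ", s,
           " has no surviving trials for at least one classifier")
  }
  out <- epochs
  out$keep <- new_keep
  log <- data.frame(
    subject = rep(seq_len(d[1]), d[2]),
    trial_index = rep(epochs$design$trial_index, each = d[1]),
    keep = as.vector(new_keep),
    reason = as.vector(reason),
    stringsAsFactors = FALSE
  )
  attr(log, "proportion_dropped") <-
    sum(epochs$keep & !new_keep) / sum(epochs$keep)
  list(epochs = out, log = log)
}
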