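# Event-epoch detection from the sample-entropy series, with anti-shake
# onset/offset marking, epoch filtering, and propagation of biceps-channel
# intervals to the other channels of the same arm.

#' Detect event epochs from a sample-entropy series
#'
#' Scans the series left to right. An onset is committed after
#' `start_count` consecutive values above the start threshold; the epoch
#' start is the window start of the first window of that run. After an
#' onset, an offset is committed after `end_count` consecutive values below
#' the end threshold; the epoch end is the window start of the first window
#' of the closing run plus the window length (inclusive boundaries). In the
#' default relative mode the thresholds are `start_factor`/`end_factor`
#' times the series maximum. An onset still open at the end of the trial is
#' closed at the final sample. Candidate epochs are then filtered: the
#' length must exceed `min_len` and the maximum absolute filtered amplitude
#' within the epoch must exceed `amp_factor` times the trial-wide maximum
#' absolute filtered amplitude.
#'
#' @param series A [sampen_series()] for the trial.
#' @param x_filtered The band-passed (un-rectified) signal of the same
#'   trial, used for the amplitude condition.
#' @param params A [sampen_params()] object.
#' @return Integer matrix with columns `start`, `end` (possibly 0 rows);
#'   attribute `candidates` holds the intervals before filtering.
#' @export
detect_epochs <- function(series, x_filtered, params = sampen_params()) {
  if (!inherits(series, "sampen_series"))
    stop("`series` must be a sampen_series", call. = FALSE)
  v <- series$values
  ws <- series$window_start_samples
  n <- length(x_filtered)
  if (params$threshold_mode == "relative") {
    mx <- max(v)
    # contrast guard: proportional thresholds are undefined on a flat
    # series (an activity-free trial)
    if (mx <= params$min_contrast * stats::median(v)) {
      out <- matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
      attr(out, "candidates") <- out
      return(out)
    }
    thr_start <- params$start_factor * mx
    thr_end <- params$end_factor * mx
  } else {
    thr_start <- params$start_factor
    thr_end <- params$end_factor
  }

  cand <- list()
  i <- 1L
  nv <- length(v)
  in_epoch <- FALSE
  ep_start <- NA_integer_
  run <- 0L
  run_first <- NA_integer_
  while (i <= nv) {
    if (!in_epoch) {
      if (v[i] > thr_start) {
        if (run == 0L) run_first <- i
        run <- run + 1L
        if (run >= params$start_count) {
          in_epoch <- TRUE
          ep_start <- ws[run_first]
          run <- 0L
        }
      } else run <- 0L
    } else {
      if (v[i] < thr_end) {
        if (run == 0L) run_first <- i
        run <- run + 1L
        if (run >= params$end_count) {
          ep_end <- min(n, ws[run_first] + params$window - 1L)
          cand[[length(cand) + 1L]] <- c(ep_start, ep_end)
          in_epoch <- FALSE
          run <- 0L
        }
      } else run <- 0L
    }
    i <- i + 1L
  }
  if (in_epoch) cand[[length(cand) + 1L]] <- c(ep_start, n)

  candidates <- if (length(cand)) do.call(rbind, cand) else
    matrix(integer(0), ncol = 2)
  colnames(candidates) <- c("start", "end")

  amp_floor <- params$amp_factor * max(abs(x_filtered))
  keep <- logical(nrow(candidates))
  for (k in seq_len(nrow(candidates))) {
    len <- candidates[k, "end"] - candidates[k, "start"] + 1L
    amp <- max(abs(x_filtered[candidates[k, "start"]:candidates[k, "end"]]))
    keep[k] <- (len > params$min_len) && (amp > amp_floor)
  }
  out <- candidates[keep, , drop = FALSE]
  attr(out, "candidates") <- candidates
  out
}

#' Propagate detected intervals to same-arm channels
#'
#' Cuts the identical sample intervals detected on a biceps channel from
#' the filtered signals of every channel of the same arm.
#'
#' @param intervals Integer matrix with `start`, `end` columns.
#' @param filtered Matrix of filtered signals (columns named by channel).
#' @param channels Channel names of the arm to cut.
#' @param subject,group,trial Labels attached to each epoch.
#' @return A list of epochs (see [new_epoch_set()]).
#' @export
propagate_epochs <- function(intervals, filtered, channels,
                             subject = "S01", group = "amateur", trial = "T1") {
  n <- nrow(filtered)
  epochs <- list()
  for (k in seq_len(nrow(intervals))) {
    s <- intervals[k, "start"]; e <- intervals[k, "end"]
    if (s < 1 || e > n || s > e)
      stop(sprintf("interval (%d, %d) out of bounds for signal of length %d",
                   s, e, n), call. = FALSE)
    for (ch in channels) {
      epochs[[length(epochs) + 1L]] <- list(
        subject = subject, group = group, trial = trial, channel = ch,
        cycle = k, start = s, end = e, samples = filtered[s:e, ch])
    }
  }
  epochs
}

#' Detect and extract all epochs of one trial
#'
#' Runs the full per-trial detection: sample-entropy series on each
#' smoothed biceps channel, epoch detection, and propagation of the
#' detected intervals to the four channels of the corresponding arm.
#'
#' @param prep Output of [preprocess_recording()].
#' @param params A [sampen_params()] object.
#' @param layout Channel layout (see [channel_layout()]).
#' @return A list: `epochs` (list of epochs over all 8 channels) and
#'   `intervals` (named list of accepted interval matrices per arm).
#' @export
detect_trial <- function(prep, params = sampen_params(),
                         layout = channel_layout()) {
  arms <- list(left = layout$left, right = layout$right)
  epochs <- list()
  intervals <- list()
  for (arm in names(arms)) {
    det_ch <- layout$detect[[arm]]
    ser <- sampen_series(prep$smoothed[, det_ch], params)
    iv <- detect_epochs(ser, prep$filtered[, det_ch], params)
    intervals[[arm]] <- iv
    epochs <- c(epochs, propagate_epochs(
      iv, prep$filtered, arms[[arm]],
      subject = prep$subject_id, group = prep$group, trial = prep$trial_id))
  }
  list(epochs = epochs, intervals = intervals)
}
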