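# Preprocessing chain: zero-phase 4th-order 20-250 Hz Butterworth band-pass
# on every channel; half-wave rectification and span-5 moving-average
# smoothing on the biceps channels only (used solely for event detection --
# features are always computed on the filtered, un-rectified signal);
# amplitude normalization of extracted epochs per (subject, channel) by the
# maximum absolute sample value. No power-line notch is applied.

#' Construct an sEMG recording
#'
#' @param samples Numeric matrix, one column per channel (finite values).
#' @param fs Sampling rate in Hz.
#' @param channel_names Channel labels; defaults to the matrix column names
#'   or C1..Cn.
#' @param subject_id,group,trial_id Annotation labels.
#' @return An object of class `semg_recording`.
#' @export
new_recording <- function(samples, fs = 1000, channel_names = NULL,
                          subject_id = "S01", group = "amateur",
                          trial_id = "T1") {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("`samples` must be a numeric matrix with no non-finite values",
         call. = FALSE)
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  if (is.null(channel_names))
    channel_names <- colnames(samples) %||% paste0("C", seq_len(ncol(samples)))
  colnames(samples) <- channel_names
  structure(list(samples = samples, fs = fs, channel_names = channel_names,
                 subject_id = subject_id, group = group, trial_id = trial_id),
            class = "semg_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the given prototype order (MATLAB
#' convention: an order-4 design yields an order-8 band-pass transfer
#' function) and applies it forward and backward (`signal::filtfilt`), so
#' the output is zero-phase and the effective magnitude response is the
#' squared one-pass magnitude.
#'
#' @param x Numeric vector, a single-channel signal.
#' @param fs Sampling rate (Hz).
#' @param low,high Band edges in Hz (`low < high < fs/2`).
#' @param order Prototype filter order.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 20, high = 250, order = 4) {
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  if (!(low < high && high < fs / 2))
    stop("band edges must satisfy low < high < fs/2", call. = FALSE)
  if (length(x) < 3 * (order + 1))
    stop(sprintf("signal too short for filtering: need >= %d samples, got %d",
                 3 * (order + 1), length(x)), call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Half-wave rectification
#'
#' @param x Numeric vector.
#' @return `max(x, 0)` elementwise.
#' @export
half_wave_rectify <- function(x) pmax(x, 0)

#' Centred moving-average smoothing
#'
#' Mean over a centred window of `span` samples; at the ends the window
#' shrinks symmetrically so the output has the same length as the input.
#'
#' @param x Numeric vector.
#' @param span Odd window length (>= 1).
#' @return Smoothed signal of the same length.
#' @export
moving_average <- function(x, span = 5) {
  stopifnot_scalar_num(span, "span", positive = TRUE, integerish = TRUE)
  if (span %% 2 == 0) stop("`span` must be odd", call. = FALSE)
  n <- length(x)
  if (span == 1 || n == 0) return(as.numeric(x))
  h <- (span - 1) / 2
  out <- as.numeric(stats::filter(x, rep(1 / span, span), sides = 2))
  # shrinking symmetric windows at the edges
  for (i in seq_len(min(h, n))) {
    k <- i - 1
    out[i] <- mean(x[1:min(n, i + k)])
    j <- n - i + 1
    out[j] <- mean(x[max(1, j - k):n])
  }
  out
}

#' Apply the full preprocessing chain to a recording
#'
#' Band-pass filters every channel and, for the two biceps detection
#' channels, additionally computes the half-wave rectified, moving-average
#' smoothed envelope used by sample-entropy event detection.
#'
#' @param rec A [new_recording()] object.
#' @param low,high,order Band-pass parameters.
#' @param span Moving-average span.
#' @param detect_channels Channels for which the rectified/smoothed
#'   detection signal is computed.
#' @return A list with `filtered` (matrix, all channels) and `smoothed`
#'   (matrix, detection channels), plus `fs` and the recording labels.
#' @export
preprocess_recording <- function(rec, low = 20, high = 250, order = 4,
                                 span = 5,
                                 detect_channels = channel_layout()$detect) {
  if (!inherits(rec, "semg_recording"))
    stop("`rec` must be a semg_recording", call. = FALSE)
  filtered <- apply(rec$samples, 2, bandpass_filter, fs = rec$fs,
                    low = low, high = high, order = order)
  colnames(filtered) <- rec$channel_names
  dc <- intersect(detect_channels, rec$channel_names)
  smoothed <- sapply(dc, function(ch)
    moving_average(half_wave_rectify(filtered[, ch]), span = span))
  if (length(dc) == 1L) smoothed <- matrix(smoothed, ncol = 1,
                                           dimnames = list(NULL, dc))
  list(filtered = filtered, smoothed = smoothed, fs = rec$fs,
       subject_id = rec$subject_id, group = rec$group, trial_id = rec$trial_id)
}

#' Construct an epoch set
#'
#' @param epochs List of epochs; each epoch is a list with `subject`,
#'   `group`, `trial`, `channel`, `cycle`, `start`, `end`, `samples`.
#' @return Object of class `epoch_set` (with `normalization` divisors once
#'   normalized).
#' @export
new_epoch_set <- function(epochs = list()) {
  structure(list(epochs = epochs, normalization = NULL), class = "epoch_set")
}

#' @export
length.epoch_set <- function(x) length(x$epochs)

#' Normalize epoch amplitudes per subject and channel
#'
#' Divides every epoch sample by the maximum absolute sample value over all
#' epochs of the same (subject, channel) group, so the extreme normalized
#' value in each group has magnitude 1. The divisor is interpreted as the
#' maximum absolute value (the filtered signal is signed), keeping the
#' normalized signal in \[-1, 1\]. Idempotent.
#'
#' @param es An `epoch_set`.
#' @return The normalized `epoch_set`; per-group divisors are stored in
#'   `$normalization`.
#' @export
normalize_epochs <- function(es) {
  if (!inherits(es, "epoch_set")) stop("`es` must be an epoch_set", call. = FALSE)
  if (length(es$epochs) == 0) return(es)
  keys <- vapply(es$epochs, function(e) paste(e$subject, e$channel, sep = "|"),
                 character(1))
  divisors <- numeric(0)
  for (k in unique(keys)) {
    idx <- which(keys == k)
    mx <- max(vapply(es$epochs[idx], function(e) max(abs(e$samples)), numeric(1)))
    if (mx == 0)
      stop(sprintf("all-zero epoch group '%s': cannot normalize", k),
           call. = FALSE)
    for (i in idx) es$epochs[[i]]$samples <- es$epochs[[i]]$samples / mx
    divisors[k] <- mx
  }
  prev <- es$normalization %||% numeric(0)
  # compose with any earlier normalization so divisors stay in raw units
  for (k in names(divisors))
    if (k %in% names(prev)) divisors[k] <- divisors[k] * prev[k]
  es$normalization <- divisors
  es
}
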