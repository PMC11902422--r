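# Sample entropy (Richman-Moorman) and its sliding-window series.
#
# SampEn(m, r, N) = -ln(A/B), where B counts pairs of length-m templates
# whose Chebyshev distance is <= r and A counts the same for length m+1;
# self-matches are excluded and both counts use the N - m templates that
# admit an (m+1)-length extension, so A and B are comparable.

#' Sample-entropy detection parameters
#'
#' Defaults follow the standard operating point for curl-burst detection on
#' smoothed sEMG at 1000 Hz: `m = 2`, tolerance `r = 0.25 * SD` of the
#' whole-trial signal (a global tolerance), a rectangular window of width
#' 64 slid in steps of 30, onset/offset threshold factors 0.02/0.01 with
#' anti-shake counts 3/2, minimum epoch length 1050 samples and an epoch
#' amplitude floor of 0.35 times the trial's maximum absolute filtered
#' amplitude.
#'
#' @param m Template length.
#' @param r_factor Tolerance multiplier on the whole-signal SD.
#' @param window,step Sliding-window width and step (samples).
#' @param start_factor,end_factor Onset/offset thresholds; in the default
#'   `"relative"` mode they multiply the maximum of the SampEn series, in
#'   `"absolute"` mode they are used as-is.
#' @param start_count,end_count Anti-shake criteria: consecutive
#'   windows required above/below threshold to commit a mark.
#' @param min_len Minimum accepted epoch length (samples).
#' @param amp_factor Epoch amplitude floor as a fraction of the trial's
#'   maximum absolute filtered amplitude.
#' @param min_contrast Relative-mode guard: the series maximum must exceed
#'   `min_contrast` times the series median, otherwise the trial is
#'   treated as activity-free (thresholds proportional to the maximum are
#'   meaningless on a flat series).
#' @param threshold_mode `"relative"` (default) or `"absolute"`.
#' @return A list of class `sampen_params`.
#' @export
sampen_params <- function(m = 2L, r_factor = 0.25, window = 64L, step = 30L,
                          start_factor = 0.02, end_factor = 0.01,
                          start_count = 3L, end_count = 2L,
                          min_len = 1050L, amp_factor = 0.35,
                          min_contrast = 4,
                          threshold_mode = c("relative", "absolute")) {
  threshold_mode <- match.arg(threshold_mode)
  p <- list(m = as.integer(m), r_factor = r_factor, window = as.integer(window),
            step = as.integer(step), start_factor = start_factor,
            end_factor = end_factor, start_count = as.integer(start_count),
            end_count = as.integer(end_count), min_len = as.integer(min_len),
            amp_factor = amp_factor, min_contrast = min_contrast,
            threshold_mode = threshold_mode)
  if (p$step <= 0 || p$step > p$window)
    stop("need 0 < step <= window", call. = FALSE)
  if (p$m >= p$window) stop("need m < window", call. = FALSE)
  structure(p, class = "sampen_params")
}

#' Sample entropy of one signal window
#'
#' Computes `-ln(A/B)` with Chebyshev template matching at tolerance `r`,
#' self-matches excluded. When no template pair matches at either length
#' (`B = 0` or `A = 0`) the value is undefined; a documented finite cap,
#' `log(n_t * (n_t - 1))` with `n_t = N - m` (the largest value the
#' estimator could resolve, from a single matched pair among all ordered
#' pairs), is returned with attribute `capped = TRUE` rather than raising.
#'
#' @param x Numeric vector (length >= m + 2).
#' @param m Template length.
#' @param r Positive tolerance (absolute units of `x`).
#' @param cap Optional override of the degenerate-case value.
#' @return Nonnegative scalar, with attribute `capped` if degenerate.
#' @export
sample_entropy <- function(x, m = 2L, r, cap = NULL) {
  n <- length(x)
  if (n < m + 2) stop("window too short: need length >= m + 2", call. = FALSE)
  if (!is.numeric(r) || r <= 0) stop("`r` must be positive", call. = FALSE)
  nt <- n - m
  d <- abs(outer(x, x, "-"))
  idx <- seq_len(nt)
  cmax <- d[idx, idx, drop = FALSE]
  for (k in seq_len(m - 1)) cmax <- pmax(cmax, d[idx + k, idx + k, drop = FALSE])
  Bmat <- cmax <= r
  Amat <- (pmax(cmax, d[idx + m, idx + m, drop = FALSE])) <= r
  B <- (sum(Bmat) - nt) / 2
  A <- (sum(Amat) - nt) / 2
  if (B == 0 || A == 0) {
    val <- cap %||% log(nt * (nt - 1))
    attr(val, "capped") <- TRUE
    return(val)
  }
  -log(A / B)
}

#' Sliding-window sample-entropy series
#'
#' Slides a rectangular window of `params$window` samples in steps of
#' `params$step` over the whole trial signal and computes SampEn in each
#' window. The tolerance is global: `r = r_factor * SD(x)` computed once
#' from the entire trial, so burst windows (large excursions relative to
#' `r`) score high and quiescent windows score near zero.
#'
#' @param x Smoothed detection signal for one trial.
#' @param params A [sampen_params()] object.
#' @return A list of class `sampen_series`: `values`,
#'   `window_start_samples` (1-based), `r`, and `params`.
#' @export
sampen_series <- function(x, params = sampen_params()) {
  n <- length(x)
  w <- params$window
  if (n < w)
    stop(sprintf("trial shorter than one window (%d < %d)", n, w),
         call. = FALSE)
  r <- params$r_factor * stats::sd(x)
  starts <- seq(1L, n - w + 1L, by = params$step)
  if (r == 0) {
    # constant trial: every window is perfectly regular
    vals <- rep(0, length(starts))
  } else {
    vals <- vapply(starts, function(s)
      as.numeric(sample_entropy(x[s:(s + w - 1L)], m = params$m, r = r)),
      numeric(1))
  }
  structure(list(values = vals, window_start_samples = starts, r = r,
                 params = params),
            class = "sampen_series")
}
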