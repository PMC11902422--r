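# 63-value per-epoch feature bank: 41 time-domain feature names and 9
# frequency-domain feature names, with the order-4 AR model contributing 4
# values, the spectral moments 4 (SM0..SM3), and the level-3 wavelet-packet
# decomposition 8 node energies, for 63 values total.
#
# Features whose exact identity is not fixed by the published catalogs
# (AE, MAS, VARe, VO, LDMA, LDASDA, LCOV, FZC) follow the best-available
# published EMG feature-toolbox conventions and are tagged
# "interpretation" in the registry.

#' The ordered 63-feature registry
#'
#' @param thresholds Named list of the small-amplitude thresholds used by
#'   ZC, SSC, WA, MYOP and CARD (defaults 0.01, on normalized amplitude).
#' @return A data frame with columns `name`, `domain` (TD/FD), `source`
#'   (`formula` for features with printed defining equations, `catalog`
#'   for standard published definitions, `interpretation` where the
#'   identity was resolved by convention).
#' @export
feature_registry <- function(thresholds = feature_thresholds()) {
  td <- c("ASM", "ASS", "AR1", "AR2", "AR3", "AR4", "AAC", "AE", "CARD",
          "COV", "DAMV", "DASDV", "DVARV", "EMAV", "EWL", "IEMG", "IQR",
          "KURT", "LCOV", "LD", "LDMA", "LDASDA", "LTKEO", "MFL", "MAS",
          "MAV", "MSR", "MMAV", "MMAV2", "MYOP", "FZC", "RMS", "SSI",
          "Skew", "SSC", "SD", "TM", "VAR", "VARe", "VO", "WL", "WA", "ZC",
          "DUR")
  fd <- c("MDF", "MNF", "FR", "PKF", "PSR", "MNP", "SM0", "SM1", "SM2",
          "SM3", "VCF", paste0("WP", 1:8))
  formula_set <- c("ASM", "ASS", "AR1", "AR2", "AR3", "AR4", "AAC", "CARD",
                   "DAMV", "LTKEO", "SSI", "SD", "WL", "DUR", "PKF", "MNF",
                   "SM0", "SM1", "SM2", "SM3", paste0("WP", 1:8))
  interp_set <- c("AE", "MAS", "VARe", "VO", "LDMA", "LDASDA", "LCOV", "FZC")
  name <- c(td, fd)
  data.frame(
    name = name,
    index = seq_along(name),
    domain = rep(c("TD", "FD"), c(length(td), length(fd))),
    source = ifelse(name %in% formula_set, "formula",
                    ifelse(name %in% interp_set, "interpretation", "catalog")),
    stringsAsFactors = FALSE)
}

#' Default small-amplitude thresholds for the thresholded features
#' @return Named list with `zc`, `ssc`, `wa`, `myop`, `card`.
#' @export
feature_thresholds <- function() {
  list(zc = 0.01, ssc = 0.01, wa = 0.01, myop = 0.01, card = 0.01)
}

#' Absolute summation of banded fractional roots (ASM)
#'
#' `ASM = | sum_i |x_i|^{e_i} | / N` with exponent 0.5 for positions
#' `0.25*N <= i <= 0.75*N` and 0.75 elsewhere. Fractional powers are
#' applied to the absolute sample values (the filtered signal is signed).
#'
#' @param x Numeric epoch.
#' @return Nonnegative scalar.
#' @export
feature_ASM <- function(x) {
  n <- length(x)
  if (n == 0) stop("empty epoch", call. = FALSE)
  i <- seq_len(n)
  e <- ifelse(i >= 0.25 * n & i <= 0.75 * n, 0.5, 0.75)
  abs(sum(abs(x)^e)) / n
}

#' Log Teager-Kaiser energy operator (LTKEO)
#'
#' `ln( sum_{i=2}^{N-1} (x_i^2 - x_{i-1} x_{i+1}) )`. A nonpositive sum
#' (e.g. a constant sequence, where every term is zero) has no logarithm;
#' `NaN` with attribute `flagged = TRUE` is returned.
#'
#' @param x Numeric epoch (length >= 3).
#' @return Scalar, or flagged `NaN` sentinel.
#' @export
feature_LTKEO <- function(x) {
  n <- length(x)
  if (n < 3) stop("LTKEO needs length >= 3", call. = FALSE)
  s <- sum(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])
  if (s <= 0) {
    out <- NaN
    attr(out, "flagged") <- TRUE
    return(out)
  }
  log(s)
}

#' Cardinality (CARD)
#'
#' Counts adjacent pairs of the ordered sample values whose absolute
#' difference exceeds the threshold: the number of "distinct" amplitude
#' levels at the given resolution. Sorted order is the default (the random
#' shuffle sometimes quoted for this feature makes it non-deterministic);
#' `order = "shuffle"` applies a literal random permutation first.
#'
#' @param x Numeric epoch (length >= 2).
#' @param threshold Gap threshold (default 0.01).
#' @param order `"sorted"` (default) or `"shuffle"`.
#' @return Integer count in `[0, N - 1]`.
#' @export
feature_CARD <- function(x, threshold = 0.01, order = c("sorted", "shuffle")) {
  order <- match.arg(order)
  if (length(x) < 2) stop("CARD needs length >= 2", call. = FALSE)
  z <- switch(order, sorted = sort(x), shuffle = sample(x))
  sum(abs(diff(z)) > threshold)
}

#' Power spectrum of an epoch
#'
#' Plain periodogram of the de-meaned epoch: `P_j = |FFT(x - mean)|^2 / N`
#' at bins `j = 1..floor(N/2)`, `f_j = j * fs / N` (DC excluded).
#'
#' @param x Numeric epoch.
#' @param fs Sampling rate (Hz).
#' @return List with `P` (power) and `f` (Hz).
#' @export
epoch_spectrum <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  j <- seq_len(floor(n / 2))
  list(P = Mod(X[j + 1])^2 / n, f = j * fs / n)
}

#' Frequency-domain features of an epoch
#'
#' All values derive from one periodogram ([epoch_spectrum()]): median
#' frequency (MDF), mean frequency (MNF), frequency ratio (FR, low-band
#' over high-band power), peak frequency (PKF), power-spectrum ratio (PSR,
#' power within +/- `psr_halfwidth` Hz of the peak over total power), mean
#' power (MNP), spectral moments `SM_k = sum P_j f_j^k` for k = 0..3, and
#' the variance of central frequency (VCF).
#'
#' @param x Numeric epoch (length >= 64).
#' @param fs Sampling rate (Hz).
#' @param fr_low,fr_high Band edges (Hz) of the FR numerator and
#'   denominator bands.
#' @param psr_halfwidth Half-width (Hz) of the PSR peak band.
#' @return Named numeric vector of 11 values
#'   (`MDF, MNF, FR, PKF, PSR, MNP, SM0..SM3, VCF`).
#' @export
spectral_features <- function(x, fs, fr_low = c(20, 100),
                              fr_high = c(100, 250), psr_halfwidth = 10) {
  if (length(x) < 64) stop("spectral features need length >= 64", call. = FALSE)
  sp <- epoch_spectrum(x, fs)
  P <- sp$P; f <- sp$f
  tot <- sum(P)
  if (tot <= 0) stop("zero-power epoch: spectrum degenerate", call. = FALSE)
  cum <- cumsum(P)
  mdf <- f[which(cum >= tot / 2)[1]]
  mnf <- sum(f * P) / tot
  lo <- sum(P[f >= fr_low[1] & f < fr_low[2]])
  hi <- sum(P[f >= fr_high[1] & f <= fr_high[2]])
  fr <- if (hi > 0) lo / hi else Inf
  pk <- which.max(P)
  pkf <- f[pk]
  psr <- sum(P[abs(f - pkf) <= psr_halfwidth]) / tot
  sm <- vapply(0:3, function(k) sum(P * f^k), numeric(1))
  vcf <- sm[3] / sm[1] - (sm[2] / sm[1])^2
  c(MDF = mdf, MNF = mnf, FR = fr, PKF = pkf, PSR = psr, MNP = mean(P),
    SM0 = sm[1], SM1 = sm[2], SM2 = sm[3], SM3 = sm[4], VCF = vcf)
}

# One Haar analysis step: (approx, detail) at half length, orthonormal.
haar_split <- function(x) {
  if (length(x) %% 2 == 1) x <- c(x, 0)
  odd <- x[seq(1, length(x), by = 2)]
  even <- x[seq(2, length(x), by = 2)]
  list(a = (odd + even) / sqrt(2), d = (odd - even) / sqrt(2))
}

#' Haar (db1) wavelet-packet node energies at level 3
#'
#' Decomposes the epoch down a full binary wavelet-packet tree with the
#' Haar filter and returns, for each of the 8 level-3 nodes in natural
#' order, the Euclidean norm of the node's reconstruction. The transform
#' is orthonormal (the epoch is zero-padded to even length at each split,
#' which preserves the norm), so the reconstruction norm equals the norm
#' of the node's coefficient vector and the squared node norms sum to the
#' squared epoch norm. Node (3,4) in (level, index) notation is `WP5`.
#'
#' @param x Numeric epoch (length >= 2^level).
#' @param level Decomposition level.
#' @return Named numeric vector `WP1..WP{2^level}` of node norms.
#' @export
wavelet_packet_features <- function(x, level = 3) {
  if (length(x) < 2^level)
    stop(sprintf("wavelet packet needs length >= %d", 2^level), call. = FALSE)
  nodes <- list(x)
  for (l in seq_len(level)) {
    nxt <- vector("list", 2 * length(nodes))
    for (k in seq_along(nodes)) {
      sp <- haar_split(nodes[[k]])
      nxt[[2 * k - 1]] <- sp$a
      nxt[[2 * k]] <- sp$d
    }
    nodes <- nxt
  }
  norms <- vapply(nodes, function(v) sqrt(sum(v^2)), numeric(1))
  stats::setNames(norms, paste0("WP", seq_along(norms)))
}

#' Autoregressive coefficients of an epoch
#'
#' Fits an AR model of the given order by Yule-Walker (default) or Burg and
#' returns the coefficients `a(1..order)` in the convention
#' `x_t = sum_k a(k) x_{t-k} + e_t` (the innovation is the model residual).
#'
#' @param x Numeric epoch (length >= 32).
#' @param order Model order.
#' @param method `"yw"` (Yule-Walker, default) or `"burg"`.
#' @return Named numeric vector `AR1..AR{order}`.
#' @export
ar_coefficients <- function(x, order = 4, method = c("yw", "burg")) {
  method <- match.arg(method)
  if (length(x) < 32) stop("AR fit needs length >= 32", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero-variance epoch: AR model degenerate", call. = FALSE)
  fit <- switch(method,
    yw = stats::ar.yw(x, aic = FALSE, order.max = order, demean = TRUE),
    burg = stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE))
  stats::setNames(as.numeric(fit$ar), paste0("AR", seq_len(order)))
}

#' Compute the 63-value feature vector of one epoch
#'
#' Evaluates the full time- and frequency-domain feature bank on a single
#' epoch of the filtered (and typically amplitude-normalized) signal.
#' `LTKEO` can be degenerate (log of a nonpositive sum) and is then a
#' `NaN` sentinel listed in the `flags` attribute; every other value is
#' finite for any nonconstant epoch.
#'
#' @param x Numeric epoch (length >= 64 and >= 2^wp_level).
#' @param fs Sampling rate (Hz).
#' @param ar_order AR model order (4 values emitted).
#' @param wp_level Wavelet-packet level (2^level values emitted).
#' @param thresholds See [feature_thresholds()].
#' @param card_order Ordering transform for CARD.
#' @return Named numeric vector of 63 values in registry order, with
#'   attribute `flags` naming degenerate entries.
#' @export
compute_feature_vector <- function(x, fs, ar_order = 4, wp_level = 3,
                                   thresholds = feature_thresholds(),
                                   card_order = "sorted") {
  n <- length(x)
  if (n < max(64, 2^wp_level, ar_order + 1))
    stop(sprintf("epoch too short for the feature bank: %d samples", n),
         call. = FALSE)
  flags <- character(0)
  dx <- diff(x)
  ax <- abs(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  i <- seq_len(n)

  ar <- ar_coefficients(x, order = ar_order)
  ltkeo <- feature_LTKEO(x)
  if (isTRUE(attr(ltkeo, "flagged"))) flags <- c(flags, "LTKEO")

  damv <- sum(abs(dx)) / (n - 1)
  dasdv <- sqrt(sum(dx^2) / (n - 1))
  mid <- i >= 0.25 * n & i <= 0.75 * n
  mid2 <- i >= 0.2 * n & i <= 0.8 * n
  w2 <- ifelse(mid, 1, ifelse(i < 0.25 * n, 4 * i / n, 4 * (n - i) / n))

  td <- c(
    ASM = feature_ASM(x),
    ASS = abs(sum(sqrt(ax))),
    ar,
    AAC = sum(abs(dx)) / n,
    AE = mean(x^2),
    CARD = feature_CARD(x, threshold = thresholds$card, order = card_order),
    COV = stats::sd(x) / mu,
    DAMV = damv,
    DASDV = dasdv,
    DVARV = sum(dx^2) / (n - 2),
    EMAV = mean(ax^ifelse(mid2, 0.75, 0.5)),
    EWL = sum(abs(dx)^ifelse(mid2[-1], 0.75, 0.5)),
    IEMG = sum(ax),
    IQR = unname(stats::IQR(x)),
    KURT = mean((x - mu)^4) / m2^2,
    LCOV = log(stats::sd(x) / mean(ax)),
    LD = exp(mean(log(ax))),
    LDMA = log(damv),
    LDASDA = log(dasdv),
    LTKEO = as.numeric(ltkeo),
    MFL = log10(sqrt(sum(dx^2))),
    MAS = max(ax),
    MAV = mean(ax),
    MSR = mean(sqrt(ax)),
    MMAV = mean(ax * ifelse(mid, 1, 0.5)),
    MMAV2 = mean(ax * w2),
    MYOP = mean(ax >= thresholds$myop),
    FZC = sum(dx[-length(dx)] * dx[-1] < 0),
    RMS = sqrt(mean(x^2)),
    SSI = sum(x^2),
    Skew = mean((x - mu)^3) / m2^1.5,
    SSC = sum((x[2:(n - 1)] - x[1:(n - 2)]) *
                (x[2:(n - 1)] - x[3:n]) >= thresholds$ssc),
    SD = stats::sd(x),
    TM = abs(mean(x^3)),
    VAR = stats::var(x),
    VARe = mean(x^2) - mu^2,
    VO = mean(ax^3)^(1 / 3),
    WL = sum(abs(dx)),
    WA = sum(abs(dx) > thresholds$wa),
    ZC = sum(x[-n] * x[-1] < 0 & abs(dx) >= thresholds$zc),
    DUR = n / fs)

  fd <- c(spectral_features(x, fs), wavelet_packet_features(x, wp_level))
  out <- c(td, fd)
  reg <- feature_registry()
  stopifnot(length(out) == nrow(reg))
  names(out) <- reg$name
  attr(out, "flags") <- flags
  out
}
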