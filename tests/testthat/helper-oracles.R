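# Independent oracle implementations used to cross-check the package:
# exhaustive pair counting for sample entropy, direct-summation loops for
# the feature formulas, an explicit DFT for the spectral sums, an explicit
# orthogonal-matrix Haar packet transform, and hand-coded ANOVA mean
# squares for the one-way ICC. These deliberately avoid the code paths of
# the implementation (no fft, no vectorized outer products).

# Exhaustive O(N^2) sample entropy: count template pairs by double loop.
sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dmax_m <- 0
      for (k in 0:(m - 1))
        dmax_m <- max(dmax_m, abs(x[i + k] - x[j + k]))
      if (dmax_m <= r) {
        B <- B + 1L
        if (max(dmax_m, abs(x[i + m] - x[j + m])) <= r) A <- A + 1L
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# Explicit DFT power spectrum (O(N^2)), bins 1..floor(N/2), DC excluded.
dft_spectrum <- function(x, fs) {
  n <- length(x)
  xc <- x - sum(x) / n
  js <- seq_len(floor(n / 2))
  P <- numeric(length(js))
  for (j in js) {
    re <- 0; im <- 0
    for (t in seq_len(n)) {
      ang <- -2 * pi * j * (t - 1) / n
      re <- re + xc[t] * cos(ang)
      im <- im + xc[t] * sin(ang)
    }
    P[j] <- (re^2 + im^2) / n
  }
  list(P = P, f = js * fs / n)
}

# Direct-summation evaluations of the formula-defined features.
oracle_formula_features <- function(x, fs) {
  n <- length(x)
  asm <- 0
  for (i in seq_len(n)) {
    e <- if (i >= 0.25 * n && i <= 0.75 * n) 0.5 else 0.75
    asm <- asm + abs(x[i])^e
  }
  asm <- abs(asm) / n
  ass <- 0
  for (i in seq_len(n)) ass <- ass + sqrt(abs(x[i]))
  ass <- abs(ass)
  aac <- 0; wl <- 0
  for (i in seq_len(n - 1)) {
    aac <- aac + abs(x[i + 1] - x[i])
    wl <- wl + abs(x[i + 1] - x[i])
  }
  aac <- aac / n
  damv <- wl / (n - 1)
  tke <- 0
  for (i in 2:(n - 1)) tke <- tke + x[i]^2 - x[i - 1] * x[i + 1]
  ltkeo <- if (tke > 0) log(tke) else NaN
  ssi <- 0
  for (i in seq_len(n)) ssi <- ssi + x[i]^2
  mu <- sum(x) / n
  sdv <- 0
  for (i in seq_len(n)) sdv <- sdv + (x[i] - mu)^2
  sdv <- sqrt(sdv / (n - 1))
  card <- 0
  xs <- sort(x)
  for (i in seq_len(n - 1)) if (abs(xs[i + 1] - xs[i]) > 0.01) card <- card + 1
  sp <- dft_spectrum(x, fs)
  tot <- sum(sp$P)
  mnf <- sum(sp$f * sp$P) / tot
  pkf <- sp$f[which.max(sp$P)]
  sm <- sapply(0:3, function(k) sum(sp$P * sp$f^k))
  c(ASM = asm, ASS = ass, AAC = aac, DAMV = damv, LTKEO = ltkeo, SSI = ssi,
    SD = sdv, WL = wl, CARD = card, DUR = n / fs, MNF = mnf, PKF = pkf,
    SM0 = sm[1], SM1 = sm[2], SM2 = sm[3], SM3 = sm[4])
}

# Loop-based recomputations of the catalog (non-formula) features.
oracle_catalog_features <- function(x, thr = 0.01) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  iemg <- sum(abs(x))
  mav <- iemg / n
  zc <- 0; wa <- 0; ssc <- 0; fzc <- 0
  for (i in seq_len(n - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= thr) zc <- zc + 1
    if (abs(x[i + 1] - x[i]) > thr) wa <- wa + 1
  }
  for (i in 2:(n - 1))
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) >= thr) ssc <- ssc + 1
  d <- diff(x)
  for (i in seq_len(length(d) - 1)) if (d[i] * d[i + 1] < 0) fzc <- fzc + 1
  w1 <- numeric(n); w2 <- numeric(n); p_emav <- numeric(n)
  for (i in seq_len(n)) {
    w1[i] <- if (i >= 0.25 * n && i <= 0.75 * n) 1 else 0.5
    w2[i] <- if (i >= 0.25 * n && i <= 0.75 * n) 1 else
      if (i < 0.25 * n) 4 * i / n else 4 * (n - i) / n
    p_emav[i] <- if (i >= 0.2 * n && i <= 0.8 * n) 0.75 else 0.5
  }
  ewl <- 0
  for (i in 2:n) {
    p <- if (i >= 0.2 * n && i <= 0.8 * n) 0.75 else 0.5
    ewl <- ewl + abs(x[i] - x[i - 1])^p
  }
  c(AE = sum(x^2) / n,
    COV = sqrt(sum((x - mu)^2) / (n - 1)) / mu,
    DASDV = sqrt(sum(d^2) / (n - 1)),
    DVARV = sum(d^2) / (n - 2),
    EMAV = sum(abs(x)^p_emav) / n,
    EWL = ewl,
    IEMG = iemg,
    KURT = (sum((x - mu)^4) / n) / m2^2,
    LD = exp(sum(log(abs(x))) / n),
    MFL = log10(sqrt(sum(d^2))),
    MAS = max(abs(x)),
    MAV = mav,
    MSR = sum(sqrt(abs(x))) / n,
    MMAV = sum(abs(x) * w1) / n,
    MMAV2 = sum(abs(x) * w2) / n,
    MYOP = sum(abs(x) >= thr) / n,
    FZC = fzc,
    RMS = sqrt(sum(x^2) / n),
    Skew = (sum((x - mu)^3) / n) / m2^1.5,
    SSC = ssc,
    TM = abs(sum(x^3) / n),
    VAR = sum((x - mu)^2) / (n - 1),
    VARe = sum(x^2) / n - mu^2,
    VO = (sum(abs(x)^3) / n)^(1 / 3),
    WA = wa,
    ZC = zc)
}

# Explicit orthogonal-matrix Haar packet transform at level 3: the node-j
# basis vector pattern is the Kronecker product of the per-level Haar
# filters along the split path (deepest level leftmost).
oracle_haar_wp3 <- function(x) {
  h <- c(1, 1) / sqrt(2)
  g <- c(1, -1) / sqrt(2)
  n <- length(x)
  stopifnot(n %% 8 == 0)
  norms <- numeric(8)
  for (j in 0:7) {
    b1 <- j %/% 4; b2 <- (j %/% 2) %% 2; b3 <- j %% 2
    s1 <- if (b1 == 0) h else g
    s2 <- if (b2 == 0) h else g
    s3 <- if (b3 == 0) h else g
    pat <- kronecker(s3, kronecker(s2, s1))
    nc <- n / 8
    ss <- 0
    for (t in seq_len(nc)) {
      blk <- x[(8 * (t - 1) + 1):(8 * t)]
      ss <- ss + sum(blk * pat)^2
    }
    norms[j + 1] <- sqrt(ss)
  }
  norms
}

# One-way single-rater ICC from hand-coded ANOVA mean squares.
oracle_icc_oneway <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- sum(Y) / (n * k)
  msb <- 0; msw <- 0
  for (i in seq_len(n)) {
    mi <- sum(Y[i, ]) / k
    msb <- msb + (mi - grand)^2
    for (j in seq_len(k)) msw <- msw + (Y[i, j] - mi)^2
  }
  msb <- k * msb / (n - 1)
  msw <- msw / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

# Cut epochs at the ground-truth intervals of selected channels from
# filtered trials (bypasses detection where only features are under test).
truth_epochs <- function(cohort, channels = "C1", fs = 1000) {
  eps <- list()
  for (tr in cohort$trials) {
    for (ch in channels) {
      filt <- bandpass_filter(tr$recording$samples[, ch], fs = fs)
      iv <- tr$truth$intervals[[ch]]
      for (k in seq_len(nrow(iv))) {
        eps[[length(eps) + 1L]] <- list(
          subject = tr$recording$subject_id, group = tr$recording$group,
          trial = tr$recording$trial_id, channel = ch, cycle = k,
          start = iv[k, "start"], end = iv[k, "end"],
          samples = filt[iv[k, "start"]:iv[k, "end"]])
      }
    }
  }
  new_epoch_set(eps)
}

# Random nonconstant epochs for property tests.
random_epoch <- function(n = 256) stats::rnorm(n, sd = 0.3)

# Shared small-cohort feature table (all 8 channels), built once per run.
.fixture_env <- new.env(parent = emptyenv())
fixture_table <- function() {
  if (is.null(.fixture_env$tab)) {
    co <- generate_cohort(n_trials = 2, seed = 301)
    tab <- build_feature_table(
      normalize_epochs(truth_epochs(co, channels = paste0("C", 1:8))))
    .fixture_env$tab <- standardize_table(tab)
  }
  .fixture_env$tab
}
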