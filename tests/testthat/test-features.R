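# Feature bank: registry structure, formula features against
# direct-summation oracles, catalog features against loop recounts,
# wavelet-packet orthogonality, AR recovery, spectral estimates on known
# signals, scaling laws, and table standardization.

test_that("the registry expands 41 TD + 9 FD names into 63 values", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 63)
  expect_equal(sum(reg$domain == "TD"), 44)  # AR expands to 4 values
  expect_equal(sum(reg$domain == "FD"), 19)  # SM -> 4, WP -> 8
  v <- compute_feature_vector(random_epoch(256), fs = 1000)
  expect_length(v, 63)
  expect_identical(names(v), reg$name)
})

test_that("hand-computable epochs give the documented feature values", {
  # direct evaluation on tiny epochs (bypassing the length guard by
  # calling the individual feature functions)
  expect_equal(feature_ASM(rep(1, 4)), 1)
  expect_equal(feature_ASM(rep(0, 8)), 0)
  # banding check for N = 4 scaled to 4s: the inclusive band
  # 0.25N <= i <= 0.75N covers i in {1, 2, 3} (exponent 0.5), i = 4
  # falls outside (exponent 0.75)
  expect_equal(feature_ASM(rep(4, 4)),
               (4^0.5 + 4^0.5 + 4^0.5 + 4^0.75) / 4)
  expect_equal(feature_LTKEO(c(1, 2, 3, 2, 1)), log(7))
  expect_true(is.nan(feature_LTKEO(rep(2, 10))))
  expect_true(is.nan(feature_LTKEO(c(1, 0, 1))))
  expect_equal(feature_CARD(rep(5, 10)), 0)
  expect_equal(feature_CARD(c(2, 0, 3, 1)), 3)

  x <- c(1, 2, 3)
  expect_equal(sum(x^2), 14)           # SSI
  expect_equal(sum(abs(diff(x))), 2)   # WL
  o <- oracle_formula_features(c(x, rep(0, 0)), fs = 1000)
  expect_equal(unname(o["SSI"]), 14)
  expect_equal(unname(o["WL"]), 2)
  expect_equal(unname(o["DAMV"]), 1)
  expect_equal(unname(o["AAC"]), 2 / 3)
})

test_that("formula features match direct-summation oracles on random epochs", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(c(128, 200, 256), 1)
    x <- random_epoch(n)
    v <- compute_feature_vector(x, fs = 1000)
    o <- oracle_formula_features(x, fs = 1000)
    for (nm in names(o))
      expect_equal(unname(v[nm]), unname(o[nm]), tolerance = 1e-9,
                   label = sprintf("%s (epoch %d)", nm, i))
  }
})

test_that("catalog features match independent loop recounts", {
  set.seed(102)
  for (i in 1:10) {
    x <- random_epoch(180)
    v <- compute_feature_vector(x, fs = 1000)
    o <- oracle_catalog_features(x)
    for (nm in names(o))
      expect_equal(unname(v[nm]), unname(o[nm]), tolerance = 1e-9, label = nm)
    # log-composites are logs of their base features
    expect_equal(unname(v["LDMA"]), log(unname(v["DAMV"])), tolerance = 1e-12)
    expect_equal(unname(v["LDASDA"]), log(unname(v["DASDV"])), tolerance = 1e-12)
    expect_equal(unname(v["LCOV"]), log(unname(v["SD"]) / unname(v["MAV"])),
                 tolerance = 1e-12)
  }
})

test_that("wavelet packet node norms are orthogonal and match the matrix oracle", {
  expect_equal(unname(wavelet_packet_features(rep(0, 64))), rep(0, 8))
  set.seed(103)
  for (i in 1:20) {
    x <- random_epoch(sample(c(64, 96, 128, 250), 1))
    wp <- wavelet_packet_features(x)
    expect_equal(sum(wp^2), sum(x^2), tolerance = 1e-9)  # Parseval
  }
  ramp <- seq_len(64) / 64
  expect_equal(unname(wavelet_packet_features(ramp)), oracle_haar_wp3(ramp),
               tolerance = 1e-9)
  x <- random_epoch(128)
  expect_equal(unname(wavelet_packet_features(x)), oracle_haar_wp3(x),
               tolerance = 1e-9)
  expect_error(wavelet_packet_features(1:4), "length")
})

test_that("AR coefficients recover known processes", {
  set.seed(104)
  a1 <- ar_coefficients(rnorm(1e5))
  expect_true(all(abs(a1) < 0.02))
  # AR(1) with coefficient 0.5
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), n = 1e5))
  a2 <- ar_coefficients(x)
  expect_lt(abs(a2["AR1"] - 0.5), 0.02)
  expect_true(all(abs(a2[2:4]) < 0.02))
  expect_error(ar_coefficients(rep(1, 100)), "degenerate")
})

test_that("spectral features locate known spectra", {
  fs <- 1000
  t <- seq_len(4096) / fs
  x <- sin(2 * pi * 100 * t)
  sf <- spectral_features(x, fs)
  expect_lt(abs(sf["PKF"] - 100), fs / 4096 + 1e-9)  # within one bin
  expect_lt(abs(sf["MNF"] - 100), 1)
  expect_equal(unname(sf["SM0"]), sum(epoch_spectrum(x, fs)$P),
               tolerance = 1e-12)
  # white noise: MNF near fs/4 over the full band
  set.seed(105)
  mnfs <- replicate(20, spectral_features(rnorm(2048), fs)["MNF"])
  expect_lt(abs(mean(mnfs) - fs / 4), 10)
  expect_error(spectral_features(rep(0, 128), fs), "degenerate")
})

test_that("features obey their scaling laws", {
  set.seed(106)
  x <- random_epoch(200)
  a <- 3.7
  v1 <- compute_feature_vector(x, fs = 1000)
  va <- compute_feature_vector(a * x, fs = 1000)
  expect_equal(unname(va["SSI"]), a^2 * unname(v1["SSI"]), tolerance = 1e-9)
  for (nm in c("WL", "AAC", "DAMV", "SD", "MAV"))
    expect_equal(unname(va[nm]), a * unname(v1[nm]), tolerance = 1e-9,
                 label = nm)
  expect_equal(unname(va["DUR"]), unname(v1["DUR"]))
  # thresholded counters are scale-free once their thresholds co-scale
  # (SSC thresholds a product of differences, so its threshold carries
  # squared amplitude units)
  thr <- feature_thresholds()
  thr_a <- lapply(thr, function(s) a * s)
  thr_a$ssc <- a^2 * thr$ssc
  va2 <- compute_feature_vector(a * x, fs = 1000, thresholds = thr_a)
  for (nm in c("ZC", "SSC", "WA", "CARD", "MYOP"))
    expect_equal(unname(va2[nm]), unname(v1[nm]), label = nm)
  expect_equal(unname(va["DUR"]), length(x) / 1000)
  expect_error(compute_feature_vector(rnorm(32), fs = 1000), "short")
})

test_that("standardization pools groups per feature and channel and inverts", {
  tab <- fixture_table()
  fcols <- feature_columns(tab)
  zv <- attr(tab, "zero_variance")
  for (ch in c("C1", "C6")) {
    ok <- fcols[!paste(fcols, ch, sep = "|") %in% zv]
    sub <- tab[tab$channel == ch, ]
    mus <- colMeans(sub[, ok])
    sds <- apply(sub[, ok], 2, sd)
    expect_true(all(abs(mus) < 1e-9))
    expect_true(all(abs(sds - 1) < 1e-9))
  }
  # idempotent
  tab2 <- standardize_table(tab)
  expect_equal(tab2[, fcols], tab[, fcols], tolerance = 1e-12)
  # inverse recovers the raw values
  raw <- build_feature_table(
    normalize_epochs(truth_epochs(generate_cohort(n_trials = 1, seed = 301,
                                                  n_amateur = 2,
                                                  n_professional = 2),
                                  "C1")))
  std <- standardize_table(raw)
  back <- unstandardize_table(std)
  expect_equal(back[, fcols], raw[, fcols], tolerance = 1e-9)
})
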