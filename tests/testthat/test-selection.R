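# Feature selection: ICC against the mean-squares oracle, t-test matrix
# calibration, and the staged reduction structure of Methods A and B.

test_that("one-way ICC matches the ANOVA mean-squares oracle", {
  # 4-target, 2-rater toy table
  Y <- cbind(c(9, 6, 8, 7), c(2, 1, 4, 1))
  tab <- fixture_table()
  icc <- icc_matrix(tab)
  expect_equal(unname(diag(icc)[1]), 1)
  expect_true(isSymmetric(unclass(icc)))
  expect_true(all(icc[is.finite(icc)] >= -1 - 1e-12 &
                  icc[is.finite(icc)] <= 1 + 1e-12))
  expect_equal(semgcurl:::icc_oneway(Y), oracle_icc_oneway(Y),
               tolerance = 1e-12)
  set.seed(201)
  for (i in 1:5) {
    Z <- matrix(rnorm(40), 20, 2)
    expect_equal(semgcurl:::icc_oneway(Z), oracle_icc_oneway(Z),
                 tolerance = 1e-12)
  }
})

test_that("a feature paired with its copy has ICC 1; independent noise near 0", {
  expect_equal(semgcurl:::icc_oneway(cbind(1:10, 1:10)), 1)
  set.seed(202)
  Z <- matrix(rnorm(2e4), ncol = 2)
  expect_lt(abs(semgcurl:::icc_oneway(Z)), 0.05)
})

test_that("the t-test matrix is calibrated and detects gross separation", {
  # identical group distributions: H = 1 rate near the 5% level
  set.seed(203)
  hits <- 0; cells <- 0
  for (s in 1:10) {
    n <- 40
    tab <- data.frame(
      subject = "S", group = rep(c("amateur", "professional"), each = n),
      trial = "T1", channel = "C1", cycle = 1,
      ASM = rnorm(2 * n), RMS = rnorm(2 * n), MNF = rnorm(2 * n),
      WL = rnorm(2 * n), DUR = rnorm(2 * n))
    class(tab) <- c("feature_table", class(tab))
    tm <- ttest_matrix(tab)
    hits <- hits + sum(tm$H, na.rm = TRUE)
    cells <- cells + sum(is.finite(tm$p))
  }
  rate <- hits / cells
  se <- sqrt(0.05 * 0.95 / cells)
  expect_lt(abs(rate - 0.05), 4 * se + 0.01)

  # overwhelming separation
  tab2 <- data.frame(
    subject = "S", group = rep(c("amateur", "professional"), each = 150),
    trial = "T1", channel = "C1", cycle = 1,
    RMS = c(rnorm(150), rnorm(150) + 5))
  class(tab2) <- c("feature_table", class(tab2))
  expect_equal(unname(ttest_matrix(tab2)$H["RMS", "C1"]), 1L)

  # identical samples: t = 0, p = 1
  tab3 <- tab2
  tab3$RMS <- rep(c(1, 2, 3), 100)
  expect_equal(unname(ttest_matrix(tab3)$p["RMS", "C1"]), 1)
})

test_that("staged reduction is nested and accounts for all 63 features", {
  tab <- fixture_table()
  icc <- icc_matrix(tab)
  tests <- ttest_matrix(tab)
  for (m in c("A", "B")) {
    sel <- reduce_features(m, tests, icc)
    s <- sel$stages
    expect_true(all(s[[3]] %in% s[[2]]))
    expect_true(all(s[[2]] %in% s[[1]]))
    expect_true(length(s[[3]]) < length(s[[2]]))
    expect_true(length(s[[2]]) < length(s[[1]]))
    expect_equal(length(sel$Z1) + length(sel$Z2) + length(sel$Z3) +
                   length(s[[3]]), 63)
    expect_equal(length(s[[3]]), sel$config$target_size)
    # stage-2 representatives are mutually non-redundant within groups:
    # every removed feature was grouped with a kept one
    expect_true(all(c(sel$Z2, s[[2]]) %in% s[[1]]))
  }
  selB <- reduce_features("B", tests, icc)
  expect_false("C6" %in% selB$consulted_channels)
  expect_true("C6" %in% reduce_features("A", tests, icc)$consulted_channels)
})

test_that("stage 2 keeps the lowest-mean-p representative of a redundant group", {
  # construct a tiny synthetic test/icc pair over 5 features
  feats <- c("F1", "F2", "F3", "F4", "F5")
  P <- matrix(0.001, 5, 2, dimnames = list(feats, c("C1", "C2")))
  P["F1", ] <- c(0.0001, 0.0001)  # best of the redundant trio
  P["F2", ] <- c(0.001, 0.001)
  P["F3", ] <- c(0.002, 0.002)
  tests <- structure(list(p = P, H = 1L * (P < 0.05), level = 0.05),
                     class = "ttest_matrix")
  icc <- matrix(0, 5, 5, dimnames = list(feats, feats))
  diag(icc) <- 1
  icc[c("F1", "F2", "F3"), c("F1", "F2", "F3")] <- 0.95
  sel <- reduce_features("A", tests, icc,
                         config = list(k_min = 1, target_size = 2,
                                       excluded_channels = character(0)))
  expect_true("F1" %in% sel$stages[[2]])
  expect_true(all(c("F2", "F3") %in% sel$Z2))
  expect_length(sel$stages[[3]], 2)
})

test_that("Method B is invariant to corruption of channel C6 statistics", {
  tab <- fixture_table()
  icc <- icc_matrix(tab)
  tests <- ttest_matrix(tab)
  sel <- reduce_features("B", tests, icc)
  corrupted <- tests
  set.seed(204)
  corrupted$p[, "C6"] <- runif(nrow(corrupted$p))
  corrupted$H[, "C6"] <- sample(0:1, nrow(corrupted$H), replace = TRUE)
  sel2 <- reduce_features("B", corrupted, icc)
  expect_identical(sel$stages, sel2$stages)
  expect_identical(sel$Z1, sel2$Z1)
  # Method A is NOT invariant in general (it consults C6)
  selA <- reduce_features("A", tests, icc)
  expect_true("C6" %in% selA$consulted_channels)
})

test_that("class effects put amplitude and spectral families in stage 3", {
  tab <- fixture_table()
  sel <- reduce_features("B", ttest_matrix(tab), icc_matrix(tab))
  amp_family <- c("RMS", "MAV", "SSI", "WL", "IEMG", "SD", "VAR", "VARe",
                  "AE", "ASS", "ASM", "MSR", "MMAV", "MMAV2", "EMAV", "VO",
                  "MAS", "EWL", "AAC", "DAMV", "DASDV")
  spec_family <- c("MNF", "MDF", "PKF", "FR", "VCF", "SM0", "SM1", "SM2",
                   "SM3", paste0("WP", 1:8))
  expect_gte(length(intersect(sel$stages[[3]], amp_family)), 1)
  expect_gte(length(intersect(sel$stages[[3]], spec_family)), 1)
})

test_that("a configuration that empties a stage raises an explicit error", {
  tab <- fixture_table()
  tests <- ttest_matrix(tab)
  icc <- icc_matrix(tab)
  expect_error(reduce_features("A", tests, icc, config = list(k_min = 9)),
               "stage 1")
  expect_error(reduce_features("A", tests, icc,
                               config = list(target_size = 63)),
               "stage 2")
})
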