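# Classification evaluation: separable and chance-level behaviour,
# determinism, the decibel significance transform, and ANOVA/Tukey against
# the closed-form two-group reduction.

test_that("a perfectly separated 1-D feature gives accuracy 1 for every model", {
  set.seed(301)
  n <- 60
  X <- matrix(c(rnorm(n, -10), rnorm(n, 10)), ncol = 1)
  y <- rep(c("amateur", "professional"), each = n)
  for (m in c("LDA", "SVM2", "SVMcore", "Subspace")) {
    cv <- crossval(X, y, cv_config(model = m, repeats = 3, shuffle_seed = 5))
    expect_equal(cv$mu, 1, label = m)
  }
})

test_that("permuted labels give chance-level accuracy", {
  set.seed(302)
  X <- matrix(rnorm(300 * 4), 300, 4)
  y <- sample(rep(c("amateur", "professional"), each = 150))
  cv <- crossval(X, y, cv_config(model = "LDA", repeats = 5, shuffle_seed = 7))
  se <- sqrt(0.25 / 300)
  expect_lt(abs(cv$mu - 0.5), 3 * se)
})

test_that("cross-validation is deterministic under a fixed seed", {
  set.seed(303)
  X <- matrix(rnorm(100 * 3), 100, 3)
  y <- rep(c("a", "b"), each = 50)
  cv1 <- crossval(X, y, cv_config(model = "SVM2", repeats = 3, shuffle_seed = 9))
  cv2 <- crossval(X, y, cv_config(model = "SVM2", repeats = 3, shuffle_seed = 9))
  expect_identical(cv1$accuracy, cv2$accuracy)
  expect_identical(cv1$mu, cv2$mu)
  cv3 <- crossval(X, y, cv_config(model = "SVM2", repeats = 3, shuffle_seed = 10))
  expect_false(identical(cv1$accuracy, cv3$accuracy))
  # accuracy is a fraction internally
  expect_true(all(cv1$accuracy >= 0 & cv1$accuracy <= 1))
  expect_error(crossval(X[1:15, ], y[c(1:10, 51:55)],
                        cv_config(model = "LDA")), "stratification|fold")
})

test_that("accuracy does not fall as the class amplitude effect grows", {
  # three amplitude-ratio levels with the spectral shift held at zero;
  # amplitude normalization removes most of the scale effect, so the
  # curve may be flat -- it must not decrease by more than one pooled SD
  mus <- sigmas <- numeric(3)
  ratios <- c(1, 1.5, 2)
  for (i in seq_along(ratios)) {
    co <- generate_cohort(
      n_amateur = 3, n_professional = 3, n_trials = 2,
      class_effects = list(amplitude_ratio = ratios[i],
                           median_freq_shift_hz = 0, duration_ratio = 1),
      seed = 310)
    tab <- standardize_table(build_feature_table(
      normalize_epochs(truth_epochs(co, "C1"))))
    cv <- crossval(tab[, f12b_features()], tab$group,
                   cv_config(model = "SVM2", repeats = 5, shuffle_seed = 311))
    mus[i] <- cv$mu; sigmas[i] <- cv$sigma
  }
  pooled <- sqrt(mean(sigmas^2))
  expect_gte(mus[2], mus[1] - pooled)
  expect_gte(mus[3], mus[2] - pooled)
})

test_that("the decibel transform of p-values behaves as documented", {
  expect_equal(abs(log10(0.05)), 1.30103, tolerance = 1e-5)
  # engineered collections with known p-values
  a <- c(-1, 0, 1); b <- c(-1, 0, 1)
  r <- significance_db(a, b)          # identical: t = 0, p = 1
  expect_equal(r$dB, 0)
  expect_true(r$no_difference)
  r2 <- significance_db(rep(0.5, 5), rep(0.5, 5))  # zero variance path
  expect_equal(r2$p, 1)
  expect_equal(r2$dB, 0)
  set.seed(304)
  r3 <- significance_db(rnorm(50), rnorm(50, 10))
  expect_gt(r3$dB, 10)
  expect_false(r3$no_difference)
  # dB = |log10 p| for the computed p
  expect_equal(r3$dB, abs(log10(r3$p)))
})

test_that("ANOVA and Tukey HSD find injected feature shifts", {
  tab <- fixture_table()
  f12 <- f12b_features()
  res <- anova_tukey(tab, f12, group = "amateur", channel = "C1")
  expect_true(is.finite(res$anova_p))
  # a 10-SD shifted copy drives the ANOVA and every pair involving it
  tab2 <- tab[tab$group == "amateur" & tab$channel == "C1", ]
  tab2$RMS <- tab2$RMS + 10
  res2 <- anova_tukey(tab2, c("RMS", "MNF", "WL", "DUR"))
  expect_lt(res2$anova_p, 1e-6)
  expect_true(all(res2$tukey["RMS", c("MNF", "WL", "DUR")] < 0.01))
  expect_true(all(is.na(diag(res2$tukey))))
})

test_that("the feature ANOVA is calibrated under exchangeable columns", {
  set.seed(306)
  n_sig <- 0
  n_sim <- 200
  for (s in seq_len(n_sim)) {
    tab <- as.data.frame(matrix(rnorm(30 * 6), 30, 6))
    names(tab) <- c("RMS", "MNF", "WL", "DUR", "SSI", "SD")
    tab$group <- "amateur"; tab$channel <- "C1"
    res <- anova_tukey(tab, names(tab)[1:6])
    if (res$anova_p < 0.05) n_sig <- n_sig + 1
  }
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(n_sig / n_sim - 0.05), 4 * se)
})

test_that("two-column Tukey p equals the mean-squares t-test reduction", {
  tab <- fixture_table()
  sub <- tab[tab$group == "professional" & tab$channel == "C2", ]
  sub$MNF <- sub$MNF + 0.5  # ensure significance so Tukey runs
  res <- anova_tukey(sub, c("MNF", "DUR"))
  # closed form: with 2 groups, Tukey's q = sqrt(2)|t| and the adjusted p
  # equals the two-sided pooled t-test p from the same mean squares
  v <- c(sub$MNF, sub$DUR)
  g <- rep(c("MNF", "DUR"), each = nrow(sub))
  p_t <- stats::t.test(v ~ g, var.equal = TRUE)$p.value
  expect_equal(unname(res$tukey["MNF", "DUR"]), p_t, tolerance = 1e-9)
})

test_that("the evaluation report aggregates cells and tolerates emptiness", {
  set.seed(305)
  X <- matrix(c(rnorm(30, -3), rnorm(30, 3)), ncol = 1)
  y <- rep(c("a", "b"), each = 30)
  cv <- crossval(X, y, cv_config(model = "LDA", repeats = 2, shuffle_seed = 1))
  rep1 <- evaluation_report(list(F12B = list(LDA = cv)))
  expect_equal(nrow(rep1$summary), 1)
  expect_equal(rep1$summary$mu, cv$mu)
  expect_warning(rep0 <- evaluation_report(list()), "empty")
  expect_equal(nrow(rep0$summary), 0)
})
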