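# Repeated stratified 10-fold cross-validation of four classifier
# families, decibel-scaled significance comparisons of accuracy
# collections, and one-way ANOVA with Tukey HSD across a feature set.

#' Cross-validation configuration
#'
#' @param folds Number of folds (default 10).
#' @param repeats Shuffle-and-refold repetitions (default 20).
#' @param model One of `"LDA"`, `"SVM2"` (quadratic-kernel SVM),
#'   `"SVMcore"` (RBF-kernel SVM), `"Subspace"`
#'   (subspace-discriminant ensemble: random feature-subspace LDA learners
#'   with majority vote).
#' @param shuffle_seed Integer seed; each repeat derives its own
#'   sub-seed.
#' @param n_learners,subspace_size Ensemble parameters (defaults: 30
#'   learners on subspaces of half the feature dimension, rounded up).
#' @param cost SVM cost parameter.
#' @return List of class `cv_config`.
#' @export
cv_config <- function(folds = 10L, repeats = 20L,
                      model = c("LDA", "SVM2", "SVMcore", "Subspace"),
                      shuffle_seed = 1L, n_learners = 30L,
                      subspace_size = NULL, cost = 1) {
  model <- match.arg(model)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 model = model, shuffle_seed = as.integer(shuffle_seed),
                 n_learners = as.integer(n_learners),
                 subspace_size = subspace_size, cost = cost,
                 stratified = TRUE),
            class = "cv_config")
}

# A redundant feature bank makes within-group covariance near-singular;
# lda()'s collinearity warning is expected and muffled.
quiet_lda <- function(...) {
  withCallingHandlers(MASS::lda(...), warning = function(w) {
    if (grepl("collinear", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

fit_predict <- function(model, Xtr, ytr, Xte, config) {
  switch(model,
    LDA = {
      fit <- quiet_lda(Xtr, grouping = ytr)
      stats::predict(fit, Xte)$class
    },
    SVM2 = {
      fit <- e1071::svm(Xtr, ytr, kernel = "polynomial", degree = 2,
                        coef0 = 1, cost = config$cost, scale = FALSE)
      stats::predict(fit, Xte)
    },
    SVMcore = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = config$cost,
                        scale = FALSE)
      stats::predict(fit, Xte)
    },
    Subspace = {
      d <- ncol(Xtr)
      ss <- config$subspace_size %||% ceiling(d / 2)
      votes <- matrix(0L, nrow(Xte), nlevels(ytr))
      for (b in seq_len(config$n_learners)) {
        keep <- sample.int(d, ss)
        fit <- quiet_lda(Xtr[, keep, drop = FALSE], grouping = ytr)
        pr <- stats::predict(fit, Xte[, keep, drop = FALSE])$class
        votes[cbind(seq_len(nrow(Xte)), as.integer(pr))] <-
          votes[cbind(seq_len(nrow(Xte)), as.integer(pr))] + 1L
      }
      factor(levels(ytr)[max.col(votes, ties.method = "first")],
             levels = levels(ytr))
    },
    stop(sprintf("unknown model '%s'", model), call. = FALSE))
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat the rows are reshuffled with a derived seed, folds are
#' stratified by class, and the per-repeat accuracy is the mean over folds
#' of (TP + TN) / (P + N). Accuracy is held as a fraction internally; the
#' conventional x100 presentation is applied only when printing.
#'
#' @param X Numeric matrix or data frame of features (one channel, one
#'   feature group).
#' @param y Two-level factor (or coercible) of class labels.
#' @param config A [cv_config()].
#' @return List of class `cv_result`: `accuracy` (per repeat), `mu`,
#'   `sigma`, `folds` (per-fold confusion counts of the last repeat),
#'   `config`.
#' @export
crossval <- function(X, y, config = cv_config()) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) stop("`y` must have exactly two classes", call. = FALSE)
  if (min(table(y)) < config$folds)
    stop(sprintf("each class needs >= %d members for %d-fold stratification",
                 config$folds, config$folds), call. = FALSE)
  K <- config$folds
  acc <- numeric(config$repeats)
  fold_counts <- NULL
  for (rep_i in seq_len(config$repeats)) {
    res <- with_seed(derive_seed(config$shuffle_seed, "cvrep", rep_i), {
      # stratified fold assignment after a class-wise shuffle
      fold <- integer(length(y))
      for (lv in levels(y)) {
        idx <- sample(which(y == lv))
        fold[idx] <- rep_len(seq_len(K), length(idx))
      }
      fk <- matrix(0, K, 2, dimnames = list(NULL, c("correct", "total")))
      for (k in seq_len(K)) {
        te <- fold == k
        pred <- fit_predict(config$model, X[!te, , drop = FALSE], y[!te],
                            X[te, , drop = FALSE], config)
        fk[k, ] <- c(sum(pred == y[te]), sum(te))
      }
      list(acc = mean(fk[, "correct"] / fk[, "total"]), fk = fk)
    })
    acc[rep_i] <- res$acc
    fold_counts <- res$fk
  }
  structure(list(accuracy = acc, mu = mean(acc), sigma = stats::sd(acc),
                 folds = fold_counts, config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s: accuracy %.2f%% (sd %.2f%%) over %d repeats of %d-fold CV\n",
              x$config$model, 100 * x$mu, 100 * x$sigma,
              x$config$repeats, x$config$folds))
  invisible(x)
}

#' Decibel-scaled significance of an accuracy difference
#'
#' Two-sample t-test between two accuracy collections, reported as
#' `dB = |log10(p)|`. Values at or below 1.301 (p >= 0.05) indicate no
#' significant difference. Identical zero-variance collections give p = 1
#' and dB = 0.
#'
#' @param acc_a,acc_b Numeric vectors of accuracies (length >= 2).
#' @param level Significance level for the no-difference flag.
#' @return List of class `significance_db`: `p`, `dB`, `no_difference`.
#' @export
significance_db <- function(acc_a, acc_b, level = 0.05) {
  if (length(acc_a) < 2 || length(acc_b) < 2)
    stop("both accuracy collections need >= 2 values", call. = FALSE)
  if (stats::sd(acc_a) == 0 && stats::sd(acc_b) == 0 &&
      mean(acc_a) == mean(acc_b)) {
    p <- 1
  } else {
    p <- stats::t.test(acc_a, acc_b, var.equal = TRUE)$p.value
  }
  dB <- abs(log10(p))
  structure(list(p = p, dB = dB, no_difference = dB <= abs(log10(level))),
            class = "significance_db")
}

#' One-way ANOVA and Tukey HSD across a feature set
#'
#' Stacks the selected (standardized) feature columns of one subject group
#' and channel into long form and tests whether the features differ in
#' mean across epochs with a one-way ANOVA; when significant, Tukey HSD
#' pairwise p-values identify which feature pairs differ.
#'
#' @param table A standardized `feature_table` restricted to one group and
#'   channel (or pass `group`/`channel` to subset).
#' @param features Character vector of feature names (e.g. a stage-3 set).
#' @param group,channel Optional subset labels.
#' @param level Significance level.
#' @return List of class `anova_tukey`: `anova_p`, `tukey` (symmetric
#'   pairwise p matrix with `NA` diagonal, `NULL` when the ANOVA is not
#'   significant), `level`.
#' @export
anova_tukey <- function(table, features, group = NULL, channel = NULL,
                        level = 0.05) {
  if (!is.null(group)) table <- table[table$group == group, , drop = FALSE]
  if (!is.null(channel)) table <- table[table$channel == channel, , drop = FALSE]
  if (nrow(table) < 2) stop("need >= 2 epochs", call. = FALSE)
  features <- intersect(features, names(table))
  long <- data.frame(
    value = unlist(table[, features], use.names = FALSE),
    feature = factor(rep(features, each = nrow(table)), levels = features))
  if (stats::var(long$value) == 0)
    stop("degenerate variance in the stacked features", call. = FALSE)
  fit <- stats::aov(value ~ feature, data = long)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tukey <- NULL
  if (is.finite(anova_p) && anova_p < level) {
    tk <- stats::TukeyHSD(fit)$feature
    M <- matrix(NA_real_, length(features), length(features),
                dimnames = list(features, features))
    pair <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (r in seq_along(pair)) {
      a <- pair[[r]][1]; b <- pair[[r]][2]
      M[a, b] <- M[b, a] <- tk[r, "p adj"]
    }
    tukey <- M
  }
  structure(list(anova_p = anova_p, tukey = tukey, level = level),
            class = "anova_tukey")
}

#' Assemble an evaluation report
#'
#' Collects completed cross-validation results into mean/SD tables per
#' (feature group, model), with optional per-channel accuracy curves and
#' dB comparison tables.
#'
#' @param results Named list: `results[[group]][[model]]` is either a
#'   `cv_result` or a named list of per-channel `cv_result`s.
#' @return List of class `evaluation_report`: `summary` (data frame of
#'   mu/sigma per feature group and model, aggregated over channels x
#'   repeats where per-channel results are supplied, with the aggregation
#'   mode recorded) and `cells` (the raw inputs).
#' @export
evaluation_report <- function(results) {
  rows <- list()
  for (grp in names(results)) {
    for (mdl in names(results[[grp]])) {
      cell <- results[[grp]][[mdl]]
      if (inherits(cell, "cv_result")) {
        accs <- cell$accuracy
        mode <- "repeats"
      } else {
        accs <- unlist(lapply(cell, function(cv) cv$accuracy))
        mode <- "channels x repeats"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature_group = grp, model = mdl, mu = mean(accs),
        sigma = stats::sd(accs), n = length(accs), aggregation = mode,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    warning("no completed cells: empty report")
    summary <- data.frame(feature_group = character(0), model = character(0),
                          mu = numeric(0), sigma = numeric(0),
                          n = integer(0), aggregation = character(0))
  } else {
    summary <- do.call(rbind, rows)
  }
  structure(list(summary = summary, cells = results),
            class = "evaluation_report")
}
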