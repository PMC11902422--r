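# Staged feature reduction: an ICC consistency matrix finds redundant
# feature pairs, per-channel two-sample t-tests find discriminative ones,
# and Methods A and B prune the 63-feature bank in three stages. Method B
# excludes channel C6 from every p-value/H-value condition.

# One-way single-rater ICC for an n x k matrix of measurements
# (targets = rows). Computed from the ANOVA mean squares:
# ICC(1) = (MSB - MSW) / (MSB + (k-1) MSW).
icc_oneway <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  m <- rowMeans(Y)
  grand <- mean(Y)
  msb <- k * sum((m - grand)^2) / (n - 1)
  msw <- sum((Y - m)^2) / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Pairwise ICC consistency matrix of the feature bank
#'
#' Features are first averaged across the 8 channels within each epoch
#' (rows matched on subject, trial and cycle), then for every feature pair
#' a one-way single-rater ICC is computed with epochs as targets and the
#' two features as the repeated measurements. Pairs with ICC above the
#' grouping threshold are considered mutually consistent (redundant).
#'
#' @param table A standardized `feature_table` (>= 3 epochs).
#' @return A 63 x 63 symmetric matrix of class `icc_matrix` with unit
#'   diagonal; rows/columns of zero-variance features are `NA` and listed
#'   in the `undefined` attribute.
#' @export
icc_matrix <- function(table) {
  fcols <- feature_columns(table)
  key <- interaction(table$subject, table$trial, table$cycle, drop = TRUE)
  if (nlevels(key) < 3)
    stop("need >= 3 epochs for the ICC matrix", call. = FALSE)
  X <- apply(table[, fcols, drop = FALSE], 2, function(v)
    tapply(v, key, mean))
  p <- length(fcols)
  M <- matrix(NA_real_, p, p, dimnames = list(fcols, fcols))
  vars <- apply(X, 2, stats::var)
  ok <- which(is.finite(vars) & vars > 0)
  for (a in ok) {
    M[a, a] <- 1
    for (b in ok[ok > a]) {
      M[a, b] <- M[b, a] <- icc_oneway(X[, c(a, b)])
    }
  }
  undefined <- fcols[setdiff(seq_len(p), ok)]
  structure(M, class = c("icc_matrix", "matrix"), undefined = undefined)
}

#' Per-channel two-sample t-test matrix
#'
#' A pooled-variance two-sample t-test of amateur vs professional epochs,
#' per feature and channel. `H = 1` records rejection at the given level.
#'
#' @param table A `feature_table` (standardized or not; the t statistic is
#'   location/scale invariant within a channel).
#' @param level Significance level (default 0.05).
#' @param var_equal Pooled variance (classical two-sample, default) or
#'   Welch when `FALSE`.
#' @return List of class `ttest_matrix`: `p` and `H` (features x
#'   channels), and `level`.
#' @export
ttest_matrix <- function(table, level = 0.05, var_equal = TRUE) {
  fcols <- feature_columns(table)
  channels <- unique(table$channel)
  groups <- unique(table$group)
  if (length(groups) != 2)
    stop("need exactly two groups for the t-test matrix", call. = FALSE)
  P <- matrix(NA_real_, length(fcols), length(channels),
              dimnames = list(fcols, channels))
  for (ch in channels) {
    idx <- table$channel == ch
    g <- table$group[idx]
    if (min(table(g)) < 2)
      stop(sprintf("channel %s: a group has < 2 epochs", ch), call. = FALSE)
    for (fc in fcols) {
      v <- table[idx, fc]
      if (any(!is.finite(v)) || stats::sd(v) == 0) next
      P[fc, ch] <- stats::t.test(v ~ g, var.equal = var_equal)$p.value
    }
  }
  structure(list(p = P, H = 1L * (P < level), level = level),
            class = "ttest_matrix")
}

# Redundancy groups of the ICC > threshold graph over `members`.
# "clique": greedy mutual-consistency grouping in registry order -- a
# feature joins a group only if it is consistent with EVERY member, so
# group members are pairwise consistent. "component": connected
# components (chains may link features that are not pairwise consistent).
icc_groups <- function(icc, members, threshold,
                       mode = c("clique", "component")) {
  mode <- match.arg(mode)
  adj <- icc[members, members, drop = FALSE] > threshold
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  if (mode == "clique") {
    groups <- list()
    for (f in members) {
      placed <- FALSE
      for (gi in seq_along(groups)) {
        if (all(adj[f, groups[[gi]]])) {
          groups[[gi]] <- c(groups[[gi]], f)
          placed <- TRUE
          break
        }
      }
      if (!placed) groups[[length(groups) + 1L]] <- f
    }
    return(groups)
  }
  comp <- rep(0L, length(members))
  cur <- 0L
  for (s in seq_along(members)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  split(members, comp)
}

#' Staged feature reduction (Methods A and B)
#'
#' Three-stage pruning of the 63-feature bank. Stage 1 removes features
#' (`Z1`) that are significant (`H = 1`) in fewer than `k_min` of the
#' consulted channels. Stage 2 groups the survivors by mutual consistency
#' (every pair within a group has ICC > `icc_threshold`; greedy grouping
#' in registry order) and removes
#' all but one representative per group (`Z2`); the representative is the
#' member with the lowest mean p-value across the consulted channels, ties
#' broken by lower registry index. Stage 3 keeps the `target_size`
#' survivors with the lowest mean p-value (`Z3` removed). Method B
#' excludes channel C6 (configurable) from every p/H condition; Method A
#' consults all channels.
#'
#' @param method `"A"` or `"B"`.
#' @param tests A [ttest_matrix()].
#' @param icc An [icc_matrix()].
#' @param config Optional overrides: `icc_threshold` (0.8), `k_min`
#'   (default: half the consulted channels, rounded up), `target_size`
#'   (12), `excluded_channels` (`"C6"` for Method B), `group_mode`
#'   (`"clique"` default, `"component"` for connected components).
#' @return List of class `selection_result`: `method`, `Z1`, `Z2`, `Z3`
#'   (removed feature names per stage), `stages` (named surviving sets,
#'   e.g. `F50B`, `F16B`, `F12B`), and `config` (all thresholds used).
#' @export
reduce_features <- function(method = c("A", "B"), tests, icc,
                            config = list()) {
  method <- match.arg(method)
  channels <- colnames(tests$p)
  cfg <- utils::modifyList(list(
    icc_threshold = 0.8,
    k_min = NULL,
    target_size = 12L,
    group_mode = "clique",
    excluded_channels = if (method == "B") "C6" else character(0)
  ), config)
  consulted <- setdiff(channels, cfg$excluded_channels)
  if (is.null(cfg$k_min)) cfg$k_min <- ceiling(length(consulted) / 2)

  features <- rownames(tests$p)
  H <- tests$H[, consulted, drop = FALSE]
  Pm <- tests$p[, consulted, drop = FALSE]
  breadth <- rowSums(H == 1L, na.rm = TRUE)
  mean_p <- rowMeans(Pm, na.rm = TRUE)
  mean_p[!is.finite(mean_p)] <- 1

  stage1 <- features[breadth >= cfg$k_min]
  if (length(stage1) == 0)
    stop("stage 1 removed every feature; relax `k_min`", call. = FALSE)
  Z1 <- setdiff(features, stage1)

  groups <- icc_groups(icc, stage1, cfg$icc_threshold, mode = cfg$group_mode)
  reg_index <- stats::setNames(seq_along(features), features)
  stage2 <- vapply(groups, function(g) {
    g[order(mean_p[g], reg_index[g])][1]
  }, character(1))
  stage2 <- features[features %in% stage2]  # registry order
  Z2 <- setdiff(stage1, stage2)

  if (length(stage2) < cfg$target_size)
    stop(sprintf(
      "stage 2 left %d features, fewer than the stage-3 target of %d",
      length(stage2), cfg$target_size), call. = FALSE)
  stage3 <- stage2[order(mean_p[stage2], reg_index[stage2])][seq_len(cfg$target_size)]
  stage3 <- features[features %in% stage3]
  Z3 <- setdiff(stage2, stage3)

  stages <- stats::setNames(
    list(stage1, stage2, stage3),
    paste0("F", c(length(stage1), length(stage2), length(stage3)), method))
  structure(list(method = method, Z1 = Z1, Z2 = Z2, Z3 = Z3,
                 stages = stages, consulted_channels = consulted,
                 config = cfg),
            class = "selection_result")
}
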