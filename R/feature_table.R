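# Feature tables: epochs x 63 features with subject/group/channel/trial
# annotations, and pooled per-(feature, channel) z-score standardization.

#' Build a feature table from an epoch set
#'
#' Computes the 63-value feature vector for every epoch and assembles a
#' data frame with one row per epoch.
#'
#' @param es An `epoch_set` (typically amplitude-normalized).
#' @param fs Sampling rate (Hz).
#' @param ... Passed to [compute_feature_vector()].
#' @return A data frame of class `feature_table` with key columns
#'   `subject`, `group`, `trial`, `channel`, `cycle` followed by the 63
#'   feature columns in registry order.
#' @export
build_feature_table <- function(es, fs = 1000, ...) {
  epochs <- if (inherits(es, "epoch_set")) es$epochs else es
  if (length(epochs) == 0) {
    reg <- feature_registry()
    tab <- cbind(
      data.frame(subject = character(0), group = character(0),
                 trial = character(0), channel = character(0),
                 cycle = integer(0), stringsAsFactors = FALSE),
      as.data.frame(matrix(numeric(0), 0, nrow(reg),
                           dimnames = list(NULL, reg$name))))
    class(tab) <- c("feature_table", class(tab))
    return(tab)
  }
  feats <- t(vapply(epochs, function(e)
    as.numeric(compute_feature_vector(e$samples, fs = fs, ...)),
    numeric(nrow(feature_registry()))))
  colnames(feats) <- feature_registry()$name
  keys <- do.call(rbind, lapply(epochs, function(e)
    data.frame(subject = e$subject, group = e$group, trial = e$trial,
               channel = e$channel, cycle = e$cycle,
               stringsAsFactors = FALSE)))
  tab <- cbind(keys, as.data.frame(feats))
  rownames(tab) <- NULL
  class(tab) <- c("feature_table", class(tab))
  attr(tab, "standardized") <- FALSE
  tab
}

#' Feature column names of a feature table
#' @param table A `feature_table`.
#' @return Character vector of the 63 feature column names.
#' @export
feature_columns <- function(table) {
  intersect(feature_registry()$name, names(table))
}

#' Standardize a feature table per feature and channel
#'
#' Z-scores every (feature, channel) column pooled across both groups and
#' all subjects. Zero-variance cells are centred only and flagged. The
#' location/scale parameters are stored so the transform is invertible and
#' idempotent (re-standardizing uses the stored parameters and leaves the
#' table unchanged).
#'
#' @param table A `feature_table`.
#' @return The standardized table with attributes `standardized`,
#'   `std_params` (per channel: center and scale vectors) and
#'   `zero_variance` (flagged cells).
#' @export
standardize_table <- function(table) {
  if (isTRUE(attr(table, "standardized"))) return(table)
  fcols <- feature_columns(table)
  channels <- unique(table$channel)
  params <- list()
  zv <- character(0)
  for (ch in channels) {
    idx <- table$channel == ch
    if (sum(idx) < 2)
      stop(sprintf("channel %s has < 2 epochs: cannot standardize", ch),
           call. = FALSE)
    ctr <- scl <- stats::setNames(numeric(length(fcols)), fcols)
    for (fc in fcols) {
      v <- table[idx, fc]
      mu <- mean(v, na.rm = TRUE)
      s <- stats::sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        zv <- c(zv, paste(fc, ch, sep = "|"))
        s <- 1  # centre only
      }
      ctr[fc] <- mu; scl[fc] <- s
      table[idx, fc] <- (v - mu) / s
    }
    params[[ch]] <- list(center = ctr, scale = scl)
  }
  attr(table, "standardized") <- TRUE
  attr(table, "std_params") <- params
  attr(table, "zero_variance") <- zv
  table
}

#' Invert the standardization of a feature table
#'
#' @param table A standardized `feature_table`.
#' @return The table on the original feature scale.
#' @export
unstandardize_table <- function(table) {
  if (!isTRUE(attr(table, "standardized")))
    stop("table is not standardized", call. = FALSE)
  params <- attr(table, "std_params")
  fcols <- feature_columns(table)
  for (ch in names(params)) {
    idx <- table$channel == ch
    for (fc in fcols)
      table[idx, fc] <- table[idx, fc] * params[[ch]]$scale[fc] +
        params[[ch]]$center[fc]
  }
  attr(table, "standardized") <- FALSE
  attr(table, "std_params") <- NULL
  table
}
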