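# File formats: recordings as delimited text (header row C1..C8, one row
# per sample) with a JSON sidecar carrying ground truth and profile
# metadata; epochs/intervals/selection results as JSON; feature tables and
# matrices as TSV. No binary formats.

#' Write a recording (and optional ground truth) to disk
#'
#' @param trial A `list(recording, truth)` as returned by
#'   [generate_trial()], or a bare `semg_recording`.
#' @param path Output path of the signal file (tab-separated text). The
#'   JSON sidecar is written next to it with extension `.json`.
#' @return Invisibly, the signal path.
#' @export
write_recording <- function(trial, path) {
  rec <- if (inherits(trial, "semg_recording")) trial else trial$recording
  truth <- if (inherits(trial, "semg_recording")) NULL else trial$truth
  utils::write.table(
    as.data.frame(rec$samples), path, sep = "\t",
    row.names = FALSE, quote = FALSE)
  meta <- list(fs = rec$fs, channel_names = rec$channel_names,
               subject_id = rec$subject_id, group = rec$group,
               trial_id = rec$trial_id)
  if (!is.null(truth))
    meta$truth <- list(
      intervals = lapply(truth$intervals, function(iv)
        as.data.frame(iv)),
      arm = truth$arm, n_cycles = truth$n_cycles,
      sub_threshold = truth$sub_threshold)
  jsonlite::write_json(meta, sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' Also accepts any delimited-text file with one named column per channel;
#' channel order must follow the C1..C8 montage convention.
#'
#' @param path Signal file path.
#' @return A `list(recording, truth)`; `truth` is `NULL` when the sidecar
#'   is absent or carries no ground truth.
#' @export
read_recording <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  samples <- as.matrix(tab)
  if (any(!is.finite(samples)))
    stop(sprintf("non-finite values in '%s'", path), call. = FALSE)
  side <- sub("\\.[^.]+$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  rec <- new_recording(samples,
                       fs = meta$fs %||% 1000,
                       subject_id = meta$subject_id %||% "S01",
                       group = meta$group %||% "amateur",
                       trial_id = meta$trial_id %||% "T1")
  truth <- NULL
  if (!is.null(meta$truth)) {
    iv <- lapply(meta$truth$intervals, function(d) {
      m <- as.matrix(as.data.frame(d))
      storage.mode(m) <- "integer"
      colnames(m) <- c("start", "end")
      m
    })
    truth <- structure(
      list(intervals = iv, arm = meta$truth$arm,
           n_cycles = meta$truth$n_cycles,
           sub_threshold = isTRUE(meta$truth$sub_threshold)),
      class = "trial_truth")
  }
  list(recording = rec, truth = truth)
}

#' Write detected epochs as JSON records plus delimited sample files
#'
#' @param det Output of [detect_trial()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the JSON index path.
#' @export
write_epochs <- function(det, dir, prefix = "epochs") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- lapply(seq_along(det$epochs), function(i) {
    e <- det$epochs[[i]]
    list(id = i, subject = e$subject, trial = e$trial, channel = e$channel,
         cycle = e$cycle, start_sample = e$start, end_sample = e$end)
  })
  idx_path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(recs, idx_path, auto_unbox = TRUE, digits = NA)
  samp <- lapply(det$epochs, function(e) e$samples)
  n_max <- max(c(0, lengths(samp)))
  if (n_max > 0) {
    m <- vapply(samp, function(s) c(s, rep(NA_real_, n_max - length(s))),
                numeric(n_max))
    colnames(m) <- paste0("e", seq_along(samp))
    utils::write.table(m, file.path(dir, paste0(prefix, "_samples.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(idx_path)
}

#' Write a feature table as TSV
#' @param table A `feature_table`.
#' @param path Output path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a selection result as JSON
#' @param sel A `selection_result`.
#' @param path Output path.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(
    list(method = sel$method, Z1 = sel$Z1, Z2 = sel$Z2, Z3 = sel$Z3,
         stages = sel$stages, consulted_channels = sel$consulted_channels,
         config = sel$config),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
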