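# Pipeline orchestration: one configuration object drives simulate ->
# preprocess -> detect -> features -> select -> evaluate, with per-stage
# artifacts and counts. All randomness flows from the single root seed
# through named sub-streams, so stages are independently reproducible.

#' Full pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one serializable
#' list: simulation design and class effects, filter band, detection
#' parameters, feature-bank options, selection thresholds, and
#' cross-validation settings.
#'
#' @param seed Root integer seed.
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    fs = 1000,
    cohort = list(n_amateur = 5L, n_professional = 5L, n_trials = 5L,
                  n_cycles = 6L,
                  class_effects = list(amplitude_ratio = 1.5,
                                       median_freq_shift_hz = 15,
                                       duration_ratio = 1),
                  base = list(amplitude_scale = 20, median_freq_hz = 80,
                              burst_duration_s = 1.8,
                              amplitude_jitter_cv = 0.05)),
    filter = list(low = 20, high = 250, order = 4L, span = 5L),
    sampen = unclass(sampen_params()),
    features = list(ar_order = 4L, wp_level = 3L,
                    thresholds = feature_thresholds()),
    selection = list(icc_threshold = 0.8, k_min = 0L, target_size = 12L,
                     excluded_channels_B = "C6"),  # k_min 0 = auto
    cv = list(folds = 10L, repeats = 20L,
              models = c("LDA", "SVM2", "SVMcore", "Subspace")),
    eval_channels = "C1")
  overrides <- list(...)
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (lossless JSON round trip)
#' @param cfg A `pipeline_config`.
#' @param path File path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$cv$models <- as.character(cfg$cv$models)
  structure(utils::modifyList(unclass(pipeline_config()), cfg),
            class = "pipeline_config")
}

#' Checksum of a configuration (embedded in output artifacts)
#' @param cfg A `pipeline_config`.
#' @return Hex string (FNV-1a over the canonical JSON serialization).
#' @export
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                         null = "null")
  bytes <- utf8ToInt(as.character(js))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' The 12-feature reporting group
#'
#' The compact default feature group used for reporting: nine time-domain
#' features (ASM, AR4, AAC, DAMV, LTKEO, SSI, SD, WL, DUR) and three
#' frequency-domain features (PKF, SM0, and the wavelet-packet node energy
#' WP5, i.e. node (3,4)).
#'
#' @return Character vector of 12 feature names.
#' @export
f12b_features <- function() {
  c("ASM", "AR4", "AAC", "DAMV", "LTKEO", "SSI", "SD", "WL", "DUR",
    "PKF", "SM0", "WP5")
}

#' Simulate a cohort and write it to disk
#'
#' Writes one delimited-text recording per trial plus JSON ground-truth
#' sidecars, and a manifest listing every file with the configuration
#' hash.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Writable output directory.
#' @return Invisibly, the manifest path.
#' @export
simulate_cohort_files <- function(cfg = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    stop(sprintf("output directory '%s' is not writable", out_dir),
         call. = FALSE)
  co <- generate_cohort(
    n_amateur = cfg$cohort$n_amateur,
    n_professional = cfg$cohort$n_professional,
    class_effects = cfg$cohort$class_effects,
    n_trials = cfg$cohort$n_trials, n_cycles = cfg$cohort$n_cycles,
    fs = cfg$fs, seed = derive_seed(cfg$seed, "simulate"),
    base = cfg$cohort$base)
  files <- character(0)
  for (tr in co$trials) {
    rec <- tr$recording
    f <- file.path(out_dir, sprintf("%s_%s.tsv", rec$subject_id, rec$trial_id))
    write_recording(tr, f)
    files <- c(files, f)
  }
  manifest <- list(config_hash = config_hash(cfg), files = basename(files),
                   profiles = co$profiles, jitter = co$jitter)
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> detect -> features -> select -> evaluate on a
#' cohort, either generated in memory from the configuration or loaded
#' from a directory written by [simulate_cohort_files()]. Per-stage counts
#' (epochs detected, candidates rejected, features removed per stage) are
#' collected in the result's `log`.
#'
#' @param cfg A [pipeline_config()].
#' @param input_dir Optional directory with a `manifest.json`; when
#'   `NULL` the cohort is generated in memory.
#' @param out_dir Optional directory for per-stage artifacts (TSV/JSON).
#' @param select Run the staged feature-reduction stage (default `TRUE`;
#'   requires a cohort large enough to support the stage criteria).
#' @param evaluate Run the cross-validation stage (default `TRUE`). When
#'   selection is disabled the compact default group of [f12b_features()]
#'   is evaluated instead of the data-driven stage-3 sets.
#' @param verbose Emit per-stage progress via `message()`.
#' @return List of class `pipeline_result`: `epoch_counts` (per channel),
#'   `table` (standardized feature table), `selection` (Methods A and B),
#'   `cv` (per feature group and model), `report`, `log`, `config_hash`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), input_dir = NULL,
                         out_dir = NULL, select = TRUE, evaluate = TRUE,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- config_hash(cfg)

  if (is.null(input_dir)) {
    say("simulating cohort (seed %d)", cfg$seed)
    co <- generate_cohort(
      n_amateur = cfg$cohort$n_amateur,
      n_professional = cfg$cohort$n_professional,
      class_effects = cfg$cohort$class_effects,
      n_trials = cfg$cohort$n_trials, n_cycles = cfg$cohort$n_cycles,
      fs = cfg$fs, seed = derive_seed(cfg$seed, "simulate"),
      base = cfg$cohort$base)
    trials <- co$trials
  } else {
    manifest <- jsonlite::read_json(file.path(input_dir, "manifest.json"),
                                    simplifyVector = TRUE)
    trials <- lapply(file.path(input_dir, manifest$files), read_recording)
  }

  params <- do.call(sampen_params, cfg$sampen[setdiff(names(cfg$sampen), NULL)])
  all_epochs <- list()
  n_candidates <- 0L
  n_accepted <- 0L
  for (tr in trials) {
    prep <- preprocess_recording(tr$recording, low = cfg$filter$low,
                                 high = cfg$filter$high,
                                 order = cfg$filter$order,
                                 span = cfg$filter$span)
    det <- detect_trial(prep, params)
    for (arm in names(det$intervals)) {
      n_accepted <- n_accepted + nrow(det$intervals[[arm]])
      n_candidates <- n_candidates +
        nrow(attr(det$intervals[[arm]], "candidates"))
    }
    all_epochs <- c(all_epochs, det$epochs)
  }
  say("detection: %d accepted / %d candidate intervals",
      n_accepted, n_candidates)

  if (length(all_epochs) == 0) {
    warning("no epochs detected: feature table is empty")
    tab <- build_feature_table(new_epoch_set())
    return(structure(list(
      epoch_counts = integer(0), table = tab, selection = NULL, cv = NULL,
      report = NULL, config_hash = hash,
      log = list(candidates = n_candidates, accepted = n_accepted,
                 rejected = n_candidates - n_accepted)),
      class = "pipeline_result"))
  }

  es <- normalize_epochs(new_epoch_set(all_epochs))
  tab <- build_feature_table(es, fs = cfg$fs,
                             ar_order = cfg$features$ar_order,
                             wp_level = cfg$features$wp_level,
                             thresholds = cfg$features$thresholds)
  tab <- standardize_table(tab)
  epoch_counts <- table(tab$channel)
  say("features: %d epochs x %d features", nrow(tab),
      length(feature_columns(tab)))

  icc <- NULL
  tests <- NULL
  sel <- NULL
  if (select) {
  kmin <- if (is.null(cfg$selection$k_min) || cfg$selection$k_min == 0) NULL
          else cfg$selection$k_min
  icc <- icc_matrix(tab)
  tests <- ttest_matrix(tab)
  sel <- list(
    A = reduce_features("A", tests, icc,
                        config = list(icc_threshold = cfg$selection$icc_threshold,
                                      k_min = kmin,
                                      target_size = cfg$selection$target_size)),
    B = reduce_features("B", tests, icc,
                        config = list(icc_threshold = cfg$selection$icc_threshold,
                                      k_min = kmin,
                                      target_size = cfg$selection$target_size,
                                      excluded_channels = cfg$selection$excluded_channels_B)))
  say("selection: A stages %s | B stages %s",
      paste(names(sel$A$stages), collapse = " "),
      paste(names(sel$B$stages), collapse = " "))
  }

  cv <- NULL
  report <- NULL
  if (evaluate) {
    groups <- if (is.null(sel)) list(F12B = f12b_features()) else
      list(F63 = feature_registry()$name,
           F12A = sel$A$stages[[3]],
           F12B = sel$B$stages[[3]])
    cv <- list()
    for (grp in names(groups)) {
      cv[[grp]] <- list()
      for (mdl in cfg$cv$models) {
        per_ch <- list()
        for (ch in cfg$eval_channels) {
          sub <- tab[tab$channel == ch, , drop = FALSE]
          per_ch[[ch]] <- crossval(
            sub[, groups[[grp]], drop = FALSE], sub$group,
            cv_config(folds = cfg$cv$folds, repeats = cfg$cv$repeats,
                      model = mdl,
                      shuffle_seed = derive_seed(cfg$seed, "shuffle", grp, mdl, ch)))
        }
        cv[[grp]][[mdl]] <- if (length(per_ch) == 1L) per_ch[[1]] else per_ch
      }
    }
    report <- evaluation_report(cv)
  }

  res <- structure(list(
    epoch_counts = epoch_counts, table = tab,
    icc = icc, tests = tests, selection = sel, cv = cv, report = report,
    config_hash = hash,
    log = list(candidates = n_candidates, accepted = n_accepted,
               rejected = n_candidates - n_accepted)),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(tab, file.path(out_dir, "feature_table.tsv"))
    if (!is.null(sel)) {
      utils::write.table(unclass(icc), file.path(out_dir, "icc_matrix.tsv"),
                         sep = "\t", quote = FALSE)
      utils::write.table(tests$p, file.path(out_dir, "ttest_p.tsv"),
                         sep = "\t", quote = FALSE)
      write_selection(sel$A, file.path(out_dir, "selection_A.json"))
      write_selection(sel$B, file.path(out_dir, "selection_B.json"))
    }
    if (!is.null(report))
      jsonlite::write_json(
        list(config_hash = hash, summary = report$summary),
        file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
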