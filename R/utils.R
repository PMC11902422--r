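# Internal helpers shared across the pipeline.

#' Run code with a temporary RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's
#' `.Random.seed` afterwards, so seeded generators do not perturb the
#' session RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: all randomness flows from one root seed
# through named sub-streams. Kept strictly below 2^31 - 1.
derive_seed <- function(root, ...) {
  parts <- c(...)
  s <- as.double(root) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p))
    s <- (s * 69069 + as.double(p) + 1) %% 2147483647
  }
  as.integer(s)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  if (integerish && x != round(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(x)
}

#' Channel layout of the standard 8-channel curl montage
#'
#' Channels C1, C2, C5, C6 record the left arm (biceps, triceps,
#' brachioradialis, flexor carpi); C3, C4, C8, C7 the right arm in the same
#' muscle order. Event detection runs on the biceps channels (C1 left,
#' C3 right) and its intervals are propagated to the other channels of the
#' same arm.
#'
#' @return A list with `channels`, `left`, `right`, and the biceps
#'   detection channel of each arm.
#' @export
channel_layout <- function() {
  list(
    channels = paste0("C", 1:8),
    left = c("C1", "C2", "C5", "C6"),
    right = c("C3", "C4", "C7", "C8"),
    detect = c(left = "C1", right = "C3")
  )
}
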