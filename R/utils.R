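# Internal helpers shared across modules.

# Scoped seeding: functions that accept `seed = NULL` leave the caller's RNG
# stream untouched when no seed is given, and restore it afterwards otherwise.
local_seed <- function(seed, .local_envir = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = .local_envir)
  invisible(seed)
}

#' Derive a stage seed from a root seed
#'
#' Deterministic fan-out of one root seed into named substreams (one per
#' pipeline stage), so that adding a stage never perturbs the randomness of
#' earlier stages. Results stay below 2^31. `NULL` passes through, meaning
#' "unseeded".
#'
#' @param seed Root integer seed or `NULL`.
#' @param stage Substream name, one of `"behavior"`, `"running"`,
#'   `"population"`, `"subsample"`, `"shuffle"`, `"decoding"`,
#'   `"disruption"`, `"bootstrap"`, `"cohort_a"`, `"cohort_b"`, `"folds"`,
#'   `"laser"`.
#' @param index Optional integer for repeated uses of one stage (e.g.
#'   session number).
#' @return An integer seed, or `NULL` if `seed` is `NULL`.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  if (is.null(seed)) return(NULL)
  stages <- c(
    behavior = 1L, running = 2L, population = 3L, subsample = 4L,
    shuffle = 5L, decoding = 6L, disruption = 7L, bootstrap = 8L,
    cohort_a = 9L, cohort_b = 10L, folds = 11L, laser = 12L
  )
  if (!stage %in% names(stages)) stop("unknown seed substream: ", stage)
  as.integer((as.numeric(seed) * 48271 + stages[[stage]] * 9973 +
                as.numeric(index) * 7919) %% 2147483647)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("`", name, "` must be a single probability in [0, 1]", call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) &&
    (if (positive) x > 0 else x >= 0)
  if (!ok)
    stop("`", name, "` must be a ", if (positive) "positive" else "nonnegative",
         " integer", call. = FALSE)
  invisible(as.integer(x))
}

other_rule <- function(rule) if (rule == "A") "B" else "A"

opposite_side <- function(side) ifelse(side == "left", "right", "left")

# Rule A: horizontal -> left, vertical -> right; Rule B reverses the mapping.
side_for_cue <- function(cue, rule) {
  a_side <- ifelse(cue == "horizontal", "left", "right")
  ifelse(rule == "A", a_side, opposite_side(a_side))
}

cue_for_side <- function(side, rule) {
  ifelse(side_for_cue("horizontal", rule) == side, "horizontal", "vertical")
}

# Normalize a two-class label vector to logical (TRUE = positive class).
as_binary_labels <- function(labels) {
  if (is.logical(labels)) {
    lv <- c("FALSE", "TRUE")
    out <- labels
  } else {
    f <- as.factor(labels)
    lv <- levels(droplevels(f))
    if (length(lv) != 2L)
      stop("labels must contain exactly two classes, got ",
           length(lv), call. = FALSE)
    out <- droplevels(f) == lv[2L]
  }
  if (any(is.na(out))) stop("labels must not contain NA", call. = FALSE)
  if (all(out) || !any(out))
    stop("labels must contain both classes", call. = FALSE)
  attr(out, "levels") <- lv
  out
}

# Stratified k-fold assignment; returns integer fold id per observation.
# Uses the current RNG stream.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}
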