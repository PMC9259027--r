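# Session CSV dialect and the plain-text activity bundle.

session_columns <- c("session_id", "mouse_id", "trial_index", "cue", "rule",
                     "correct_side", "choice", "correct", "guided",
                     "laser_target", "forced_by_bias_correction")

#' Write / read a behavioral session as CSV
#'
#' One row per trial with columns `session_id`, `mouse_id`, `trial_index`,
#' `cue`, `rule`, `correct_side`, `choice`, `correct`, `guided`,
#' `laser_target`, `forced_by_bias_correction`. Reading validates the
#' schema and enum values, reporting offending row numbers.
#'
#' @param session A `session_behavior` data frame.
#' @param path File path.
#' @return `read_session_csv` returns a `session_behavior` data frame;
#'   `write_session_csv` returns `path` invisibly.
#' @export
write_session_csv <- function(session, path) {
  session <- as.data.frame(session)
  stopifnot(all(session_columns %in% names(session)))
  write.csv(session[, session_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(session_columns, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  check_enum <- function(col, allowed) {
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad))
      stop("invalid ", col, " value '", df[[col]][bad[1]], "' at row ", bad[1],
           call. = FALSE)
  }
  check_enum("cue", c("horizontal", "vertical"))
  check_enum("rule", c("A", "B"))
  check_enum("correct_side", c("left", "right"))
  check_enum("choice", c("left", "right"))
  check_enum("laser_target", c("none", "control", "S1", "RSC", "PPC"))
  for (col in c("correct", "guided", "forced_by_bias_correction")) {
    df[[col]] <- as.logical(df[[col]])
    if (any(is.na(df[[col]])))
      stop("NA in required column '", col, "' at row ",
           which(is.na(df[[col]]))[1], call. = FALSE)
  }
  if (any(is.na(df$trial_index)))
    stop("NA trial_index at row ", which(is.na(df$trial_index))[1], call. = FALSE)
  class(df) <- c("session_behavior", "data.frame")
  df
}

fmt_num <- function(x) sprintf("%.17g", x)  # lossless double round-trip

#' Write / read an activity bundle
#'
#' A session's binned activity (plus optional running trace and generator
#' ground truth) as a plain-text directory: `activity.csv` (long format:
#' neuron, trial, bin, value), `neurons.csv`, `bin_edges.csv`,
#' `trial_meta.csv`, optional `running.csv` and `truth.csv`, and
#' `meta.json` with array dimensions and an echo of the generator
#' configuration. Doubles are written with 17 significant digits so the
#' round-trip is lossless. Reading validates the trials-axis agreement
#' between the activity array and the trial metadata.
#'
#' @param activity A [binned_activity()].
#' @param path Directory to create/fill.
#' @param running Optional `running_trace`.
#' @param truth Optional ground-truth data frame.
#' @param config Optional configuration list echoed into `meta.json`.
#' @return `read_activity_bundle` returns a list with `activity` and (when
#'   present) `running`, `truth`, `config`; the writer returns `path`
#'   invisibly.
#' @export
write_activity_bundle <- function(activity, path, running = NULL,
                                  truth = NULL, config = NULL) {
  stopifnot(inherits(activity, "binned_activity"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(activity$activity)
  long <- data.frame(
    neuron = rep(seq_len(d[1]), times = d[2] * d[3]),
    trial = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    bin = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = fmt_num(as.vector(activity$activity))
  )
  write.csv(long, file.path(path, "activity.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(neuron = seq_len(d[1]), area = activity$area),
            file.path(path, "neurons.csv"), row.names = FALSE)
  write.csv(data.frame(edge_cm = fmt_num(activity$bin_edges)),
            file.path(path, "bin_edges.csv"), row.names = FALSE, quote = FALSE)
  write.csv(activity$trial_meta, file.path(path, "trial_meta.csv"),
            row.names = FALSE)
  if (!is.null(running)) {
    nbr <- ncol(running$lateral)
    run_long <- data.frame(
      trial = rep(seq_len(nrow(running$lateral)), times = nbr),
      bin = rep(seq_len(nbr), each = nrow(running$lateral)),
      pitch = fmt_num(as.vector(running$pitch)),
      roll = fmt_num(as.vector(running$roll)),
      yaw = fmt_num(as.vector(running$yaw)),
      lateral = fmt_num(as.vector(running$lateral))
    )
    write.csv(run_long, file.path(path, "running.csv"), row.names = FALSE,
              quote = FALSE)
  }
  if (!is.null(truth)) {
    tr <- truth
    attr(tr, "expected_noise_correlation") <- NULL
    write.csv(tr, file.path(path, "truth.csv"), row.names = FALSE)
  }
  meta <- list(
    n_neurons = d[1], n_trials = d[2], n_bins = d[3],
    expected_noise_correlation =
      if (!is.null(truth)) attr(truth, "expected_noise_correlation") else NULL,
    config = config
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_activity_bundle
#' @export
read_activity_bundle <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  long <- read.csv(file.path(path, "activity.csv"))
  neurons <- read.csv(file.path(path, "neurons.csv"), stringsAsFactors = FALSE)
  edges <- read.csv(file.path(path, "bin_edges.csv"))$edge_cm
  trial_meta <- read.csv(file.path(path, "trial_meta.csv"),
                         stringsAsFactors = FALSE)
  d <- c(meta$n_neurons, meta$n_trials, meta$n_bins)
  if (nrow(long) != prod(d))
    stop("activity.csv has ", nrow(long), " rows; expected ", prod(d), call. = FALSE)
  if (nrow(trial_meta) != d[2])
    stop("trials axis mismatch: meta.json declares ", d[2],
         " trials but trial_meta.csv has ", nrow(trial_meta), " rows", call. = FALSE)
  ord <- order(long$bin, long$trial, long$neuron)
  act <- array(long$value[ord], dim = d)
  out <- list(activity = binned_activity(act, neurons$area, edges, trial_meta))
  run_path <- file.path(path, "running.csv")
  if (file.exists(run_path)) {
    rl <- read.csv(run_path)
    nbr <- max(rl$bin)
    ntr <- max(rl$trial)
    ordr <- order(rl$bin, rl$trial)
    out$running <- structure(
      list(pitch = matrix(rl$pitch[ordr], ntr, nbr),
           roll = matrix(rl$roll[ordr], ntr, nbr),
           yaw = matrix(rl$yaw[ordr], ntr, nbr),
           lateral = matrix(rl$lateral[ordr], ntr, nbr),
           bin_edges = edges,
           choice = if ("choice" %in% names(trial_meta)) trial_meta$choice else NULL),
      class = "running_trace")
  }
  truth_path <- file.path(path, "truth.csv")
  if (file.exists(truth_path)) {
    out$truth <- read.csv(truth_path, stringsAsFactors = FALSE)
    if (!is.null(meta$expected_noise_correlation))
      attr(out$truth, "expected_noise_correlation") <- meta$expected_noise_correlation
  }
  if (!is.null(meta$config)) out$config <- meta$config
  out
}
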