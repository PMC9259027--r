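#' Spatially binned population activity
#'
#' Container for deconvolved, spatially binned activity of one imaging
#' session: a `neurons x trials x bins` array, per-neuron area labels,
#' uniform bin edges in cm along the maze's long axis, and per-trial
#' metadata.
#'
#' @param activity Numeric array `[neurons, trials, bins]`.
#' @param area Character vector of per-neuron area labels (e.g. `"V1"`,
#'   `"PPC"`, `"RSC"`).
#' @param bin_edges Numeric vector of length `bins + 1`, strictly increasing.
#' @param trial_meta Data frame with one row per trial (typically the
#'   corresponding `session_behavior` rows).
#' @return An object of class `binned_activity`.
#' @export
binned_activity <- function(activity, area, bin_edges, trial_meta) {
  d <- dim(activity)
  if (is.null(d) || length(d) != 3L)
    stop("`activity` must be a 3-d array [neurons, trials, bins]", call. = FALSE)
  if (length(area) != d[1])
    stop("`area` length (", length(area), ") != number of neurons (", d[1], ")",
         call. = FALSE)
  if (length(bin_edges) != d[3] + 1L)
    stop("`bin_edges` must have length n_bins + 1", call. = FALSE)
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  if (!is.data.frame(trial_meta) || nrow(trial_meta) != d[2])
    stop("trials axis mismatch: activity has ", d[2], " trials but trial_meta has ",
         if (is.data.frame(trial_meta)) nrow(trial_meta) else "no", " rows",
         call. = FALSE)
  structure(
    list(activity = activity, area = as.character(area),
         bin_edges = as.numeric(bin_edges), trial_meta = trial_meta),
    class = "binned_activity"
  )
}

#' @export
print.binned_activity <- function(x, ...) {
  d <- dim(x$activity)
  cat("<binned_activity> ", d[1], " neurons x ", d[2], " trials x ", d[3],
      " bins\n", sep = "")
  cat("  areas: ", paste(sprintf("%s (%d)", names(table(x$area)),
                                 table(x$area)), collapse = ", "), "\n", sep = "")
  cat("  maze extent: [", min(x$bin_edges), ", ", max(x$bin_edges), ") cm\n",
      sep = "")
  invisible(x)
}

#' Dimensions and bin centers of a binned-activity object
#' @param x A `binned_activity`.
#' @return Integer (or numeric for `bin_centers`) vector.
#' @export
n_neurons <- function(x) dim(x$activity)[1]

#' @rdname n_neurons
#' @export
n_trials <- function(x) dim(x$activity)[2]

#' @rdname n_neurons
#' @export
n_bins <- function(x) dim(x$activity)[3]

#' @rdname n_neurons
#' @export
bin_centers <- function(x) {
  e <- x$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Subset a binned-activity object
#'
#' @param x A `binned_activity`.
#' @param neurons Integer indices or an area label.
#' @param trials Integer trial indices (1-based positions).
#' @return A `binned_activity` restricted to the requested neurons/trials.
#' @export
subset_activity <- function(x, neurons = NULL, trials = NULL) {
  stopifnot(inherits(x, "binned_activity"))
  if (is.character(neurons)) neurons <- which(x$area %in% neurons)
  if (is.null(neurons)) neurons <- seq_len(n_neurons(x))
  if (is.null(trials)) trials <- seq_len(n_trials(x))
  binned_activity(x$activity[neurons, trials, , drop = FALSE],
                  x$area[neurons], x$bin_edges,
                  x$trial_meta[trials, , drop = FALSE])
}

#' Trial-type labels from trial metadata
#'
#' A trial type is one cue-choice combination: two types per rule among
#' correct trials, four across both rules. Returns a factor built from the
#' interaction of `cue` and `choice`.
#'
#' @param trial_meta Data frame with `cue` and `choice` columns, or a
#'   `binned_activity`.
#' @return Factor of trial types, one per trial.
#' @export
trial_types <- function(trial_meta) {
  if (inherits(trial_meta, "binned_activity")) trial_meta <- trial_meta$trial_meta
  droplevels(interaction(trial_meta$cue, trial_meta$choice, drop = TRUE))
}
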