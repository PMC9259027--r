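# Fluorescence normalization, spatial binning, and the trial-selection
# rules applied before every neural analysis.

# Sliding-window percentile with a centered window truncated at the edges.
# Linear-interpolation percentile (stats::quantile type 7). O(n * w log w);
# adequate at the trace lengths this package handles.
running_percentile <- function(x, window, p) {
  n <- length(x)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    quantile(x[lo:hi], p / 100, names = FALSE, type = 7)
  }, numeric(1))
}

#' Neuropil-corrected dF/F
#'
#' Normalized fluorescence change computed as
#' `dff = (F_corr - baseline(F_corr)) / baseline(F)`, where
#' `F_corr = F - neuropil_coeff * F_neuropil` and `baseline(x)` is the
#' running 8th percentile of `x` within a centered sliding window of
#' `baseline_window_s` seconds (truncated at the trace edges). The
#' denominator uses the baseline of the raw (uncorrected) fluorescence.
#'
#' @param f Raw somatic fluorescence vector, or a `neurons x frames` matrix.
#' @param f_neuropil Neuropil fluorescence, same shape as `f`.
#' @param fs Sampling rate in Hz.
#' @param neuropil_coeff Neuropil subtraction coefficient (default 0.7).
#' @param baseline_percentile Percentile used for the baseline (default 8).
#' @param baseline_window_s Baseline window length in seconds (default 60).
#' @return dF/F with the same shape as `f`.
#' @export
compute_dff <- function(f, f_neuropil, fs,
                        neuropil_coeff = 0.7,
                        baseline_percentile = 8,
                        baseline_window_s = 60) {
  if (is.matrix(f)) {
    stopifnot(is.matrix(f_neuropil), all(dim(f) == dim(f_neuropil)))
    out <- t(vapply(seq_len(nrow(f)), function(i)
      compute_dff(f[i, ], f_neuropil[i, ], fs, neuropil_coeff,
                  baseline_percentile, baseline_window_s),
      numeric(ncol(f))))
    dimnames(out) <- dimnames(f)
    return(out)
  }
  if (length(f) != length(f_neuropil))
    stop("`f` and `f_neuropil` must have equal length", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  w <- max(1L, round(fs * baseline_window_s))
  if (length(f) <= w)
    stop("trace shorter than the baseline window (", w, " samples)", call. = FALSE)
  f_corr <- f - neuropil_coeff * f_neuropil
  base_corr <- running_percentile(f_corr, w, baseline_percentile)
  base_raw <- running_percentile(f, w, baseline_percentile)
  if (any(base_raw <= 0))
    stop("nonpositive raw baseline at ", sum(base_raw <= 0),
         " frames; dF/F undefined (check raw fluorescence offset)", call. = FALSE)
  (f_corr - base_corr) / base_raw
}

#' Spatially bin frame-wise activity along the maze's long axis
#'
#' Sums activity (deconvolved events) over the frames of each trial whose
#' maze position falls in each half-open bin `[lo, hi)`. Frames outside the
#' maze extent are dropped (with a message reporting the count). With
#' `normalize = "occupancy"` sums are divided by the frame count per bin.
#'
#' @param activity_ts Numeric vector (one neuron) or `neurons x frames`
#'   matrix of frame-wise activity.
#' @param position Position in cm along the long axis, one value per frame.
#' @param trial_id Trial identifier per frame; trials are ordered by first
#'   appearance.
#' @param maze_length Maze extent in cm.
#' @param bin_size Bin width in cm (default 5).
#' @param normalize `"sum"` (default) or `"occupancy"`.
#' @param area Optional per-neuron area labels.
#' @param trial_meta Optional per-trial metadata data frame.
#' @return A [binned_activity()] (`trial_meta` defaults to a data frame with
#'   the trial ids).
#' @export
bin_by_position <- function(activity_ts, position, trial_id,
                            maze_length = 230, bin_size = 5,
                            normalize = c("sum", "occupancy"),
                            area = NULL, trial_meta = NULL) {
  normalize <- match.arg(normalize)
  if (is.vector(activity_ts)) activity_ts <- matrix(activity_ts, nrow = 1L)
  n_frames <- ncol(activity_ts)
  stopifnot(length(position) == n_frames, length(trial_id) == n_frames)

  edges <- seq(0, maze_length, by = bin_size)
  nb <- length(edges) - 1L
  bin <- findInterval(position, edges, rightmost.closed = FALSE)
  in_maze <- bin >= 1L & bin <= nb & position < edges[nb + 1L]
  n_dropped <- sum(!in_maze)
  if (n_dropped > 0L)
    message("bin_by_position: dropped ", n_dropped, " frames outside [0, ",
            maze_length, ") cm")

  trials <- unique(trial_id)
  nt <- length(trials)
  nn <- nrow(activity_ts)
  act <- array(0, dim = c(nn, nt, nb))
  occ <- matrix(0, nt, nb)
  for (ti in seq_len(nt)) {
    sel <- trial_id == trials[ti] & in_maze
    if (!any(sel)) {
      warning("trial '", trials[ti], "' has no in-maze frames; all-zero row")
      next
    }
    b <- bin[sel]
    occ[ti, ] <- tabulate(b, nbins = nb)
    for (bb in unique(b)) {
      fr <- which(sel)[b == bb]
      act[, ti, bb] <- rowSums(activity_ts[, fr, drop = FALSE])
    }
  }
  if (normalize == "occupancy") {
    for (ti in seq_len(nt)) {
      nzero <- occ[ti, ] > 0
      act[, ti, nzero] <- sweep(act[, ti, nzero, drop = FALSE], 3,
                                occ[ti, nzero], "/")
    }
  }
  if (is.null(area)) area <- rep("unknown", nn)
  if (is.null(trial_meta)) trial_meta <- data.frame(trial = trials)
  binned_activity(act, area, edges, trial_meta)
}

#' Select correct trials from high-performance periods
#'
#' Returns the (1-based) indices of correct trials lying in a
#' high-performance period: at least `threshold` fraction correct within a
#' window of `window` trials, which excludes periods after rule switches.
#' Window anchoring is configurable: with `"any"` (default) a trial
#' qualifies if any length-`window` window containing it meets the
#' threshold; `"trailing"` uses the window ending at the trial; `"centered"`
#' the window centered on it. Windows are truncated at session edges.
#'
#' @param session A `session_behavior` data frame or logical `correct`
#'   vector.
#' @param window Window length in trials (default 10).
#' @param threshold Minimum fraction correct in the window (default 0.8).
#' @param anchor Window placement: `"any"`, `"trailing"`, or `"centered"`.
#' @return Sorted integer vector of qualifying correct-trial indices
#'   (1-based row positions).
#' @export
select_high_performance_trials <- function(session, window = 10L,
                                           threshold = 0.8,
                                           anchor = c("any", "trailing", "centered")) {
  anchor <- match.arg(anchor)
  window <- assert_count(window, "window")
  assert_probability(threshold, "threshold")
  correct <- if (is.data.frame(session)) session$correct else session
  stopifnot(is.logical(correct))
  n <- length(correct)
  if (n < window)
    stop("session shorter (", n, " trials) than the window (", window, ")",
         call. = FALSE)

  win_mean <- function(lo, hi) mean(correct[max(1L, lo):min(n, hi)])
  qualifies <- switch(anchor,
    any = {
      # window starting at s covers s .. s+window-1, truncated at both
      # session edges; s ranges so that truncated edge windows exist on
      # both sides
      starts <- (2L - window):n
      ok_start <- vapply(starts, function(s)
        win_mean(s, s + window - 1L) >= threshold, logical(1))
      vapply(seq_len(n), function(i) {
        pos <- ((i - window + 1L):i) - (2L - window) + 1L
        any(ok_start[pos])
      }, logical(1))
    },
    trailing = vapply(seq_len(n), function(i)
      win_mean(i - window + 1L, i) >= threshold, logical(1)),
    centered = {
      half <- window %/% 2L
      vapply(seq_len(n), function(i)
        win_mean(i - half, i - half + window - 1L) >= threshold, logical(1))
    }
  )
  sort(which(correct & qualifies))
}

#' Subsample trials to a fixed count per trial type
#'
#' Uniform sampling without replacement of exactly `n_per_type` trials from
#' each requested type, matching trial counts across conditions (30 per
#' type for two-type comparisons; 15 per type for the four-type variant,
#' giving 60 trials overall).
#'
#' @param types Factor or character vector of trial types, one per trial.
#' @param n_per_type Number of trials to keep per type.
#' @param keep_types Types to sample from (default: all present).
#' @param seed Integer seed; deterministic given the seed.
#' @return Sorted integer vector of selected trial indices.
#' @export
subsample_trials <- function(types, n_per_type, keep_types = NULL, seed = NULL) {
  n_per_type <- assert_count(n_per_type, "n_per_type")
  types <- as.character(types)
  if (is.null(keep_types)) keep_types <- sort(unique(types))
  local_seed(seed)
  idx <- integer(0)
  for (tp in keep_types) {
    avail <- which(types == tp)
    if (length(avail) < n_per_type)
      stop("trial type '", tp, "' has only ", length(avail),
           " trials; need ", n_per_type, call. = FALSE)
    idx <- c(idx, if (length(avail) == n_per_type) avail
             else sample(avail, n_per_type))
  }
  sort(idx)
}
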