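# Single-neuron trial-type selectivity: per-bin auROC, permutation
# significance, maze-segment summaries, four-trial-type categorization.

# Trial ranks of the activity array, reshaped to trials x (neurons * bins).
# auROC for any label assignment is then a single matrix product:
# auROC = (sum of positive-class ranks - n1 (n1 + 1) / 2) / (n1 * n0),
# the Mann-Whitney U statistic with average ranks, i.e. ties get 1/2 credit.
activity_trial_ranks <- function(activity) {
  d <- dim(activity)
  m <- matrix(aperm(activity, c(2, 1, 3)), nrow = d[2])  # trials x (neurons*bins)
  apply(m, 2L, rank)                                     # average ties
}

auroc_from_ranks <- function(rank_mat, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (colSums(rank_mat[pos, , drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-bin auROC for trial-type discrimination
#'
#' For each neuron and spatial bin, the area under the ROC curve comparing
#' activity distributions between the two trial types: the probability that
#' a randomly drawn positive-class trial has higher activity than a
#' randomly drawn negative-class trial, with ties counted 1/2
#' (Mann-Whitney convention). 0.5 means uninformative.
#'
#' @param activity A [binned_activity()] or a `neurons x trials x bins`
#'   array.
#' @param labels Two-class label vector, one per trial (logical, factor, or
#'   character; the second factor level is the positive class).
#' @return Numeric matrix `neurons x bins` of auROC values in `[0, 1]`.
#' @export
auroc_per_bin <- function(activity, labels) {
  act <- if (inherits(activity, "binned_activity")) activity$activity else activity
  d <- dim(act)
  pos <- as_binary_labels(labels)
  if (length(pos) != d[2])
    stop("labels length (", length(pos), ") != number of trials (", d[2], ")",
         call. = FALSE)
  auc <- auroc_from_ranks(activity_trial_ranks(act), pos)
  matrix(auc, nrow = d[1], ncol = d[3])
}

#' Trial-type selectivity index
#'
#' The unsigned deviation of auROC from chance: `2 * |auROC - 0.5|`, in
#' `[0, 1]`; invariant to which class is called positive.
#'
#' @param auroc auROC values in `[0, 1]` (any shape).
#' @return Selectivity values, same shape.
#' @export
selectivity_index <- function(auroc) {
  if (any(auroc < 0 | auroc > 1, na.rm = TRUE))
    stop("auROC values must lie in [0, 1]", call. = FALSE)
  2 * abs(auroc - 0.5)
}

#' Permutation significance of trial-type selectivity
#'
#' Recomputes the selectivity index `n_shuffles` times with shuffled trial
#' labels and compares the observed value to the shuffled distribution.
#' The p-value uses the add-one estimator
#' `p = (1 + #\{shuffles >= observed\}) / (1 + n_shuffles)`, so with 100
#' shuffles significance at `p < 0.01` requires the observed selectivity to
#' exceed every shuffle. By default one label permutation per shuffle is
#' applied jointly to all neurons (preserving cross-neuron structure within
#' a shuffle); `per_neuron = TRUE` draws independent permutations per
#' neuron.
#'
#' @inheritParams auroc_per_bin
#' @param n_shuffles Number of label shuffles (default 100).
#' @param alpha Significance threshold on the permutation p (default 0.01).
#' @param seed Integer seed.
#' @param per_neuron Shuffle labels independently per neuron?
#' @return A list of class `selectivity_profile`: matrices (`neurons x
#'   bins`) `auroc`, `selectivity`, `p`, `significant`, plus `alpha`,
#'   `n_shuffles`, and the `area`/`bin_edges` of the input when available.
#' @export
shuffle_significance <- function(activity, labels, n_shuffles = 100L,
                                 alpha = 0.01, seed = NULL,
                                 per_neuron = FALSE) {
  n_shuffles <- assert_count(n_shuffles, "n_shuffles")
  assert_probability(alpha, "alpha")
  act <- if (inherits(activity, "binned_activity")) activity$activity else activity
  d <- dim(act)
  pos <- as_binary_labels(labels)
  if (length(pos) != d[2]) stop("labels length != number of trials", call. = FALSE)
  local_seed(seed)

  rank_mat <- activity_trial_ranks(act)               # trials x (neurons*bins)
  obs_sel <- selectivity_index(auroc_from_ranks(rank_mat, pos))

  n1 <- sum(pos)
  nt <- d[2]
  cols_per_neuron <- d[3]
  exceed <- numeric(length(obs_sel))
  if (per_neuron) {
    for (s in seq_len(n_shuffles)) {
      for (nrn in seq_len(d[1])) {
        cols <- nrn + d[1] * (seq_len(cols_per_neuron) - 1L)
        perm_pos <- logical(nt)
        perm_pos[sample.int(nt, n1)] <- TRUE
        sel_s <- selectivity_index(
          auroc_from_ranks(rank_mat[, cols, drop = FALSE], perm_pos))
        exceed[cols] <- exceed[cols] + (sel_s >= obs_sel[cols])
      }
    }
  } else {
    # indicator matrix of shuffled positive classes: trials x n_shuffles
    S <- matrix(0, nt, n_shuffles)
    for (s in seq_len(n_shuffles)) S[sample.int(nt, n1), s] <- 1
    n0 <- nt - n1
    auc_shuf <- (crossprod(S, rank_mat) - n1 * (n1 + 1) / 2) / (n1 * n0)
    sel_shuf <- selectivity_index(auc_shuf)           # n_shuffles x (neurons*bins)
    exceed <- colSums(sel_shuf >= rep(obs_sel, each = n_shuffles))
  }
  p <- (1 + exceed) / (1 + n_shuffles)

  shape <- function(v) matrix(v, nrow = d[1], ncol = d[3])
  structure(
    list(auroc = shape(auroc_from_ranks(rank_mat, pos)),
         selectivity = shape(obs_sel),
         p = shape(p),
         significant = shape(p < alpha),
         alpha = alpha, n_shuffles = n_shuffles,
         area = if (inherits(activity, "binned_activity")) activity$area else NULL,
         bin_edges = if (inherits(activity, "binned_activity")) activity$bin_edges else NULL),
    class = "selectivity_profile"
  )
}

#' Default maze segments
#'
#' The three analysis segments of the 230-cm imaging maze: first half of
#' the Y-stem (15-75 cm), second half of the Y-stem (75-150 cm), and the
#' Y-arms (150-220 cm).
#'
#' @return Data frame with columns `segment`, `lo`, `hi` (cm, half-open
#'   ranges).
#' @export
segment_spec <- function() {
  data.frame(segment = c("stem_first", "stem_second", "arms"),
             lo = c(15, 75, 150), hi = c(75, 150, 220),
             stringsAsFactors = FALSE)
}

#' Per-segment summaries of activity and selectivity
#'
#' Averages each neuron's activity and selectivity over the bins whose
#' centers fall in each maze segment, and computes the fraction of
#' significantly selective neurons per bin, averaged over the segment's
#' bins, per area.
#'
#' @param activity A [binned_activity()].
#' @param profile A `selectivity_profile` from [shuffle_significance()].
#' @param segments Segment table as from [segment_spec()].
#' @return A list with `per_neuron` (data frame: neuron, area, segment,
#'   mean_activity, mean_selectivity) and `per_area` (data frame: area,
#'   segment, fraction_selective).
#' @export
segment_summaries <- function(activity, profile, segments = segment_spec()) {
  stopifnot(inherits(activity, "binned_activity"),
            inherits(profile, "selectivity_profile"))
  centers <- bin_centers(activity)
  mean_act <- apply(activity$activity, c(1, 3), mean)  # neurons x bins
  per_neuron <- NULL
  per_area <- NULL
  areas <- unique(activity$area)
  for (k in seq_len(nrow(segments))) {
    bins <- which(centers >= segments$lo[k] & centers < segments$hi[k])
    if (length(bins) == 0L)
      stop("segment '", segments$segment[k], "' contains no bins", call. = FALSE)
    per_neuron <- rbind(per_neuron, data.frame(
      neuron = seq_len(n_neurons(activity)), area = activity$area,
      segment = segments$segment[k],
      mean_activity = rowMeans(mean_act[, bins, drop = FALSE]),
      mean_selectivity = rowMeans(profile$selectivity[, bins, drop = FALSE]),
      stringsAsFactors = FALSE
    ))
    # fraction selective per bin (share of neurons significant at that bin),
    # then averaged over the segment's bins
    for (a in areas) {
      nrns <- activity$area == a
      frac_by_bin <- colMeans(profile$significant[nrns, bins, drop = FALSE])
      per_area <- rbind(per_area, data.frame(
        area = a, segment = segments$segment[k],
        fraction_selective = mean(frac_by_bin), stringsAsFactors = FALSE
      ))
    }
  }
  list(per_neuron = per_neuron, per_area = per_area)
}

# longest run handling: returns list of runs (start, length, direction) of
# consecutive significant bins with direction = majority sign of auroc - 0.5
significant_runs <- function(sig, auroc, run_length) {
  r <- rle(as.vector(sig))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= run_length
  lapply(which(keep), function(i) {
    bins <- starts[i]:ends[i]
    s <- sign(auroc[bins] - 0.5)
    maj <- sum(s > 0) - sum(s < 0)
    dir <- if (maj > 0) "pos" else if (maj < 0) "neg"
    else if (sign(mean(auroc[bins]) - 0.5) >= 0) "pos" else "neg"
    list(bins = bins, direction = dir)
  })
}

#' Categorize neuron selectivity across both rules
#'
#' Using all four cue-choice trial types (both rules), classifies each
#' neuron by comparing its left-vs-right choice selectivity between rules.
#' Within each rule, trials are subsampled to `n_per_type` per type, per-bin
#' auROC (left vs right choice) and permutation significance are computed,
#' and the neuron counts as selective in the rule if it has at least
#' `run_length` consecutive significant bins; the rule's preferred choice is
#' the majority sign over the significant run. Categories: `single_trial_type`
#' (selective in one rule only), `choice` (both rules, same preferred
#' choice), `cue` (both rules, opposite choices — i.e. tied to the cue,
#' whose choice mapping reverses across rules), `complex` (conflicting
#' directions at different positions within a rule), `none`.
#'
#' @param activity A [binned_activity()] whose `trial_meta` has `rule`,
#'   `cue` and `choice` columns covering all four trial types.
#' @param n_per_type Trials subsampled per cue-choice-rule type (default
#'   15, giving 60 trials overall).
#' @param run_length Consecutive significant bins required (default 3).
#' @param n_shuffles,alpha Permutation-test parameters (defaults 100, 0.01).
#' @param seed Integer seed.
#' @return Data frame: `neuron`, `area`, `selective_A`, `selective_B`,
#'   `direction_A`, `direction_B` (preferred choice or `NA`), `category`.
#' @export
categorize_across_rules <- function(activity, n_per_type = 15L,
                                    run_length = 3L, n_shuffles = 100L,
                                    alpha = 0.01, seed = NULL) {
  stopifnot(inherits(activity, "binned_activity"))
  meta <- activity$trial_meta
  if (!all(c("rule", "cue", "choice") %in% names(meta)))
    stop("trial_meta must have rule, cue and choice columns", call. = FALSE)
  run_length <- assert_count(run_length, "run_length")

  four_types <- interaction(meta$rule, meta$cue, drop = TRUE)
  keep <- subsample_trials(four_types, n_per_type,
                           seed = derive_seed(seed, "subsample"))
  act <- subset_activity(activity, trials = keep)
  meta <- act$trial_meta

  nn <- n_neurons(act)
  res <- data.frame(neuron = seq_len(nn), area = act$area,
                    selective_A = FALSE, selective_B = FALSE,
                    direction_A = NA_character_, direction_B = NA_character_,
                    category = "none", stringsAsFactors = FALSE)
  conflict <- logical(nn)

  for (rl in c("A", "B")) {
    tr <- which(meta$rule == rl)
    labels <- meta$choice[tr] == "right"   # positive class = right choice
    prof <- shuffle_significance(act$activity[, tr, , drop = FALSE], labels,
                                 n_shuffles = n_shuffles, alpha = alpha,
                                 seed = derive_seed(seed, "shuffle",
                                                    index = match(rl, c("A", "B"))))
    for (nrn in seq_len(nn)) {
      runs <- significant_runs(prof$significant[nrn, ], prof$auroc[nrn, ],
                               run_length)
      if (length(runs) == 0L) next
      dirs <- unique(vapply(runs, `[[`, character(1), "direction"))
      sel_col <- paste0("selective_", rl)
      dir_col <- paste0("direction_", rl)
      res[[sel_col]][nrn] <- TRUE
      if (length(dirs) > 1L) {
        conflict[nrn] <- TRUE             # opposite choices within one rule
      } else {
        res[[dir_col]][nrn] <- if (dirs == "pos") "right" else "left"
      }
    }
  }

  for (nrn in seq_len(nn)) {
    a <- res$selective_A[nrn]; b <- res$selective_B[nrn]
    res$category[nrn] <-
      if (!a && !b) "none"
      else if (conflict[nrn]) "complex"
      else if (xor(a, b)) "single_trial_type"
      else if (res$direction_A[nrn] == res$direction_B[nrn]) "choice"
      else "cue"
  }
  res
}
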