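# Population decoding of trial type and choice, pairwise noise
# correlations, and the correlation-disruption analysis.

default_repetitions <- function(size) if (size <= 10) 40L else 20L

# z-score columns using train-fold statistics only (no leakage);
# zero-variance columns are left centered at 0.
zscore_train_test <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2L, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(x_test, 2, mu), 2, sdv, "/"))
}

svm_fold_accuracy <- function(x, y, fold, cost) {
  acc <- 0
  n <- 0L
  for (k in unique(fold)) {
    tr <- fold != k
    if (length(unique(y[tr])) < 2L) next   # degenerate fold; skip
    z <- zscore_train_test(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    fit <- e1071::svm(z$train, y[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- predict(fit, z$test)
    acc <- acc + sum(pred == y[!tr])
    n <- n + sum(!tr)
  }
  if (n == 0L) return(NA_real_)
  acc / n
}

#' Cross-validated trial-type decoding from subsampled populations
#'
#' For each requested population size and repetition, draws a uniform
#' random subsample of neurons without replacement, then for each spatial
#' bin trains a linear maximum-margin classifier (linear SVM, fixed
#' regularization `cost`) on the z-scored activity with stratified
#' `n_folds`-fold cross-validation, scoring held-out accuracy. Each
#' neuron's activity is standardized using training-fold statistics only.
#' Accuracy is averaged over folds, then spatial bins, then repetitions.
#' By default 40 repetitions are run for populations of 5 or 10 neurons and
#' 20 for larger ones.
#'
#' @param activity A [binned_activity()] (restrict to one area with
#'   [subset_activity()] to analyze areas separately) or a 3-d array.
#' @param labels Two-class trial labels (balanced by prior subsampling).
#' @param sizes Population sizes to evaluate (default
#'   `c(5, 10, 25, 50, 75, 150, 200)`); sizes exceeding the available
#'   neuron count are skipped with a warning.
#' @param n_folds Cross-validation folds (default 10).
#' @param reps Repetitions per size; `NULL` uses the default schedule.
#' @param cost Linear SVM regularization parameter (default 1).
#' @param bins Bin indices to decode (default: all).
#' @param seed Integer seed.
#' @return A list of class `decoding_curve`: `sizes`, `accuracy` (mean per
#'   size), `per_rep` (data frame size/rep/accuracy), `per_bin` (matrix
#'   sizes x bins of repetition-averaged accuracy), `n_folds`.
#' @export
decode_trial_type <- function(activity, labels,
                              sizes = c(5, 10, 25, 50, 75, 150, 200),
                              n_folds = 10L, reps = NULL, cost = 1,
                              bins = NULL, seed = NULL) {
  act <- if (inherits(activity, "binned_activity")) activity$activity else activity
  d <- dim(act)
  pos <- as_binary_labels(labels)
  if (length(pos) != d[2]) stop("labels length != number of trials", call. = FALSE)
  y <- factor(ifelse(pos, "pos", "neg"))
  if (is.null(bins)) bins <- seq_len(d[3])
  local_seed(seed)

  usable <- sizes[sizes <= d[1]]
  if (length(usable) < length(sizes))
    warning("skipping population sizes exceeding ", d[1], " neurons: ",
            paste(setdiff(sizes, usable), collapse = ", "))
  per_rep <- NULL
  per_bin <- matrix(NA_real_, length(usable), length(bins),
                    dimnames = list(usable, bins))
  for (si in seq_along(usable)) {
    size <- usable[si]
    n_rep <- if (is.null(reps)) default_repetitions(size) else reps
    bin_acc_sum <- numeric(length(bins))
    for (r in seq_len(n_rep)) {
      nrns <- sample.int(d[1], size)
      fold <- stratified_folds(y, n_folds)
      bin_acc <- vapply(seq_along(bins), function(bi) {
        x <- t(act[nrns, , bins[bi], drop = TRUE])
        if (size == 1L) x <- matrix(act[nrns, , bins[bi]], ncol = 1L)
        svm_fold_accuracy(x, y, fold, cost)
      }, numeric(1))
      bin_acc_sum <- bin_acc_sum + bin_acc
      per_rep <- rbind(per_rep, data.frame(size = size, rep = r,
                                           accuracy = mean(bin_acc)))
    }
    per_bin[si, ] <- bin_acc_sum / n_rep
  }
  structure(
    list(sizes = usable,
         accuracy = vapply(usable, function(s)
           mean(per_rep$accuracy[per_rep$size == s]), numeric(1)),
         per_rep = per_rep, per_bin = per_bin, n_folds = n_folds),
    class = "decoding_curve"
  )
}

#' @export
print.decoding_curve <- function(x, ...) {
  cat("<decoding_curve>\n")
  print(data.frame(size = x$sizes, accuracy = round(x$accuracy, 3)))
  invisible(x)
}

#' Decode choice from running kinematics, per spatial bin
#'
#' Fits a binomial generalized linear model per spatial bin with four
#' predictors — pitch, roll and yaw treadmill velocities and lateral maze
#' position — and scores held-out accuracy with stratified
#' `n_folds`-fold cross-validation.
#'
#' @param running A `running_trace` from [simulate_running()] (or a list of
#'   trials x bins matrices `pitch`, `roll`, `yaw`, `lateral`).
#' @param choices Choice per trial (`"left"`/`"right"`), default taken from
#'   the trace.
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed (fold assignment).
#' @return Numeric vector of per-bin held-out accuracy.
#' @export
decode_choice_from_running <- function(running, choices = running$choice,
                                       n_folds = 10L, seed = NULL) {
  stopifnot(all(c("pitch", "roll", "yaw", "lateral") %in% names(running)))
  y <- factor(choices)
  if (nlevels(y) != 2L) stop("both choices must be present", call. = FALSE)
  nb <- ncol(running$lateral)
  local_seed(seed)
  acc <- numeric(nb)
  for (b in seq_len(nb)) {
    df <- data.frame(y = y,
                     pitch = running$pitch[, b], roll = running$roll[, b],
                     yaw = running$yaw[, b], lateral = running$lateral[, b])
    if (all(vapply(df[-1], function(v) sd(v) == 0, logical(1)))) {
      warning("bin ", b, ": constant predictors; accuracy set to 0.5")
      acc[b] <- 0.5
      next
    }
    fold <- stratified_folds(y, n_folds)
    hits <- 0L
    for (k in unique(fold)) {
      tr <- fold != k
      fit <- suppressWarnings(glm(y ~ ., data = df[tr, ], family = binomial()))
      p <- suppressWarnings(predict(fit, df[!tr, ], type = "response"))
      pred <- levels(y)[1 + (p > 0.5)]
      hits <- hits + sum(pred == as.character(y[!tr]))
    }
    acc[b] <- hits / length(y)
  }
  acc
}

#' Pairwise noise correlations within and across areas
#'
#' For each pair of neurons, the Pearson correlation of trial-to-trial
#' responses is computed separately for each trial type and then averaged
#' across trial types, conditioning out stimulus-driven variance. With
#' `mode = "per_bin"` (default) the correlation is computed per spatial bin
#' across trials and averaged over bins (avoiding conflation of spatial
#' tuning with trial-to-trial covariance); `"concatenate"` correlates the
#' concatenated trial x bin response vectors. Pairs with zero variance in
#' every usable slice are dropped (count reported via a message).
#'
#' @param activity A [binned_activity()].
#' @param labels Trial-type factor, one per trial (default: cue-choice
#'   types from the trial metadata).
#' @param mode `"per_bin"` or `"concatenate"`.
#' @return A list of class `noise_correlation_summary`: `pairwise_r`
#'   (symmetric neurons x neurons matrix, NA diagonal), `area_pair_means`
#'   (data frame area_a/area_b/mean_r/n_pairs), `mean_r`, `n_pairs_used`.
#' @export
noise_correlations <- function(activity, labels = trial_types(activity),
                               mode = c("per_bin", "concatenate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(activity, "binned_activity"))
  act <- activity$activity
  d <- dim(act)
  types <- as.factor(labels)
  if (length(types) != d[2]) stop("labels length != number of trials", call. = FALSE)
  if (any(table(types) < 3L))
    stop("need at least 3 trials per trial type", call. = FALSE)

  acc <- matrix(0, d[1], d[1])
  cnt <- matrix(0L, d[1], d[1])
  for (tp in levels(types)) {
    tr <- which(types == tp)
    if (mode == "per_bin") {
      r_type <- matrix(0, d[1], d[1])
      n_type <- matrix(0L, d[1], d[1])
      for (b in seq_len(d[3])) {
        m <- t(act[, tr, b, drop = TRUE])          # trials x neurons
        cc <- suppressWarnings(cor(m))             # NA for zero-variance neurons
        ok <- !is.na(cc)
        r_type[ok] <- r_type[ok] + cc[ok]
        n_type <- n_type + ok
      }
      ok <- n_type > 0L
      acc[ok] <- acc[ok] + r_type[ok] / n_type[ok]
      cnt <- cnt + ok
    } else {
      m <- t(matrix(act[, tr, , drop = FALSE], nrow = d[1]))  # (trials*bins) x neurons
      cc <- suppressWarnings(cor(m))
      ok <- !is.na(cc)
      acc[ok] <- acc[ok] + cc[ok]
      cnt <- cnt + ok
    }
  }
  r <- ifelse(cnt > 0L, acc / cnt, NA_real_)
  diag(r) <- NA_real_

  ut <- upper.tri(r)
  n_skipped <- sum(is.na(r[ut]))
  if (n_skipped > 0L)
    message("noise_correlations: ", n_skipped,
            " pairs skipped (zero variance in all usable slices)")

  areas <- activity$area
  combos <- unique(t(apply(expand.grid(a = unique(areas), b = unique(areas),
                                       stringsAsFactors = FALSE), 1, sort)))
  area_pair_means <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    a <- combos[i, 1]; b <- combos[i, 2]
    mask <- (outer(areas == a, areas == b) | outer(areas == b, areas == a)) & ut
    vals <- r[mask]
    data.frame(area_a = a, area_b = b, mean_r = mean(vals, na.rm = TRUE),
               n_pairs = sum(!is.na(vals)), stringsAsFactors = FALSE)
  }))
  structure(
    list(pairwise_r = r, area_pair_means = area_pair_means,
         mean_r = mean(r[ut], na.rm = TRUE),
         n_pairs_used = sum(!is.na(r[ut]))),
    class = "noise_correlation_summary"
  )
}

#' Disrupt noise correlations by trial shuffling
#'
#' Within each trial type, independently permutes the order of trials for
#' each neuron. This destroys shared trial-to-trial variability (driving
#' pairwise noise correlations to zero in expectation) while leaving every
#' single-neuron statistic — per-type trial means, label-conditional
#' response distributions, auROC, selectivity — exactly unchanged.
#'
#' @param activity A [binned_activity()].
#' @param labels Trial-type factor (default: cue-choice types from the
#'   metadata).
#' @param seed Integer seed.
#' @return A [binned_activity()] with shuffled trial order per neuron and
#'   type.
#' @export
disrupt_correlations <- function(activity, labels = trial_types(activity),
                                 seed = NULL) {
  stopifnot(inherits(activity, "binned_activity"))
  types <- as.factor(labels)
  if (any(table(types) < 2L))
    stop("need at least 2 trials per trial type", call. = FALSE)
  local_seed(seed)
  act <- activity$activity
  for (tp in levels(types)) {
    tr <- which(types == tp)
    for (nrn in seq_len(dim(act)[1])) {
      act[nrn, tr, ] <- act[nrn, tr[sample.int(length(tr))], ]
    }
  }
  binned_activity(act, activity$area, activity$bin_edges, activity$trial_meta)
}

#' Effect of noise correlations on decoding accuracy
#'
#' Runs trial-type decoding on the intact activity and on a
#' correlation-disrupted copy, using matched neuron subsamples and
#' cross-validation folds (same decoding seed), and returns the difference
#' intact minus disrupted mean accuracy at the stated population size.
#' Negative values mean decoding is better with correlations disrupted
#' (information-limiting correlations).
#'
#' @param activity A [binned_activity()].
#' @param labels Two-class trial labels.
#' @param size Population size (default 200).
#' @param seed Integer seed (fans out into disruption and decoding
#'   substreams).
#' @param ... Passed to [decode_trial_type()] (e.g. `reps`, `bins`).
#' @return A list: `delta` (intact - disrupted), `intact`, `disrupted`.
#' @export
correlation_impact_on_decoding <- function(activity, labels, size = 200L,
                                           seed = NULL, ...) {
  seed_dec <- derive_seed(seed, "decoding")
  shuffled <- disrupt_correlations(activity, seed = derive_seed(seed, "disruption"))
  intact <- decode_trial_type(activity, labels, sizes = size,
                              seed = seed_dec, ...)
  disrupted <- decode_trial_type(shuffled, labels, sizes = size,
                                 seed = seed_dec, ...)
  list(delta = intact$accuracy - disrupted$accuracy,
       intact = intact$accuracy, disrupted = disrupted$accuracy)
}
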