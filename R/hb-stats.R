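# Hierarchical bootstrap estimation and testing.

resample_nested <- function(groups, levels) {
  # groups: data.frame; levels: character vector of grouping columns,
  # outermost first. Draw groups with replacement at the first level, then
  # recurse within each drawn group; at the innermost level rows are drawn
  # with replacement (resample size = original group size).
  if (length(levels) == 0L) {
    return(groups[sample.int(nrow(groups), replace = TRUE), , drop = FALSE])
  }
  g <- split(groups, groups[[levels[1]]], drop = TRUE)
  drawn <- sample(names(g), length(g), replace = TRUE)
  do.call(rbind, lapply(drawn, function(k) resample_nested(g[[k]], levels[-1])))
}

#' Hierarchical bootstrap of a statistic
#'
#' Estimates the sampling distribution of a statistic by resampling with
#' replacement at nested levels: first groups (e.g. sessions pooled across
#' mice), then units within each drawn group (e.g. trials, or neurons).
#' The SEM is reported as the standard deviation of the `n_boot` resampled
#' statistics.
#'
#' @param data Data frame in long format.
#' @param value Name of the value column.
#' @param levels Character vector of grouping columns, outermost first
#'   (e.g. `"session"` for sessions-then-units; empty for a plain one-level
#'   bootstrap of rows).
#' @param statistic Function reducing a numeric vector to a scalar
#'   (default `mean`).
#' @param n_boot Number of resampled datasets (default 1000).
#' @param seed Integer seed; same seed gives identical bootstrap draws.
#' @param statistic_name Label stored in the result.
#' @return An object of class `bootstrap_result`: `statistic_name`,
#'   `point_estimate` (statistic on the full data), `boot_stats` (length
#'   `n_boot`), `sem` (SD of `boot_stats`), `n_boot`, `levels`.
#' @export
hierarchical_bootstrap <- function(data, value, levels = character(0),
                                   statistic = mean, n_boot = 1000L,
                                   seed = NULL, statistic_name = value) {
  n_boot <- assert_count(n_boot, "n_boot")
  if (!is.data.frame(data)) data <- data.frame(value = data)
  if (!value %in% names(data)) {
    if (identical(value, "value") && !"value" %in% names(data))
      stop("value column '", value, "' not found", call. = FALSE)
    stop("value column '", value, "' not found", call. = FALSE)
  }
  if (nrow(data) == 0L) stop("empty data", call. = FALSE)
  for (lv in levels) {
    if (!lv %in% names(data)) stop("grouping column '", lv, "' not found", call. = FALSE)
    if (any(is.na(data[[lv]]))) stop("NA in grouping column '", lv, "'", call. = FALSE)
  }
  local_seed(seed)
  boot_stats <- vapply(seq_len(n_boot), function(i)
    statistic(resample_nested(data, levels)[[value]]), numeric(1))
  structure(
    list(statistic_name = statistic_name,
         point_estimate = statistic(data[[value]]),
         boot_stats = boot_stats,
         sem = sd(boot_stats),
         n_boot = n_boot, levels = levels),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> ", x$statistic_name, ": ",
      signif(x$point_estimate, 4), " +/- ", signif(x$sem, 4),
      " (SEM of ", x$n_boot, " bootstrap means)\n", sep = "")
  invisible(x)
}

#' Two-tailed bootstrap p-value
#'
#' Compares two bootstrap distributions (or one distribution against a
#' scalar reference): the probability that one is greater or less than the
#' other, whichever is smaller, is doubled to give a two-tailed p. The
#' one-sided probability is floored at `1 / n_boot`, so the smallest
#' reportable two-tailed p is `2 / n_boot`; the result is capped at 1.
#'
#' @param a A `bootstrap_result` or numeric vector of bootstrap statistics.
#' @param b A second `bootstrap_result`/vector (compared resample-wise,
#'   equal lengths required) or a scalar reference (e.g. 0).
#' @return Two-tailed p-value in `(0, 1]`.
#' @export
bootstrap_p <- function(a, b = 0) {
  if (inherits(a, "bootstrap_result")) a <- a$boot_stats
  if (inherits(b, "bootstrap_result")) b <- b$boot_stats
  stopifnot(is.numeric(a), length(a) > 0L, is.numeric(b))
  if (length(b) != 1L && length(a) != length(b))
    stop("bootstrap distributions must have equal length for a paired comparison",
         call. = FALSE)
  p_greater <- mean(a > b)
  p_less <- mean(a < b)
  n <- length(a)
  if (p_greater == 0 && p_less == 0) return(1)   # complete ties: no difference
  min(1, 2 * max(min(p_greater, p_less), 1 / n))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for `m` comparisons.
#'
#' @param p Numeric vector of p-values.
#' @param m Number of comparisons (default `length(p)`; must be at least
#'   that).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p))
    stop("`m` must be at least the number of comparisons", call. = FALSE)
  pmin(1, m * p)
}
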