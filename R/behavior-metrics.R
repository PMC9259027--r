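#' Fraction of correct choices
#'
#' Performance is quantified as the fraction of trials on which the correct
#' choice was made. Guided trials (reward side explicitly marked) are
#' excluded by default because they are always correct by construction;
#' chance performance is 50% correct.
#'
#' @param trials A `session_behavior` data frame (or any data frame with
#'   logical `correct` and `guided` columns).
#' @param include_guided Include visually guided trials?
#' @return Fraction correct in `[0, 1]`.
#' @export
fraction_correct <- function(trials, include_guided = FALSE) {
  trials <- as.data.frame(trials)
  if (!include_guided) trials <- trials[!trials$guided, , drop = FALSE]
  if (nrow(trials) == 0L)
    stop("no trials remain after filtering; cannot compute fraction correct",
         call. = FALSE)
  mean(trials$correct)
}

#' Inhibition effect on performance for one laser target
#'
#' The fraction correct on trials with the laser on the given cortical
#' target minus the fraction correct on trials with the laser steered to
#' the off-cortex control spot, computed within one session.
#'
#' @param session A `session_behavior` data frame.
#' @param target Laser target label (e.g. `"RSC"`).
#' @param include_guided Include guided trials?
#' @return Delta fraction correct in `[-1, 1]`.
#' @export
delta_fraction_correct <- function(session, target, include_guided = FALSE) {
  session <- as.data.frame(session)
  tgt <- session[session$laser_target == target, , drop = FALSE]
  ctl <- session[session$laser_target == "control", , drop = FALSE]
  if (nrow(tgt) == 0L) stop("no trials with laser target '", target, "'", call. = FALSE)
  if (nrow(ctl) == 0L) stop("no control laser trials in session", call. = FALSE)
  fraction_correct(tgt, include_guided) - fraction_correct(ctl, include_guided)
}

#' Signed choice bias
#'
#' `(FracCorr_left - FracCorr_right) / (FracCorr_left + FracCorr_right)`,
#' where `FracCorr_side` is the fraction correct among trials whose correct
#' side is that side. A value of 1 (-1) means the subject only made left
#' (right) choices.
#'
#' @param session A `session_behavior` data frame.
#' @param target Laser target to restrict to, or `NULL` for all trials.
#' @param include_guided Include guided trials?
#' @return Signed bias in `[-1, 1]`.
#' @export
signed_choice_bias <- function(session, target = NULL, include_guided = FALSE) {
  session <- as.data.frame(session)
  if (!is.null(target)) {
    session <- session[session$laser_target == target, , drop = FALSE]
    if (nrow(session) == 0L)
      stop("no trials with laser target '", target, "'", call. = FALSE)
  }
  if (!include_guided) session <- session[!session$guided, , drop = FALSE]
  left <- session[session$correct_side == "left", , drop = FALSE]
  right <- session[session$correct_side == "right", , drop = FALSE]
  if (nrow(left) == 0L || nrow(right) == 0L)
    stop("need at least one trial of each correct side", call. = FALSE)
  fl <- mean(left$correct)
  fr <- mean(right$correct)
  if (fl + fr == 0)
    stop("no correct responses at all; signed choice bias undefined", call. = FALSE)
  (fl - fr) / (fl + fr)
}

#' Per-session performance summary
#'
#' Fraction correct overall and per laser target, with the inhibition
#' effect (delta fraction correct) and signed choice bias per cortical
#' target when control trials are present.
#'
#' @param session A `session_behavior` data frame.
#' @param include_guided Include guided trials?
#' @return A list of class `performance_summary`.
#' @export
performance_summary <- function(session, include_guided = FALSE) {
  session <- as.data.frame(session)
  nong <- if (include_guided) session else session[!session$guided, , drop = FALSE]
  targets <- setdiff(unique(session$laser_target), "none")
  cortical <- setdiff(targets, "control")
  by_target <- vapply(targets, function(tg)
    fraction_correct(session[session$laser_target == tg, , drop = FALSE],
                     include_guided), numeric(1))
  has_ctl <- "control" %in% targets
  delta <- if (has_ctl && length(cortical))
    vapply(cortical, function(tg)
      delta_fraction_correct(session, tg, include_guided), numeric(1))
  else setNames(numeric(0), character(0))
  bias <- vapply(targets, function(tg)
    tryCatch(signed_choice_bias(session, tg, include_guided),
             error = function(e) NA_real_), numeric(1))
  structure(
    list(fraction_correct = mean(nong$correct), n_trials = nrow(nong),
         by_target = by_target, delta_fraction_correct = delta,
         signed_choice_bias = bias),
    class = "performance_summary"
  )
}

#' Training sessions to performance criterion
#'
#' Counts sessions from the first Y-maze day until both criteria are met
#' within one session: at most 20% visually guided trials, and fraction
#' correct of at least 70% (switching task, all trials including post-switch
#' periods) or 85% (simple and delay tasks). For the delay task a session
#' additionally qualifies only where `delay_ok` is `TRUE` (delay length
#' criterion reached).
#'
#' @param sessions List of `session_behavior` data frames in chronological
#'   order.
#' @param task_kind `"simple"`, `"delay"`, or `"switching"`.
#' @param guided_max Maximum guided-trial fraction (default 0.2).
#' @param delay_ok Logical vector, one per session; delay-length criterion
#'   flag used for the delay task only.
#' @param include_guided Include guided trials in fraction correct?
#' @return 1-based index of the first qualifying session, or `NA_integer_`
#'   if no session qualifies.
#' @export
sessions_to_criterion <- function(sessions,
                                  task_kind = c("simple", "delay", "switching"),
                                  guided_max = 0.2, delay_ok = NULL,
                                  include_guided = FALSE) {
  task_kind <- match.arg(task_kind)
  if (length(sessions) == 0L) stop("empty session list", call. = FALSE)
  fc_min <- if (task_kind == "switching") 0.70 else 0.85
  if (task_kind == "delay") {
    if (is.null(delay_ok)) delay_ok <- rep(TRUE, length(sessions))
    stopifnot(length(delay_ok) == length(sessions))
  }
  for (i in seq_along(sessions)) {
    s <- as.data.frame(sessions[[i]])
    ok <- mean(s$guided) <= guided_max &&
      fraction_correct(s, include_guided) >= fc_min
    if (task_kind == "delay") ok <- ok && isTRUE(delay_ok[i])
    if (ok) return(i)
  }
  NA_integer_
}

#' Performance aligned to rule switches
#'
#' Mean correctness per trial offset relative to each rule switch (offset 0
#' = first trial under the new rule), averaged over all switches in the
#' supplied sessions. Offsets extending past a block or session edge are
#' averaged over the switches for which data exist.
#'
#' @param sessions List of `session_behavior` data frames (or a single one).
#' @param window Maximum |offset| in trials.
#' @return A list of class `switch_aligned_curve` with `offsets`,
#'   `mean_performance`, `n`, `n_switches`.
#' @export
switch_aligned_performance <- function(sessions, window = 30L) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  window <- assert_count(window, "window")
  offsets <- -window:window
  acc <- num <- setNames(numeric(length(offsets)), offsets)
  n_switches <- 0L
  for (s in sessions) {
    s <- as.data.frame(s)
    for (sw in switch_indices(s)) {       # 0-based index of new block start
      n_switches <- n_switches + 1L
      for (k in seq_along(offsets)) {
        idx <- sw + offsets[k] + 1L       # 1-based row
        if (idx >= 1L && idx <= nrow(s)) {
          acc[k] <- acc[k] + s$correct[idx]
          num[k] <- num[k] + 1
        }
      }
    }
  }
  if (n_switches == 0L) stop("no rule switches found in sessions", call. = FALSE)
  keep <- num > 0
  structure(
    list(offsets = offsets[keep], mean_performance = (acc / num)[keep],
         n = num[keep], n_switches = n_switches),
    class = "switch_aligned_curve"
  )
}
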