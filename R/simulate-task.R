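#' Simulate one behavioral Y-maze session
#'
#' Steps a stochastic agent through a session of the configured task,
#' producing one trial record per row. The switching task applies a rule
#' switch before trial `t` iff (i) at least `switch_min_trials` have elapsed
#' since the previous switch or session start, (ii) the fraction correct
#' over the last `switch_window` trials is at least
#' `switch_perf_threshold`, and (iii) trial `t - 1` was correct. The
#' criterion is evaluated once per trial boundary, so at most one switch can
#' occur between consecutive trials.
#'
#' Bias correction (when `task$bias_correction_run > 0`): if the agent made
#' the same choice on that many consecutive trials irrespective of
#' correctness, the next trial's correct side is forced to the opposite
#' side (cue chosen to match under the current rule) and flagged
#' `forced_by_bias_correction`; the run counter then restarts from the
#' following trial.
#'
#' @param task A [task_config()].
#' @param agent An [agent_config()].
#' @param seed Integer seed; same seed gives a bit-identical session.
#' @param session_id,mouse_id Identifiers copied into every trial row.
#' @param laser Optional [laser_spec()]; `NULL` means no laser trials.
#' @return A `data.frame` of class `session_behavior` with columns
#'   `session_id`, `mouse_id`, `trial_index` (0-based), `cue`, `rule`,
#'   `correct_side`, `choice`, `correct`, `guided`, `laser_target`,
#'   `forced_by_bias_correction`, and an attribute `switch_trials` holding
#'   the 0-based indices of the first trial of each new rule block.
#' @export
simulate_task_session <- function(task, agent, seed = NULL,
                                  session_id = "S1", mouse_id = "M1",
                                  laser = NULL) {
  stopifnot(inherits(task, "task_config"), inherits(agent, "agent_config"))
  if (!is.null(laser)) stopifnot(inherits(laser, "laser_spec"))
  local_seed(seed)

  n <- task$n_trials
  rule <- task$initial_rule
  last_switch <- 0L            # 0-based index of the current block's first trial
  switch_trials <- integer(0)
  run_len <- 0L                # consecutive same-choice run before this trial
  run_side <- NA_character_

  cue <- correct_side <- choice <- character(n)
  rule_v <- character(n)
  correct <- guided <- forced <- logical(n)
  laser_target <- rep("none", n)

  for (t in seq_len(n) - 1L) {   # 0-based trial index
    # (i)-(iii): rule-switch criterion, checked once per trial boundary
    if (task$task_kind == "switching" && t > 0L) {
      since <- t - last_switch
      if (since >= task$switch_min_trials) {
        w <- task$switch_window
        recent <- correct[(t - w + 1L):t]   # trials t-w .. t-1 (0-based)
        if (mean(recent) >= task$switch_perf_threshold && correct[t]) {
          rule <- other_rule(rule)
          last_switch <- t
          switch_trials <- c(switch_trials, t)
        }
      }
    }
    rule_v[t + 1L] <- rule

    forced_t <- task$bias_correction_run > 0L &&
      run_len >= task$bias_correction_run
    if (forced_t) {
      correct_side[t + 1L] <- opposite_side(run_side)
      cue[t + 1L] <- cue_for_side(correct_side[t + 1L], rule)
    } else if (task$task_kind == "run_to_target") {
      correct_side[t + 1L] <- sample(c("left", "right"), 1L)
      cue[t + 1L] <- sample(c("horizontal", "vertical"), 1L)
    } else {
      cue[t + 1L] <- sample(c("horizontal", "vertical"), 1L)
      correct_side[t + 1L] <- side_for_cue(cue[t + 1L], rule)
    }
    forced[t + 1L] <- forced_t

    if (!is.null(laser) && runif(1) < laser$p_laser)
      laser_target[t + 1L] <- sample(laser$targets, 1L)

    guided_t <- task$task_kind == "run_to_target" ||
      runif(1) < task$guided_fraction
    guided[t + 1L] <- guided_t

    if (guided_t) {
      choice[t + 1L] <- correct_side[t + 1L]
    } else {
      since_switch <- t - last_switch
      p_eff <- agent$p_correct
      if (length(switch_trials) > 0L && agent$post_switch_relearn_trials > 0L &&
          since_switch < agent$post_switch_relearn_trials) {
        p_eff <- 0.5 + (agent$p_correct - 0.5) *
          since_switch / agent$post_switch_relearn_trials
      }
      tgt <- laser_target[t + 1L]
      if (!tgt %in% c("none", "control") && !is.null(laser) &&
          tgt %in% names(laser$effects)) {
        p_eff <- min(1, max(0, p_eff - laser$effects[[tgt]]))
      }
      if (runif(1) < agent$lapse_rate) {
        p_left <- 0.5
      } else {
        p_left <- if (correct_side[t + 1L] == "left") p_eff else 1 - p_eff
      }
      p_left <- min(1, max(0, p_left + agent$side_bias / 2))
      choice[t + 1L] <- if (runif(1) < p_left) "left" else "right"
    }
    correct[t + 1L] <- choice[t + 1L] == correct_side[t + 1L]

    # same-choice run bookkeeping; a forced trial restarts the count at the
    # following trial (its own choice is not counted)
    if (forced_t) {
      run_len <- 0L
      run_side <- NA_character_
    } else if (!is.na(run_side) && choice[t + 1L] == run_side) {
      run_len <- run_len + 1L
    } else {
      run_side <- choice[t + 1L]
      run_len <- 1L
    }
  }

  out <- data.frame(
    session_id = session_id, mouse_id = mouse_id,
    trial_index = seq_len(n) - 1L,
    cue = cue, rule = rule_v, correct_side = correct_side, choice = choice,
    correct = correct, guided = guided, laser_target = laser_target,
    forced_by_bias_correction = forced,
    stringsAsFactors = FALSE
  )
  attr(out, "switch_trials") <- switch_trials
  class(out) <- c("session_behavior", "data.frame")
  out
}

#' Rule-switch trial indices of a session
#'
#' Returns the 0-based indices of trials on which a new rule block starts,
#' recovered from the `rule` column (so it works for sessions read back from
#' CSV, which carry no attributes).
#'
#' @param session A `session_behavior` data frame.
#' @return Integer vector of 0-based switch trial indices.
#' @export
switch_indices <- function(session) {
  r <- session$rule
  which(r[-1] != r[-length(r)])  # 1-based position == 0-based index of new block
}
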