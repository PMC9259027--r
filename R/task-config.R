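#' Task configuration for the Y-maze simulator
#'
#' Describes one behavioral session of a virtual-reality Y-maze task. In all
#' task variants a wall cue (horizontal or vertical grating) is associated
#' with a rewarded side. Under Rule A, horizontal maps to left and vertical
#' to right; Rule B reverses the mapping. In the switching task the rule
#' changes unsignaled within a session once three criteria are jointly met:
#' at least `switch_min_trials` since the previous switch (or session start),
#' at least `switch_perf_threshold` fraction correct over the last
#' `switch_window` trials, and a correct choice on the immediately preceding
#' trial.
#'
#' @param task_kind One of `"simple"`, `"delay"`, `"switching"`,
#'   `"run_to_target"`. Only the switching task performs rule switches; the
#'   run-to-target task has no informative wall cue, so every trial's correct
#'   side is drawn at random and marked guided.
#' @param n_trials Number of trials in the session.
#' @param guided_fraction Probability that a trial is visually guided
#'   (reward side marked by a checkerboard); guided trials are always
#'   answered correctly.
#' @param switch_min_trials Minimum trials since the last switch (or session
#'   start) before a rule switch may occur. Default 75.
#' @param switch_window Window (trials) over which recent performance is
#'   evaluated for the switch criterion. Default 30.
#' @param switch_perf_threshold Minimum fraction correct over
#'   `switch_window` recent trials. Default 0.85.
#' @param bias_correction_run Length of a same-choice run that triggers bias
#'   correction: if the agent made the identical choice on this many
#'   consecutive trials (irrespective of correctness), the next trial's
#'   correct side is forced to the opposite side. Set to `0` to disable.
#'   Default 5.
#' @param initial_rule Rule in force at the session start, `"A"` or `"B"`.
#' @param delay_onset_fraction For the delay task only: fraction of the stem
#'   after which the cue disappears, in `[0, 1]`. Ignored by the simulator's
#'   choice model (the agent is not cue-limited) but carried for metadata.
#' @return An object of class `task_config`.
#' @export
task_config <- function(task_kind = c("simple", "delay", "switching", "run_to_target"),
                        n_trials = 300L,
                        guided_fraction = 0,
                        switch_min_trials = 75L,
                        switch_window = 30L,
                        switch_perf_threshold = 0.85,
                        bias_correction_run = 5L,
                        initial_rule = c("A", "B"),
                        delay_onset_fraction = NULL) {
  task_kind <- match.arg(task_kind)
  initial_rule <- match.arg(initial_rule)
  switch_args_given <- !missing(switch_min_trials) || !missing(switch_window) ||
    !missing(switch_perf_threshold)
  if (task_kind != "switching" && switch_args_given)
    stop("rule-switch criteria are only meaningful for the switching task",
         call. = FALSE)
  n_trials <- assert_count(n_trials, "n_trials")
  assert_probability(guided_fraction, "guided_fraction")
  assert_probability(switch_perf_threshold, "switch_perf_threshold")
  switch_min_trials <- assert_count(switch_min_trials, "switch_min_trials")
  switch_window <- assert_count(switch_window, "switch_window")
  bias_correction_run <- assert_count(bias_correction_run, "bias_correction_run",
                                      positive = FALSE)
  if (switch_min_trials < switch_window)
    stop("`switch_min_trials` must be >= `switch_window`", call. = FALSE)
  if (!is.null(delay_onset_fraction)) {
    if (task_kind != "delay")
      stop("`delay_onset_fraction` applies to the delay task only", call. = FALSE)
    assert_probability(delay_onset_fraction, "delay_onset_fraction")
  }
  structure(
    list(task_kind = task_kind, n_trials = n_trials,
         guided_fraction = guided_fraction,
         switch_min_trials = switch_min_trials, switch_window = switch_window,
         switch_perf_threshold = switch_perf_threshold,
         bias_correction_run = bias_correction_run,
         initial_rule = initial_rule,
         delay_onset_fraction = delay_onset_fraction),
    class = "task_config"
  )
}

#' Agent (simulated mouse) configuration
#'
#' A stochastic choice model standing in for the mouse. On nonguided trials
#' the agent chooses the correct side with probability `p_correct`; after
#' each rule switch its effective accuracy ramps linearly from chance (0.5)
#' back to `p_correct` over `post_switch_relearn_trials` trials, reproducing
#' the performance drop-and-recovery seen around unsignaled switches without
#' modeling belief updating. With probability `lapse_rate` the agent lapses
#' and chooses uniformly at random. `side_bias` adds `side_bias / 2` to the
#' probability of a left choice (clipped to `[0, 1]`), so `side_bias = 1`
#' with `p_correct = 0.5` produces an agent that always chooses left.
#'
#' @param p_correct Probability of choosing the correct side at asymptote.
#' @param side_bias Excess tendency to choose left, in `[-1, 1]`.
#' @param lapse_rate Probability of a uniform random lapse.
#' @param post_switch_relearn_trials Trials over which accuracy recovers
#'   after a rule switch (0 = instant relearning).
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(p_correct = 0.9, side_bias = 0, lapse_rate = 0,
                         post_switch_relearn_trials = 0L) {
  assert_probability(p_correct, "p_correct")
  assert_probability(lapse_rate, "lapse_rate")
  if (!is.numeric(side_bias) || length(side_bias) != 1L ||
      is.na(side_bias) || abs(side_bias) > 1)
    stop("`side_bias` must be in [-1, 1]", call. = FALSE)
  post_switch_relearn_trials <-
    assert_count(post_switch_relearn_trials, "post_switch_relearn_trials",
                 positive = FALSE)
  structure(
    list(p_correct = p_correct, side_bias = side_bias, lapse_rate = lapse_rate,
         post_switch_relearn_trials = post_switch_relearn_trials),
    class = "agent_config"
  )
}

#' Photoinhibition schedule for simulated sessions
#'
#' Optional laser schedule: each trial is a laser trial with probability
#' `p_laser`; on laser trials the target is drawn uniformly from `targets`
#' (which should include `"control"`). A named vector `effects` gives, per
#' cortical target, the decrement applied to the agent's effective accuracy
#' on trials with that target (control and off trials are unaffected).
#'
#' @param p_laser Probability that a trial receives laser light.
#' @param targets Candidate targets, a subset of
#'   `c("control", "S1", "RSC", "PPC")`.
#' @param effects Named numeric vector of accuracy decrements per target.
#' @return An object of class `laser_spec`.
#' @export
laser_spec <- function(p_laser = 0.5,
                       targets = c("control", "S1", "RSC", "PPC"),
                       effects = c(S1 = 0, RSC = 0, PPC = 0)) {
  assert_probability(p_laser, "p_laser")
  targets <- match.arg(targets, c("control", "S1", "RSC", "PPC"),
                       several.ok = TRUE)
  if (length(effects) && is.null(names(effects)))
    stop("`effects` must be a named vector", call. = FALSE)
  structure(list(p_laser = p_laser, targets = targets, effects = effects),
            class = "laser_spec")
}
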