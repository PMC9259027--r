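# Fixtures built in code.

# Hand-built session with explicit choice/correct structure.
make_session <- function(correct_side, choice, guided = FALSE,
                         laser_target = "none", rule = "A",
                         session_id = "S1", mouse_id = "M1") {
  n <- length(correct_side)
  cue <- ifelse(rule == "A",
                ifelse(correct_side == "left", "horizontal", "vertical"),
                ifelse(correct_side == "left", "vertical", "horizontal"))
  df <- data.frame(
    session_id = session_id, mouse_id = mouse_id,
    trial_index = seq_len(n) - 1L,
    cue = cue, rule = rule, correct_side = correct_side, choice = choice,
    correct = choice == correct_side,
    guided = rep_len(guided, n),
    laser_target = rep_len(laser_target, n),
    forced_by_bias_correction = FALSE,
    stringsAsFactors = FALSE
  )
  class(df) <- c("session_behavior", "data.frame")
  df
}

# Balanced two-type trial metadata (left/right choices, matching cues).
make_two_type_meta <- function(n_per_type) {
  data.frame(
    cue = rep(c("horizontal", "vertical"), each = n_per_type),
    choice = rep(c("left", "right"), each = n_per_type),
    rule = "A", correct = TRUE, guided = FALSE,
    stringsAsFactors = FALSE
  )
}

# Small deterministic activity cube with optional per-type mean shifts.
# shift: neurons x 1 vector added on trials of the second type.
make_activity <- function(n_neurons, n_per_type, n_bins, shift = 0,
                          noise_sd = 0.1, seed = 1, bin_size = 5) {
  withr::with_seed(seed, {
    meta <- make_two_type_meta(n_per_type)
    act <- array(rnorm(n_neurons * 2 * n_per_type * n_bins, sd = noise_sd),
                 dim = c(n_neurons, 2 * n_per_type, n_bins))
    type2 <- (n_per_type + 1):(2 * n_per_type)
    act[, type2, ] <- act[, type2, ] + shift
    binned_activity(act, rep("PPC", n_neurons),
                    seq(0, by = bin_size, length.out = n_bins + 1),
                    meta)
  })
}

# A session + generated population shared by several analysis tests.
make_generated_session <- function(seed = 101, n_trials = 220, n_per_type = 30,
                                   ...) {
  beh <- simulate_task_session(task_config("simple", n_trials = n_trials),
                               agent_config(p_correct = 0.9), seed = seed)
  hp <- select_high_performance_trials(beh)
  keep <- hp[subsample_trials(trial_types(beh[hp, , drop = FALSE]), n_per_type,
                              seed = seed + 1)]
  cfg <- neural_gen_config(...)
  gen <- generate_population_activity(beh[keep, , drop = FALSE], cfg,
                                      seed = seed + 2)
  gen$behavior <- beh
  gen$labels <- trial_types(gen$activity)
  gen
}
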