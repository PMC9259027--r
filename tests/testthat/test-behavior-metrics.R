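test_that("fraction correct counts correct choices over filtered trials", {
  s <- make_session(correct_side = rep("left", 50),
                    choice = c(rep("left", 45), rep("right", 5)))
  expect_equal(fraction_correct(s), 0.9)

  sg <- make_session(correct_side = rep(c("left", "right"), 10),
                     choice = rep(c("left", "right"), 10),
                     guided = TRUE)
  expect_error(fraction_correct(sg), "no trials")
  expect_equal(fraction_correct(sg, include_guided = TRUE), 1)
})

test_that("a uniform-random chooser performs at 50% chance", {
  s <- simulate_task_session(
    task_config("simple", n_trials = 10000L, bias_correction_run = 0L),
    agent_config(p_correct = 0.5), seed = 41)
  se <- sqrt(0.25 / nrow(s))
  expect_lt(abs(fraction_correct(s) - 0.5), 3 * se)
})

test_that("delta fraction correct subtracts control from target performance", {
  s <- make_session(
    correct_side = rep("left", 40),
    choice = c(rep("left", 18), rep("right", 2),    # control: 0.90
               rep("left", 11), rep("right", 9)),   # RSC: 0.55
    laser_target = rep(c("control", "RSC"), each = 20))
  expect_equal(delta_fraction_correct(s, "RSC"), -0.35)
  expect_error(delta_fraction_correct(s, "PPC"), "PPC")

  # antisymmetry under exchanging target and control trial sets
  s_swapped <- s
  s_swapped$laser_target <- rep(c("RSC", "control"), each = 20)
  expect_equal(delta_fraction_correct(s_swapped, "RSC"),
               -delta_fraction_correct(s, "RSC"))
})

test_that("a simulated RSC-specific deficit is recovered by delta fraction correct", {
  ls <- laser_spec(p_laser = 0.8, effects = c(RSC = 0.3, S1 = 0, PPC = 0))
  s <- simulate_task_session(
    task_config("simple", n_trials = 8000L, bias_correction_run = 0L),
    agent_config(p_correct = 0.9), seed = 42, laser = ls)
  n_rsc <- sum(s$laser_target == "RSC")
  tol <- 3 * sqrt(0.25 / n_rsc) * sqrt(2)
  expect_lt(abs(delta_fraction_correct(s, "RSC") - (-0.3)), tol)
  expect_lt(abs(delta_fraction_correct(s, "S1")), tol)
})

test_that("signed choice bias follows the per-side fraction-correct formula", {
  all_left <- make_session(correct_side = rep(c("left", "right"), 10),
                           choice = rep("left", 20))
  expect_identical(signed_choice_bias(all_left), 1)
  all_right <- make_session(correct_side = rep(c("left", "right"), 10),
                            choice = rep("right", 20))
  expect_identical(signed_choice_bias(all_right), -1)

  # FracCorr_left = 0.9, FracCorr_right = 0.6 -> 0.3/1.5 = 0.2
  s <- make_session(
    correct_side = rep(c("left", "right"), each = 10),
    choice = c(rep("left", 9), "right", rep("right", 6), rep("left", 4)))
  expect_equal(signed_choice_bias(s), 0.2)

  # swapping left/right labels flips the sign
  s2 <- s
  s2$correct_side <- ifelse(s$correct_side == "left", "right", "left")
  s2$choice <- ifelse(s$choice == "left", "right", "left")
  s2$correct <- s2$choice == s2$correct_side
  expect_equal(signed_choice_bias(s2), -signed_choice_bias(s))

  sym <- make_session(correct_side = rep(c("left", "right"), each = 4),
                      choice = c("left", "left", "left", "right",
                                 "right", "right", "right", "left"))
  expect_equal(signed_choice_bias(sym), 0)

  none <- make_session(correct_side = rep(c("left", "right"), 3),
                       choice = rep(c("right", "left"), 3))
  expect_error(signed_choice_bias(none), "undefined")
})

test_that("sessions_to_criterion scans guided fraction and accuracy criteria", {
  mk <- function(guided_frac, acc, n = 100L) {
    n_g <- round(n * guided_frac)
    n_c <- round((n - n_g) * acc)
    make_session(
      correct_side = rep("left", n),
      choice = c(rep("left", n_g),                 # guided, always correct
                 rep("left", n_c), rep("right", n - n_g - n_c)),
      guided = rep(c(TRUE, FALSE), c(n_g, n - n_g)))
  }
  sessions <- list(mk(0.5, 0.6), mk(0.3, 0.8), mk(0.15, 0.9))
  expect_identical(sessions_to_criterion(sessions, "simple"), 3L)
  expect_identical(sessions_to_criterion(list(mk(0.1, 0.95)), "simple"), 1L)
  expect_identical(sessions_to_criterion(list(mk(0.5, 0.6)), "simple"),
                   NA_integer_)
  # switching task uses the laxer 70% criterion
  expect_identical(sessions_to_criterion(list(mk(0.15, 0.8)), "switching"), 1L)
  # delay task additionally requires the delay-length criterion
  expect_identical(
    sessions_to_criterion(list(mk(0.1, 0.95), mk(0.1, 0.95)), "delay",
                          delay_ok = c(FALSE, TRUE)), 2L)
  expect_error(sessions_to_criterion(list(), "simple"), "empty")
})

test_that("switch-aligned performance shows the drop and recovery of relearning", {
  perfect <- simulate_task_session(task_config("switching", n_trials = 300L),
                                   agent_config(p_correct = 1), seed = 43)
  curve <- switch_aligned_performance(perfect, window = 10L)
  expect_true(all(curve$mean_performance == 1))

  relearn <- simulate_task_session(
    task_config("switching", n_trials = 500L, bias_correction_run = 0L),
    agent_config(p_correct = 0.95, post_switch_relearn_trials = 20L),
    seed = 44)
  curve <- switch_aligned_performance(relearn, window = 25L)
  pre <- mean(curve$mean_performance[curve$offsets < 0])
  early <- mean(curve$mean_performance[curve$offsets >= 0 & curve$offsets < 5])
  late <- mean(curve$mean_performance[curve$offsets >= 20])
  expect_lt(early, pre - 0.2)
  expect_gt(late, pre - 0.1)

  no_switch <- simulate_task_session(task_config("simple", n_trials = 50L),
                                     agent_config(1), seed = 45)
  expect_error(switch_aligned_performance(no_switch), "no rule switches")
})

test_that("performance_summary collects per-target metrics", {
  s <- make_session(
    correct_side = rep(c("left", "right"), 20),
    choice = c(rep(c("left", "right"), 10), rep("left", 20)),
    laser_target = rep(c("control", "RSC"), each = 20))
  ps <- performance_summary(s)
  expect_equal(unname(ps$by_target["control"]), 1)
  expect_equal(unname(ps$by_target["RSC"]), 0.5)
  expect_equal(unname(ps$delta_fraction_correct["RSC"]), -0.5)
  expect_equal(unname(ps$signed_choice_bias["RSC"]), 1)
})
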