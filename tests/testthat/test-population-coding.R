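test_that("a noiseless, strongly selective population decodes perfectly", {
  n <- 15
  lab <- rep(c(FALSE, TRUE), each = n)
  act <- array(0, dim = c(12, 2 * n, 2))
  act[1:6, lab, ] <- 1          # half the neurons prefer the positive type
  act[7:12, !lab, ] <- 1
  dec <- decode_trial_type(act, lab, sizes = c(5, 10), reps = 3, seed = 71)
  expect_equal(dec$accuracy, c(1, 1))
  expect_equal(dec$sizes, c(5, 10))
})

test_that("shuffled labels decode at chance", {
  g <- make_generated_session(seed = 72, n_neurons_per_area = c(PPC = 30L),
                              n_bins = 4L, selectivity_strength = 1)
  lab <- withr::with_seed(73, sample(as.logical(g$labels == levels(g$labels)[1])))
  dec <- decode_trial_type(g$activity, lab, sizes = 10, reps = 40, seed = 74)
  se <- sd(dec$per_rep$accuracy) / sqrt(nrow(dec$per_rep))
  expect_lt(abs(dec$accuracy - 0.5), max(3 * se, 0.03))
})

test_that("accuracy grows with selectivity strength and population size", {
  accs <- vapply(c(0.2, 1.5), function(s) {
    g <- make_generated_session(seed = 75, n_neurons_per_area = c(PPC = 40L),
                                n_bins = 6L, selectivity_strength = s,
                                fraction_selective = 0.5)
    decode_trial_type(g$activity, g$labels, sizes = c(5, 25), reps = 8,
                      seed = 76)$accuracy
  }, numeric(2))
  expect_true(all(accs[, 2] > accs[, 1]))        # stronger selectivity helps
  expect_gt(accs[2, 2], accs[1, 2])              # larger population helps
})

test_that("oversized populations are skipped with a warning", {
  act <- make_activity(8, 10, 2, shift = 1)
  expect_warning(
    dec <- decode_trial_type(act, trial_types(act), sizes = c(5, 50),
                             reps = 2, seed = 77),
    "skipping")
  expect_equal(dec$sizes, 5)
})

test_that("choice decoding from running is at chance under the null construction", {
  beh <- simulate_task_session(task_config("simple", n_trials = 200L,
                                           bias_correction_run = 0L),
                               agent_config(p_correct = 0.5), seed = 78)
  tr <- simulate_running(beh, rep(0, 6), noise_sd = 1, seed = 79)
  acc <- decode_choice_from_running(tr, seed = 80)
  expect_true(all(abs(acc - 0.5) < 0.12))
  # constant predictors fall back to chance with a warning
  tr0 <- tr
  for (ch in c("pitch", "roll", "yaw", "lateral"))
    tr0[[ch]] <- matrix(1, nrow(tr[[ch]]), 1)
  expect_warning(acc0 <- decode_choice_from_running(tr0, seed = 81),
                 "constant")
  expect_equal(acc0, 0.5)
})

test_that("duplicated and negated neurons give correlations of +1 and -1", {
  act0 <- make_activity(1, 10, 3, noise_sd = 0.5, seed = 82)
  act <- array(0, dim = c(3, 20, 3))
  act[1, , ] <- act0$activity[1, , ]
  act[2, , ] <- act0$activity[1, , ]      # duplicate
  act[3, , ] <- -act0$activity[1, , ]     # negation
  ba <- binned_activity(act, rep("PPC", 3), act0$bin_edges, act0$trial_meta)
  nc <- noise_correlations(ba)
  expect_equal(nc$pairwise_r[1, 2], 1)
  expect_equal(nc$pairwise_r[1, 3], -1)
  expect_equal(nc$pairwise_r, t(nc$pairwise_r))
})

test_that("adding a constant to one neuron leaves correlations unchanged", {
  g <- make_generated_session(seed = 83, n_neurons_per_area = c(PPC = 10L),
                              n_bins = 4L, clip = FALSE)
  nc1 <- noise_correlations(g$activity, g$labels)
  shifted <- g$activity
  shifted$activity[3, , ] <- shifted$activity[3, , ] + 100
  nc2 <- noise_correlations(shifted, g$labels)
  expect_equal(nc1$pairwise_r, nc2$pairwise_r)
})

test_that("area-pair means cover within- and across-area combinations", {
  g <- make_generated_session(seed = 84,
                              n_neurons_per_area = c(V1 = 8L, PPC = 8L, RSC = 8L),
                              n_bins = 4L)
  nc <- suppressMessages(noise_correlations(g$activity, g$labels))
  expect_equal(nrow(nc$area_pair_means), 6)   # 3 within + 3 across
  expect_true(all(nc$area_pair_means$n_pairs > 0))
})

test_that("trial shuffling preserves single-neuron statistics bit-exactly", {
  g <- make_generated_session(seed = 85, n_neurons_per_area = c(PPC = 20L),
                              n_bins = 5L, shared_noise_loading = 0.6)
  lab <- g$labels
  shuf <- disrupt_correlations(g$activity, lab, seed = 86)
  for (tp in levels(lab)) {
    tr <- which(lab == tp)
    expect_identical(apply(g$activity$activity[, tr, ], c(1, 3), mean),
                     apply(shuf$activity[, tr, ], c(1, 3), mean))
    expect_identical(apply(g$activity$activity[, tr, ], c(1, 3), sort),
                     apply(shuf$activity[, tr, ], c(1, 3), sort))
  }
  two <- as.logical(lab == levels(lab)[2])
  expect_identical(auroc_per_bin(g$activity, two), auroc_per_bin(shuf, two))
})

test_that("trial shuffling collapses the shared-latent correlations", {
  g <- make_generated_session(seed = 87, n_neurons_per_area = c(PPC = 40L),
                              n_bins = 5L, shared_noise_loading = 0.6,
                              clip = FALSE)
  before <- noise_correlations(g$activity, g$labels)$mean_r
  after <- noise_correlations(disrupt_correlations(g$activity, g$labels, seed = 88),
                              g$labels)$mean_r
  expect_gt(before, 0.2)
  expect_lt(abs(after), 0.05)
})

test_that("disruption has no effect on decoding when there is nothing to disrupt", {
  g <- make_generated_session(seed = 89, n_neurons_per_area = c(PPC = 30L),
                              n_bins = 4L, shared_noise_loading = 0)
  imp <- correlation_impact_on_decoding(g$activity, g$labels, size = 20,
                                        reps = 10, seed = 90)
  expect_lt(abs(imp$delta), 0.05)
})

test_that("matched seeds make the disruption comparison reproducible", {
  g <- make_generated_session(seed = 91, n_neurons_per_area = c(PPC = 15L),
                              n_bins = 3L)
  i1 <- correlation_impact_on_decoding(g$activity, g$labels, size = 10,
                                       reps = 3, seed = 92)
  i2 <- correlation_impact_on_decoding(g$activity, g$labels, size = 10,
                                       reps = 3, seed = 92)
  expect_identical(i1, i2)
})
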