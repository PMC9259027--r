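make_cube <- function(values_by_trial) {
  # 1 neuron x trials x 1 bin from a plain vector
  array(values_by_trial, dim = c(1, length(values_by_trial), 1))
}

test_that("auROC reproduces hand-computable cases", {
  lab <- c(rep(FALSE, 3), rep(TRUE, 3))
  expect_equal(auroc_per_bin(make_cube(c(1, 2, 3, 4, 5, 6)), lab)[1, 1], 1)
  expect_equal(auroc_per_bin(make_cube(c(4, 5, 6, 1, 2, 3)), lab)[1, 1], 0)
  expect_equal(auroc_per_bin(make_cube(c(1, 2, 3, 1, 2, 3)), lab)[1, 1], 0.5)
  # L = {1,3}, R = {2,4}: 3 of 4 pairs won, 0 ties -> 0.75
  expect_equal(auroc_per_bin(make_cube(c(1, 3, 2, 4)),
                             c(FALSE, FALSE, TRUE, TRUE))[1, 1], 0.75)
})

test_that("auROC agrees exactly with the all-pairs oracle on random small instances", {
  withr::with_seed(61, {
    for (i in 1:300) {
      n1 <- sample(2:6, 1)
      n0 <- sample(2:6, 1)
      # integer-valued data so ties actually occur
      vals <- sample(0:4, n1 + n0, replace = TRUE)
      lab <- c(rep(TRUE, n1), rep(FALSE, n0))
      expect_identical(auroc_per_bin(make_cube(vals), lab)[1, 1],
                       oracle_auroc(vals[lab], vals[!lab]))
    }
  })
})

test_that("label swap maps auROC to its complement; selectivity is invariant", {
  withr::with_seed(62, {
    act <- array(rnorm(5 * 20 * 4), dim = c(5, 20, 4))
    lab <- rep(c(TRUE, FALSE), 10)
  })
  a1 <- auroc_per_bin(act, lab)
  a2 <- auroc_per_bin(act, !lab)
  expect_equal(a2, 1 - a1)
  expect_equal(selectivity_index(a1), selectivity_index(a2))
})

test_that("selectivity index is the unsigned deviation from chance", {
  expect_equal(selectivity_index(0.5), 0)
  expect_equal(selectivity_index(1), 1)
  expect_equal(selectivity_index(0), 1)
  expect_equal(selectivity_index(0.75), 0.5)
  expect_error(selectivity_index(1.2), "\\[0, 1\\]")
})

test_that("permutation test flags a noiseless selective neuron and spares a constant one", {
  n <- 30
  lab <- rep(c(FALSE, TRUE), each = n)
  act <- array(0, dim = c(2, 2 * n, 3))
  act[1, lab, ] <- 1                      # perfectly selective everywhere
  act[2, , ] <- 7                         # constant
  prof <- shuffle_significance(act, lab, n_shuffles = 100, seed = 63)
  expect_true(all(prof$significant[1, ]))
  expect_equal(prof$p[2, ], rep(1, 3))
  expect_false(any(prof$significant[2, ]))
  # add-one estimator: p can never be zero and lives in (0, 1]
  expect_true(all(prof$p > 0 & prof$p <= 1))
  expect_equal(min(prof$p), 1 / 101)
})

test_that("permutation p-values are reproducible and respect the shuffle count", {
  withr::with_seed(64, act <- array(rnorm(4 * 20 * 2), dim = c(4, 20, 2)))
  lab <- rep(c(TRUE, FALSE), each = 10)
  p1 <- shuffle_significance(act, lab, seed = 65)
  p2 <- shuffle_significance(act, lab, seed = 65)
  expect_identical(p1, p2)
  p3 <- shuffle_significance(act, lab, n_shuffles = 19, seed = 65)
  expect_true(all(p3$p >= 1 / 20))
})

test_that("segment summaries match direct arithmetic on a 3-neuron toy", {
  # 2 bins per segment over [15, 220); centers at 17.5 + 5k
  edges <- seq(15, 220, length.out = 9)   # 8 bins, uniform
  nb <- 8
  act <- array(0, dim = c(3, 4, nb))
  act[1, , ] <- 1
  act[2, , ] <- matrix(rep(1:nb, each = 4), 4, nb)   # bin index as activity
  act[3, , ] <- 0
  meta <- data.frame(cue = rep(c("horizontal", "vertical"), 2),
                     choice = rep(c("left", "right"), 2))
  ba <- binned_activity(act, c("PPC", "PPC", "V1"), edges, meta)
  centers <- bin_centers(ba)
  segs <- segment_spec()
  prof <- structure(
    list(auroc = matrix(0.5, 3, nb),
         selectivity = matrix(rep(c(0, 0.4, 1), nb), 3, nb),
         p = matrix(1, 3, nb),
         significant = rbind(rep(FALSE, nb), rep(TRUE, nb),
                             c(rep(TRUE, 4), rep(FALSE, 4))),
         alpha = 0.01, n_shuffles = 100, area = ba$area, bin_edges = edges),
    class = "selectivity_profile")
  sm <- segment_summaries(ba, prof, segs)
  for (sg in segs$segment) {
    bins <- which(centers >= segs$lo[segs$segment == sg] &
                    centers < segs$hi[segs$segment == sg])
    pn <- sm$per_neuron[sm$per_neuron$segment == sg, ]
    expect_equal(pn$mean_activity[pn$neuron == 1], 1)
    expect_equal(pn$mean_activity[pn$neuron == 2], mean(bins))
    expect_equal(pn$mean_selectivity, c(0, 0.4, 1))
    pa <- sm$per_area[sm$per_area$segment == sg, ]
    # PPC: neurons 1 (never) and 2 (always) -> fraction 0.5 in every segment
    expect_equal(pa$fraction_selective[pa$area == "PPC"], 0.5)
    # V1: neuron 3 significant only in bins 1-4
    expect_equal(pa$fraction_selective[pa$area == "V1"],
                 mean(bins %in% 1:4))
  }
  bad_seg <- data.frame(segment = "nowhere", lo = 500, hi = 600)
  expect_error(segment_summaries(ba, prof, bad_seg), "no bins")
})

test_that("selectivity in the arms only leaves stem segments at zero", {
  edges <- seq(0, 230, by = 5)
  nb <- 46
  centers <- (edges[-1] + edges[-47]) / 2
  arms <- centers >= 150 & centers < 220
  prof <- structure(
    list(auroc = matrix(0.5, 2, nb),
         selectivity = matrix(rep(as.numeric(arms), each = 2), 2, nb),
         p = matrix(1, 2, nb), significant = matrix(FALSE, 2, nb),
         alpha = 0.01, n_shuffles = 100, area = c("RSC", "RSC"),
         bin_edges = edges),
    class = "selectivity_profile")
  meta <- data.frame(cue = rep(c("horizontal", "vertical"), 2),
                     choice = rep(c("left", "right"), 2))
  ba <- binned_activity(array(0, dim = c(2, 4, nb)), c("RSC", "RSC"), edges, meta)
  sm <- segment_summaries(ba, prof)
  pn <- sm$per_neuron
  expect_true(all(pn$mean_selectivity[pn$segment != "arms"] == 0))
  expect_true(all(pn$mean_selectivity[pn$segment == "arms"] == 1))
})

test_that("four-trial-type categorization recovers built-in cell classes", {
  # construct 4-type sessions: rules A/B x cues h/v, 20 trials each
  n_t <- 20
  meta <- data.frame(
    rule = rep(c("A", "B"), each = 2 * n_t),
    cue = rep(c("horizontal", "vertical", "horizontal", "vertical"),
              each = n_t),
    stringsAsFactors = FALSE
  )
  meta$choice <- ifelse(meta$rule == "A",
                        ifelse(meta$cue == "horizontal", "left", "right"),
                        ifelse(meta$cue == "horizontal", "right", "left"))
  meta$correct <- TRUE
  nb <- 8
  withr::with_seed(66, {
    act <- array(rnorm(4 * nrow(meta) * nb, sd = 0.2),
                 dim = c(4, nrow(meta), nb))
  })
  boost <- 3
  # neuron 1: single trial type (horizontal cue under Rule A only)
  sel1 <- meta$rule == "A" & meta$cue == "horizontal"
  act[1, sel1, 1:4] <- act[1, sel1, 1:4] + boost
  # neuron 2: choice cell (left choice under both rules)
  sel2 <- meta$choice == "left"
  act[2, sel2, 1:4] <- act[2, sel2, 1:4] + boost
  # neuron 3: cue cell (horizontal cue under both rules -> opposite choices)
  sel3 <- meta$cue == "horizontal"
  act[3, sel3, 1:4] <- act[3, sel3, 1:4] + boost
  # neuron 4: untuned
  ba <- binned_activity(act, rep("PPC", 4),
                        seq(0, by = 5, length.out = nb + 1), meta)
  res <- categorize_across_rules(ba, n_per_type = 15, seed = 67)
  expect_equal(res$category, c("single_trial_type", "choice", "cue", "none"))
  expect_equal(res$direction_A[2], "left")
  expect_equal(res$direction_B[2], "left")
  expect_equal(res$direction_A[3], "left")   # horizontal -> left under Rule A
  expect_equal(res$direction_B[3], "right")  # horizontal -> right under Rule B
})
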