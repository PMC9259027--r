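# End-to-end orchestration: simulate two synthetic cohorts and run the
# selectivity / decoding / correlation / bootstrap chain on each.

#' Configuration for an end-to-end synthetic experiment
#'
#' Two cohorts are simulated that differ only in the generator parameters
#' listed under `cohorts` (by default a "simple-only" cohort and a
#' "switching-experience" cohort with higher trial-type selectivity and a
#' weaker shared noise source, the pattern expected from complex-task
#' experience). All other stages — high-performance trial filtering, trial
#' subsampling, selectivity with permutation nulls, subsampled decoding,
#' noise correlations, disruption, and hierarchical bootstrap — are
#' identical across cohorts.
#'
#' @param seed Root seed; every stochastic stage receives a seed derived
#'   deterministically from it.
#' @param out_dir Output directory for CSV/JSON summaries, or `NULL` to
#'   skip writing.
#' @param n_sessions Sessions per cohort.
#' @param n_trials Trials per simulated session.
#' @param p_correct Agent accuracy.
#' @param cohorts Named list of generator-parameter overrides per cohort.
#' @param neural Baseline [neural_gen_config()] shared by both cohorts.
#' @param n_per_type Trials per type after subsampling (default 30).
#' @param sizes Decoding population sizes.
#' @param decode_bins Spatial-bin indices used for decoding (a subset keeps
#'   runtime moderate; selectivity always uses all bins).
#' @param reps Decoding repetitions per size (`NULL` = default schedule).
#' @param n_shuffles,alpha Permutation-test parameters.
#' @param n_boot Bootstrap resamples.
#' @param disruption_size Population size for the correlation-disruption
#'   decoding comparison.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = NULL,
                       n_sessions = 2L, n_trials = 260L, p_correct = 0.9,
                       cohorts = list(
                         simple = list(selectivity_strength = 0.3,
                                       shared_noise_loading = 0.35),
                         switching = list(selectivity_strength = 0.8,
                                          shared_noise_loading = 0.15)),
                       neural = neural_gen_config(
                         n_neurons_per_area = c(V1 = 40L, PPC = 40L, RSC = 40L)),
                       n_per_type = 30L, sizes = c(5, 10, 25),
                       decode_bins = seq(1L, 46L, by = 4L), reps = 10L,
                       n_shuffles = 100L, alpha = 0.01, n_boot = 500L,
                       disruption_size = 25L) {
  stopifnot(length(cohorts) == 2L, !is.null(names(cohorts)))
  structure(as.list(environment()), class = "run_config")
}

cohort_neural_config <- function(base, overrides) {
  args <- unclass(base)
  args[names(overrides)] <- overrides
  do.call(neural_gen_config, args)
}

simulate_analyzed_session <- function(cfg, cohort_name, overrides, s_idx, seed0) {
  beh <- simulate_task_session(
    task_config("simple", n_trials = cfg$n_trials),
    agent_config(p_correct = cfg$p_correct),
    seed = derive_seed(seed0, "behavior", s_idx),
    session_id = sprintf("%s_s%02d", cohort_name, s_idx),
    mouse_id = sprintf("%s_m%d", cohort_name, (s_idx - 1L) %/% 2L + 1L))
  hp <- select_high_performance_trials(beh)
  types_hp <- trial_types(beh[hp, , drop = FALSE])
  keep <- hp[subsample_trials(types_hp, cfg$n_per_type,
                              seed = derive_seed(seed0, "subsample", s_idx))]
  ncfg <- cohort_neural_config(cfg$neural, overrides)
  gen <- generate_population_activity(beh[keep, , drop = FALSE], ncfg,
                                      seed = derive_seed(seed0, "population", s_idx))
  act <- gen$activity
  labels <- trial_types(act)

  prof <- shuffle_significance(act, labels, n_shuffles = cfg$n_shuffles,
                               alpha = cfg$alpha,
                               seed = derive_seed(seed0, "shuffle", s_idx))
  seg <- segment_summaries(act, prof)
  dec <- decode_trial_type(act, labels, sizes = cfg$sizes, reps = cfg$reps,
                           bins = cfg$decode_bins,
                           seed = derive_seed(seed0, "decoding", s_idx))
  nc <- suppressMessages(noise_correlations(act, labels))
  imp <- correlation_impact_on_decoding(act, labels, size = cfg$disruption_size,
                                        reps = cfg$reps, bins = cfg$decode_bins,
                                        seed = derive_seed(seed0, "disruption", s_idx))
  session_id <- beh$session_id[1]
  list(
    selectivity = data.frame(cohort = cohort_name, session = session_id,
                             neuron = seq_len(n_neurons(act)), area = act$area,
                             mean_selectivity = rowMeans(prof$selectivity),
                             frac_sig_bins = rowMeans(prof$significant)),
    segments = cbind(cohort = cohort_name, session = session_id, seg$per_area),
    decoding = data.frame(cohort = cohort_name, session = session_id,
                          size = dec$sizes, accuracy = dec$accuracy),
    correlations = cbind(cohort = cohort_name, session = session_id,
                         nc$area_pair_means),
    mean_r = data.frame(cohort = cohort_name, session = session_id,
                        mean_r = nc$mean_r),
    disruption = data.frame(cohort = cohort_name, session = session_id,
                            size = cfg$disruption_size, delta = imp$delta,
                            intact = imp$intact, disrupted = imp$disrupted)
  )
}

#' Run the full synthetic-cohort experiment
#'
#' Simulates the two configured cohorts, runs the complete analysis chain
#' on each session (high-performance filtering, subsampling, auROC
#' selectivity with permutation significance, segment summaries, subsampled
#' linear decoding, noise correlations and disruption), and compares the
#' cohorts with hierarchical bootstrap (sessions, then neurons, for
#' selectivity; sessions for mean noise correlation). When `out_dir` is
#' set, tidy CSV summaries and a manifest (configuration echo plus root
#' seed) are written; repeated runs with the same config are byte-identical.
#'
#' @param config A [run_config()].
#' @return A list of class `experiment_report` with tidy data frames
#'   (`selectivity`, `segments`, `decoding`, `correlations`, `disruption`)
#'   and `comparisons` (bootstrap estimates and p-values per cohort
#'   contrast).
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort_names <- names(config$cohorts)
  parts <- list()
  for (ci in seq_along(config$cohorts)) {
    seed0 <- derive_seed(config$seed, if (ci == 1L) "cohort_a" else "cohort_b")
    for (s in seq_len(config$n_sessions)) {
      parts[[length(parts) + 1L]] <-
        simulate_analyzed_session(config, cohort_names[ci],
                                  config$cohorts[[ci]], s, seed0)
    }
  }
  bind <- function(name) do.call(rbind, lapply(parts, `[[`, name))
  report <- list(
    selectivity = bind("selectivity"), segments = bind("segments"),
    decoding = bind("decoding"), correlations = bind("correlations"),
    mean_r = bind("mean_r"), disruption = bind("disruption")
  )

  boot_sel <- lapply(seq_along(cohort_names), function(ci) {
    dat <- report$selectivity[report$selectivity$cohort == cohort_names[ci], ]
    hierarchical_bootstrap(dat, "mean_selectivity", levels = "session",
                           n_boot = config$n_boot,
                           seed = derive_seed(config$seed, "bootstrap", ci),
                           statistic_name = paste0("mean_selectivity_",
                                                   cohort_names[ci]))
  })
  boot_r <- lapply(seq_along(cohort_names), function(ci) {
    dat <- report$mean_r[report$mean_r$cohort == cohort_names[ci], ]
    hierarchical_bootstrap(dat, "mean_r",
                           n_boot = config$n_boot,
                           seed = derive_seed(config$seed, "bootstrap", 10L + ci),
                           statistic_name = paste0("mean_r_", cohort_names[ci]))
  })
  report$comparisons <- data.frame(
    statistic = c("mean_selectivity", "mean_noise_correlation"),
    estimate_1 = c(boot_sel[[1]]$point_estimate, boot_r[[1]]$point_estimate),
    estimate_2 = c(boot_sel[[2]]$point_estimate, boot_r[[2]]$point_estimate),
    sem_1 = c(boot_sel[[1]]$sem, boot_r[[1]]$sem),
    sem_2 = c(boot_sel[[2]]$sem, boot_r[[2]]$sem),
    p = c(bootstrap_p(boot_sel[[1]], boot_sel[[2]]),
          bootstrap_p(boot_r[[1]], boot_r[[2]]))
  )
  names(report$comparisons)[2:5] <- c(
    paste0("estimate_", cohort_names), paste0("sem_", cohort_names))
  class(report) <- "experiment_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("selectivity", "segments", "decoding", "correlations",
                 "mean_r", "disruption", "comparisons"))
      write.csv(report[[nm]], file.path(config$out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    manifest <- unclass(config)
    manifest$out_dir <- NULL   # location-independent: results are a function
    manifest$neural <- unclass(manifest$neural)  # of config + seed only
    manifest$package_version <- as.character(utils::packageVersion("ymazepop"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat("cohort comparisons:\n")
  print(x$comparisons, digits = 3)
  invisible(x)
}
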