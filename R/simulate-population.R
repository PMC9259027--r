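#' Configuration for the synthetic population-activity generator
#'
#' Parameters of the generative model for deconvolved-like, spatially binned
#' population activity. Each neuron has a Gaussian spatial tuning bump at a
#' uniformly drawn preferred bin (so neurons tile the maze as an activity
#' sequence). A fraction of neurons is selective: their bump amplitude is
#' increased by `selectivity_strength` on trials of their preferred label
#' level. Trial-to-trial covariability is induced by a shared latent: on
#' trial `t` a standard-normal scalar `z_t` enters every neuron's activity
#' scaled by its loading, plus private Gaussian noise of sd
#' `private_noise_sd`. For unit-loading pairs the expected (pre-clipping)
#' pairwise noise correlation is `lambda^2 / (lambda^2 + sigma^2)`.
#'
#' @param n_neurons_per_area Named integer vector, neurons per area.
#' @param n_bins Number of 5-cm spatial bins (46 for the 230-cm imaging maze).
#' @param bin_size Bin width in cm.
#' @param tuning_width_bins Gaussian tuning width (sd) in bins.
#' @param peak_rate Bump amplitude on nonpreferred trials (event units).
#' @param baseline_rate Additive baseline event rate.
#' @param selectivity_strength Amplitude increase on preferred-type trials.
#' @param fraction_selective Fraction of neurons that are selective.
#' @param shared_noise_loading Shared-latent loading magnitude `lambda`.
#' @param private_noise_sd Private noise sd `sigma`.
#' @param selectivity_mode Which label the selectivity boost keys on:
#'   `"trial_type"` (cue x choice combination), `"cue"`, or `"choice"`.
#' @param shared_noise_mode `"global"` (one latent, uniform positive
#'   loadings), `"signal_aligned"` (loadings signed by each neuron's
#'   selectivity direction, producing information-limiting correlations), or
#'   `"per_area"` (independent latent per area).
#' @param clip Clip activity at zero (deconvolved activity is nonnegative).
#'   Closed-form correlation checks use `clip = FALSE`.
#' @return An object of class `neural_gen_config`.
#' @export
neural_gen_config <- function(n_neurons_per_area = c(V1 = 100L, PPC = 100L, RSC = 100L),
                              n_bins = 46L,
                              bin_size = 5,
                              tuning_width_bins = 3,
                              peak_rate = 1,
                              baseline_rate = 0.05,
                              selectivity_strength = 0.5,
                              fraction_selective = 0.4,
                              shared_noise_loading = 0.23,
                              private_noise_sd = 1,
                              selectivity_mode = c("trial_type", "cue", "choice"),
                              shared_noise_mode = c("global", "signal_aligned", "per_area"),
                              clip = TRUE) {
  if (is.null(names(n_neurons_per_area)) || any(n_neurons_per_area <= 0))
    stop("`n_neurons_per_area` must be a named vector of positive counts",
         call. = FALSE)
  n_bins <- assert_count(n_bins, "n_bins")
  assert_probability(fraction_selective, "fraction_selective")
  if (tuning_width_bins <= 0) stop("`tuning_width_bins` must be positive", call. = FALSE)
  if (selectivity_strength < 0) stop("`selectivity_strength` must be nonnegative", call. = FALSE)
  if (shared_noise_loading < 0) stop("`shared_noise_loading` must be nonnegative", call. = FALSE)
  if (private_noise_sd <= 0) stop("`private_noise_sd` must be positive", call. = FALSE)
  structure(
    list(n_neurons_per_area = n_neurons_per_area, n_bins = n_bins,
         bin_size = bin_size, tuning_width_bins = tuning_width_bins,
         peak_rate = peak_rate, baseline_rate = baseline_rate,
         selectivity_strength = selectivity_strength,
         fraction_selective = fraction_selective,
         shared_noise_loading = shared_noise_loading,
         private_noise_sd = private_noise_sd,
         selectivity_mode = match.arg(selectivity_mode),
         shared_noise_mode = match.arg(shared_noise_mode),
         clip = isTRUE(clip)),
    class = "neural_gen_config"
  )
}

#' Generate synthetic population activity for a behavioral session
#'
#' Draws per-neuron tuning (preferred bin, selectivity, preferred label
#' level, latent loading) and per-trial activity under the model described
#' in [neural_gen_config()], returning the binned activity together with the
#' ground truth needed for parameter-recovery tests.
#'
#' @param behavior A `session_behavior` data frame (or any data frame with
#'   `cue` and `choice` columns); every trial becomes one slice of the
#'   activity array.
#' @param cfg A [neural_gen_config()].
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return A list with elements `activity` (a [binned_activity()]) and
#'   `truth`, a data frame with per-neuron `neuron`, `area`, `is_selective`,
#'   `preferred_type`, `preferred_bin`, `loading`, plus attribute
#'   `expected_noise_correlation` = lambda^2 / (lambda^2 + sigma^2), the
#'   closed-form pre-clipping pairwise noise correlation for unit-loading
#'   pairs.
#' @export
generate_population_activity <- function(behavior, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "neural_gen_config"))
  local_seed(seed)

  meta <- as.data.frame(behavior)
  n_tr <- nrow(meta)
  grouping <- switch(cfg$selectivity_mode,
    trial_type = droplevels(interaction(meta$cue, meta$choice, drop = TRUE)),
    cue = factor(meta$cue),
    choice = factor(meta$choice)
  )
  counts <- table(grouping)
  if (any(counts < 2L))
    stop("need at least 2 trials of each trial type; deficient: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)

  area <- rep(names(cfg$n_neurons_per_area), cfg$n_neurons_per_area)
  n_nrn <- length(area)
  nb <- cfg$n_bins

  preferred_bin <- sample.int(nb, n_nrn, replace = TRUE)
  is_selective <- runif(n_nrn) < cfg$fraction_selective
  type_levels <- levels(grouping)
  preferred_type <- ifelse(is_selective,
                           sample(type_levels, n_nrn, replace = TRUE),
                           NA_character_)

  # selectivity direction used for signal-aligned loadings: +1 for neurons
  # preferring the last factor level, -1 otherwise; nonselective neurons get
  # a random sign so loading magnitudes stay comparable
  dir_sign <- ifelse(is_selective,
                     ifelse(preferred_type == type_levels[length(type_levels)], 1, -1),
                     sample(c(-1, 1), n_nrn, replace = TRUE))
  loading <- switch(cfg$shared_noise_mode,
    global = rep(cfg$shared_noise_loading, n_nrn),
    per_area = rep(cfg$shared_noise_loading, n_nrn),
    signal_aligned = cfg$shared_noise_loading * dir_sign
  )

  bump <- exp(-0.5 * ((matrix(seq_len(nb), n_nrn, nb, byrow = TRUE) - preferred_bin) /
                        cfg$tuning_width_bins)^2)   # neurons x bins

  boost <- matrix(0, n_nrn, n_tr)                   # neurons x trials
  sel_idx <- which(is_selective)
  if (length(sel_idx))
    boost[sel_idx, ] <- cfg$selectivity_strength *
      outer(preferred_type[sel_idx], as.character(grouping), `==`)

  z <- switch(cfg$shared_noise_mode,
    global = ,
    signal_aligned = matrix(rnorm(n_tr), n_nrn, n_tr, byrow = TRUE),
    per_area = {
      za <- vapply(unique(area), function(a) rnorm(n_tr), numeric(n_tr))
      t(za)[match(area, unique(area)), , drop = FALSE]
    }
  )
  shared <- loading * z                              # neurons x trials

  act <- array(0, dim = c(n_nrn, n_tr, nb))
  for (b in seq_len(nb)) {
    mu <- cfg$baseline_rate + (cfg$peak_rate + boost) * bump[, b]
    act[, , b] <- mu + shared +
      matrix(rnorm(n_nrn * n_tr, sd = cfg$private_noise_sd), n_nrn, n_tr)
  }
  if (cfg$clip) act <- pmax(act, 0)

  truth <- data.frame(
    neuron = seq_len(n_nrn), area = area, is_selective = is_selective,
    preferred_type = preferred_type, preferred_bin = preferred_bin,
    loading = loading, stringsAsFactors = FALSE
  )
  lam2 <- cfg$shared_noise_loading^2
  attr(truth, "expected_noise_correlation") <-
    lam2 / (lam2 + cfg$private_noise_sd^2)

  edges <- seq(0, by = cfg$bin_size, length.out = nb + 1L)
  list(activity = binned_activity(act, area, edges, meta), truth = truth)
}
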