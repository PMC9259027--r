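#' Simulate running kinematics for a session
#'
#' Produces per-trial, per-spatial-bin treadmill velocities (pitch, roll,
#' yaw) and lateral maze position with a configurable left/right divergence.
#' At bin `b`, the mean lateral position of right-choice trials exceeds that
#' of left-choice trials by `divergence_profile[b]` (each side is offset by
#' half the divergence); yaw follows the same profile scaled by `yaw_gain`,
#' since turning drives lateral displacement. Pitch carries a constant
#' forward-running baseline and roll is pure noise. All four channels carry
#' additive Gaussian noise of standard deviation `noise_sd`.
#'
#' @param behavior A `session_behavior` data frame (its `choice` column sets
#'   the divergence sign: right = positive).
#' @param divergence_profile Numeric vector, one divergence value per bin
#'   (maze-width units).
#' @param noise_sd Standard deviation of the additive noise on each channel.
#' @param seed Integer seed.
#' @param bin_size Bin width in cm (used only to construct `bin_edges`).
#' @param yaw_gain Scale factor from lateral divergence to yaw velocity.
#' @param base_pitch Mean pitch (forward) velocity, arbitrary units.
#' @return An object of class `running_trace`: list of matrices
#'   `pitch`, `roll`, `yaw`, `lateral` (each trials x bins), `bin_edges`,
#'   and the trial `choice` vector.
#' @export
simulate_running <- function(behavior, divergence_profile, noise_sd = 1,
                             seed = NULL, bin_size = 5, yaw_gain = 0.5,
                             base_pitch = 20) {
  if (!is.numeric(divergence_profile) || length(divergence_profile) < 1L)
    stop("`divergence_profile` must be a numeric vector", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be nonnegative", call. = FALSE)
  local_seed(seed)

  n_trials <- nrow(behavior)
  n_bins <- length(divergence_profile)
  sign_t <- ifelse(behavior$choice == "right", 1, -1)
  div <- outer(sign_t, divergence_profile / 2)   # trials x bins

  noise <- function() matrix(rnorm(n_trials * n_bins, sd = noise_sd),
                             n_trials, n_bins)
  structure(
    list(
      pitch = base_pitch + noise(),
      roll = noise(),
      yaw = yaw_gain * 2 * div + noise(),
      lateral = div + noise(),
      bin_edges = seq(0, by = bin_size, length.out = n_bins + 1L),
      choice = behavior$choice
    ),
    class = "running_trace"
  )
}
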