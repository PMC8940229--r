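# Configuration objects for the task, subjects, and the signal simulator.

#' Go/No-Go task configuration
#'
#' @param n_trials trials per run (default 49).
#' @param nogo_go_ratio integer pair `c(nogo, go)` giving the No-Go:Go count
#'   ratio (default `c(1, 6)`).
#' @param cue_duration cue display time in seconds; responses within this
#'   window count as reactions.
#' @param iti_mean mean intertrial interval in seconds.
#' @param iti_jitter_halfwidth half-width of the uniform ITI jitter in
#'   seconds; ITIs are drawn from
#'   `[iti_mean - halfwidth, iti_mean + halfwidth]`.
#' @param allow_rounding if `TRUE`, a ratio that does not divide `n_trials`
#'   exactly is rounded (No-Go count = `round(n_trials * nogo/(nogo+go))`);
#'   if `FALSE` (default) such a configuration is an error.
#' @return a `task_config` list.
#' @export
task_config <- function(n_trials = 49L,
                        nogo_go_ratio = c(1L, 6L),
                        cue_duration = 1,
                        iti_mean = 1,
                        iti_jitter_halfwidth = 0.25,
                        allow_rounding = FALSE) {
  stopifnot(n_trials > 0, length(nogo_go_ratio) == 2L,
            all(nogo_go_ratio > 0), cue_duration > 0)
  if (iti_mean - iti_jitter_halfwidth <= 0)
    stop("iti_mean - iti_jitter_halfwidth must be positive")
  structure(list(
    n_trials = as.integer(n_trials),
    nogo_go_ratio = as.integer(nogo_go_ratio),
    cue_duration = cue_duration,
    iti_mean = iti_mean,
    iti_jitter_halfwidth = iti_jitter_halfwidth,
    allow_rounding = isTRUE(allow_rounding)
  ), class = "task_config")
}

#' Subject profile
#'
#' @param subject_id label.
#' @param age age in years.
#' @param grid_side hemisphere carrying the electrode grid, `"left"` or
#'   `"right"`; only that hemisphere's channels exist.
#' @param hands_tested character vector, subset of `c("left", "right")`.
#' @param behavioral_accuracy probability of a correct response; either a
#'   single value applied to both cue types or a named vector
#'   `c(go = , nogo = )`.
#' @return a `subject_profile` list.
#' @export
subject_profile <- function(subject_id, age,
                            grid_side = c("right", "left"),
                            hands_tested = "right",
                            behavioral_accuracy = 0.9) {
  grid_side <- match.arg(grid_side)
  stopifnot(age > 0, all(hands_tested %in% c("left", "right")))
  acc <- behavioral_accuracy
  if (length(acc) == 1L && is.null(names(acc))) acc <- c(go = unname(acc), nogo = unname(acc))
  if (!all(c("go", "nogo") %in% names(acc)))
    stop("behavioral_accuracy must be a single value or c(go=, nogo=)")
  if (any(acc < 0 | acc > 1)) stop("behavioral_accuracy must lie in [0, 1]")
  structure(list(
    subject_id = as.character(subject_id),
    age = age,
    grid_side = grid_side,
    hands_tested = hands_tested,
    behavioral_accuracy = acc[c("go", "nogo")]
  ), class = "subject_profile")
}

#' Default channel metadata for a 2 x 8 strip
#'
#' Sixteen channels on the grid hemisphere: two inferior-frontal (IFG),
#' two motor, the rest unlabeled cortex.
#'
#' @param n_channels total channel count (>= 4 when both ROIs requested).
#' @param grid_side `"left"` or `"right"`.
#' @return data.frame with columns `channel`, `label`, `roi`, `hemisphere`.
#' @export
default_channel_meta <- function(n_channels = 16L, grid_side = "right") {
  n_channels <- as.integer(n_channels)
  stopifnot(n_channels >= 4L)
  roi <- rep("other", n_channels)
  roi[c(3L, 4L)] <- "IFG"
  roi[c(7L, 8L)] <- "motor"
  data.frame(
    channel = seq_len(n_channels),
    label = sprintf("C%02d", seq_len(n_channels)),
    roi = roi,
    hemisphere = grid_side,
    stringsAsFactors = FALSE
  )
}

#' Signal-simulator configuration
#'
#' Defines the generative model for synthetic ECoG: a 1/f^alpha Gaussian
#' background with line noise, plus cue-locked injections. The designated
#' motor channel receives a high-gamma burst on responded Go trials
#' (contralateral hand only); the designated IFG channel receives
#' condition-dependent theta, beta, and high-gamma responses whose
#' high-gamma envelope is modulated by theta phase with condition-specific
#' depth. Injection amplitudes are expressed as multiples of the background
#' noise's own band-limited standard deviation, so "gain 2" means twice the
#' resting band amplitude. An age-dependent logistic laterality weight
#' shrinks the left-hemisphere No-Go excess toward the Go baseline.
#'
#' @param sampling_rate Hz (default 1200, the clinical acquisition rate).
#' @param n_channels channel count for [default_channel_meta()].
#' @param noise_exponent 1/f spectral exponent alpha.
#' @param noise_sd background standard deviation, microvolts.
#' @param line_noise_amplitudes named amplitudes (microvolts) of mains
#'   harmonics at 60/120/180 Hz.
#' @param hg_burst_gain_motor motor-burst gain (x resting HG SD).
#' @param band_gains_ifg list with elements `theta`, `beta`, `hg`, each a
#'   named pair `c(go=, nogo=)` of gains on the IFG channel.
#' @param pac_depth named pair `c(go=, nogo=)` of modulation depths m in
#'   `[0, 1]` for the theta-phase modulation of the IFG high-gamma
#'   envelope.
#' @param theta_freq injected theta frequency, Hz.
#' @param hg_carrier_band band of the injected high-gamma carrier, Hz.
#' @param laterality_age_center,laterality_age_slope parameters of the
#'   logistic laterality weight `w(age) = 1/(1+exp(-(age-center)/slope))`;
#'   `w` rises from 0 (bilateral) toward 1 (right-dominant) with age.
#' @param secondary_gain_frac fraction of the target-channel gain applied
#'   to the second electrode of the same ROI (spatial falloff).
#' @return a `sim_config` list.
#' @export
sim_config <- function(sampling_rate = 1200,
                       n_channels = 16L,
                       noise_exponent = 2,
                       noise_sd = 50,
                       line_noise_amplitudes = c("60" = 20, "120" = 5, "180" = 2),
                       hg_burst_gain_motor = 3,
                       band_gains_ifg = list(
                         theta = c(go = 1, nogo = 2),
                         beta  = c(go = 1, nogo = 2),
                         hg    = c(go = 1, nogo = 2)
                       ),
                       pac_depth = c(go = 0.2, nogo = 0.6),
                       theta_freq = 6,
                       hg_carrier_band = c(90, 130),
                       laterality_age_center = 12,
                       laterality_age_slope = 2,
                       secondary_gain_frac = 0.5) {
  stopifnot(sampling_rate > 0, all(pac_depth >= 0), all(pac_depth <= 1))
  for (b in c("theta", "beta", "hg")) {
    g <- band_gains_ifg[[b]]
    if (is.null(g) || !all(c("go", "nogo") %in% names(g)))
      stop("band_gains_ifg$", b, " must be a named pair c(go=, nogo=)")
  }
  if (!all(c("go", "nogo") %in% names(pac_depth)))
    stop("pac_depth must be a named pair c(go=, nogo=)")
  structure(list(
    sampling_rate = sampling_rate,
    n_channels = as.integer(n_channels),
    noise_exponent = noise_exponent,
    noise_sd = noise_sd,
    line_noise_amplitudes = line_noise_amplitudes,
    hg_burst_gain_motor = hg_burst_gain_motor,
    band_gains_ifg = band_gains_ifg,
    pac_depth = pac_depth[c("go", "nogo")],
    theta_freq = theta_freq,
    hg_carrier_band = hg_carrier_band,
    laterality_age_center = laterality_age_center,
    laterality_age_slope = laterality_age_slope,
    secondary_gain_frac = secondary_gain_frac
  ), class = "sim_config")
}

#' Age-dependent laterality weight
#'
#' Logistic map from age to the right-lateralization weight of the No-Go
#' effect: 0 means fully bilateral (left excess intact), 1 means fully
#' right-lateralized (left-hemisphere No-Go excess collapsed onto the Go
#' baseline). Non-decreasing in age.
#'
#' @param age years.
#' @param sim a [sim_config()].
#' @return weight in `[0, 1]`.
#' @export
laterality_weight <- function(age, sim = sim_config()) {
  1 / (1 + exp(-(age - sim$laterality_age_center) / sim$laterality_age_slope))
}
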