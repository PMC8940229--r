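# Synthetic Go/No-Go cohort generator: task schedules, behavior, and
# multichannel ECoG with known injected structure.

#' Generate a randomized Go/No-Go trial schedule
#'
#' Cue types are randomly ordered at the configured No-Go:Go ratio and
#' placed on the time axis with uniformly jittered intertrial intervals.
#'
#' @param task a [task_config()].
#' @param sampling_rate Hz, used to convert onset times to sample indices.
#' @param seed integer seed; identical seeds give identical schedules.
#' @param hand hand used for this run, `"left"` or `"right"`.
#' @param start_margin seconds of recording before the first cue.
#' @return data.frame (event table) with columns `trial`, `onset_s`,
#'   `onset_sample`, `cue_type` (`"go"`/`"nogo"`), `hand`, `iti_s`.
#' @export
generate_task_sequence <- function(task = task_config(),
                                   sampling_rate = 1200,
                                   seed = NULL,
                                   hand = "right",
                                   start_margin = 2) {
  r <- task$nogo_go_ratio
  n <- task$n_trials
  n_nogo_exact <- n * r[1] / (r[1] + r[2])
  if (n_nogo_exact != round(n_nogo_exact)) {
    if (!task$allow_rounding)
      stop("nogo_go_ratio ", r[1], ":", r[2], " does not divide n_trials = ",
           n, " exactly; set allow_rounding = TRUE to permit rounding")
    n_nogo <- as.integer(round(n_nogo_exact))
  } else {
    n_nogo <- as.integer(n_nogo_exact)
  }
  with_seed(seed, {
    cue <- sample(c(rep("nogo", n_nogo), rep("go", n - n_nogo)))
    iti <- stats::runif(n, task$iti_mean - task$iti_jitter_halfwidth,
                        task$iti_mean + task$iti_jitter_halfwidth)
    onset <- start_margin + cumsum(c(0, (task$cue_duration + iti)[-n]))
    data.frame(
      trial = seq_len(n),
      onset_s = onset,
      onset_sample = as.integer(round(onset * sampling_rate)) + 1L,
      cue_type = cue,
      hand = hand,
      iti_s = iti,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate behavioral responses for a trial schedule
#'
#' Each trial is marked correct with the profile's per-cue-type accuracy;
#' responded trials receive a reaction latency drawn from a truncated
#' normal (mean 0.45 s, SD 0.1 s, clipped to (0.15, 1) s). Outcomes are
#' labeled via [classify_trials()].
#'
#' @param events event table from [generate_task_sequence()].
#' @param profile a [subject_profile()].
#' @param seed integer seed.
#' @return the event table with added columns `response` (logical),
#'   `latency_s`, and `outcome`.
#' @export
simulate_behavior <- function(events, profile, seed = NULL) {
  stopifnot(is.data.frame(events), "cue_type" %in% names(events))
  acc <- profile$behavioral_accuracy
  with_seed(seed, {
    p_correct <- ifelse(events$cue_type == "go", acc["go"], acc["nogo"])
    correct <- stats::rbinom(nrow(events), 1L, p_correct) == 1L
    # correct Go and wrong No-Go trials carry a response
    response <- ifelse(events$cue_type == "go", correct, !correct)
    lat <- pmin(pmax(stats::rnorm(nrow(events), 0.45, 0.1), 0.15), 0.999)
    events$response <- response
    events$latency_s <- ifelse(response, lat, NA_real_)
    classify_trials(events)
  })
}

# Effective No-Go parameter after laterality shrinkage: the excess of the
# No-Go value over the Go value is scaled by (1 - w) on the left
# hemisphere and left intact on the right.
.lateralized_nogo <- function(go, nogo, hemisphere, w) {
  go <- unname(go); nogo <- unname(nogo)
  if (identical(hemisphere, "left")) go + (nogo - go) * (1 - w) else nogo
}

# Band-limited SD of a background trace (resting amplitude scale used to
# express injection gains).
.band_sd <- function(x, band, fs) {
  stats::sd(Re(fft_band_analytic(x, band, fs)))
}

#' Simulate one Go/No-Go ECoG session
#'
#' Builds a continuous multichannel recording: 1/f^alpha Gaussian
#' background plus mains harmonics on every channel, a cue-locked
#' high-gamma burst on the target motor channel for responded Go trials
#' when the tested hand is contralateral to the grid, and
#' condition-dependent theta/beta/high-gamma responses on the target IFG
#' channel, with the high-gamma envelope modulated by theta phase at the
#' condition's coupling depth. The second electrode of each ROI receives a
#' spatially attenuated copy (no coupling), emulating falloff across the
#' strip. Left-hemisphere No-Go excesses (band gains and coupling depth)
#' shrink with age according to the logistic laterality weight.
#'
#' @param profile a [subject_profile()].
#' @param task a [task_config()].
#' @param sim a [sim_config()].
#' @param seed integer seed; the session is fully determined by
#'   (profile, task, sim, seed).
#' @param hand hand used; defaults to the profile's first tested hand.
#' @param channels optional channel metadata data.frame (columns `channel`,
#'   `label`, `roi`, `hemisphere`); defaults to
#'   [default_channel_meta()] on the profile's grid side.
#' @return list with elements `session` (an `ecog_session`: `signal`
#'   channels x samples in microvolts, `fs`, `channels`, `events`) and
#'   `truth` (injected parameters: effective band gains, coupling depths,
#'   laterality weight, target channel indices, schedule).
#' @export
simulate_session <- function(profile, task = task_config(),
                             sim = sim_config(), seed = NULL,
                             hand = profile$hands_tested[1],
                             channels = NULL) {
  if (is.null(channels))
    channels <- default_channel_meta(sim$n_channels, profile$grid_side)
  if (!all(c("channel", "label", "roi", "hemisphere") %in% names(channels)))
    stop("channel metadata must have columns channel, label, roi, hemisphere")
  ifg_idx <- which(channels$roi == "IFG")
  mot_idx <- which(channels$roi == "motor")
  if (length(ifg_idx) == 0L || length(mot_idx) == 0L)
    stop("channel metadata must label at least one IFG and one motor channel")

  fs <- sim$sampling_rate
  with_seed(seed, {
    events <- generate_task_sequence(task, fs, seed = NULL, hand = hand)
    events <- simulate_behavior(events, profile, seed = NULL)

    n_samp <- max(events$onset_sample) + as.integer(round(2 * fs))
    nch <- nrow(channels)
    w <- laterality_weight(profile$age, sim)
    hemi <- channels$hemisphere[ifg_idx[1]]

    # effective (lateralized) injection parameters on the IFG side
    g <- lapply(sim$band_gains_ifg, function(gb) {
      c(go = unname(gb["go"]),
        nogo = .lateralized_nogo(gb["go"], gb["nogo"], hemi, w))
    })
    m_pac <- c(go = unname(sim$pac_depth["go"]),
               nogo = .lateralized_nogo(sim$pac_depth["go"],
                                        sim$pac_depth["nogo"], hemi, w))

    sig <- matrix(0, nrow = nch, ncol = n_samp)
    line_phase <- stats::runif(length(sim$line_noise_amplitudes), 0, 2 * pi)
    tt <- (seq_len(n_samp) - 1L) / fs
    for (c_i in seq_len(nch)) {
      x <- pink_noise(n_samp, fs, sim$noise_exponent, sim$noise_sd)
      for (k in seq_along(sim$line_noise_amplitudes)) {
        f0 <- as.numeric(names(sim$line_noise_amplitudes))[k]
        amp <- sim$line_noise_amplitudes[k] * stats::runif(1, 0.8, 1.2)
        x <- x + amp * sin(2 * pi * f0 * tt + line_phase[k] +
                             stats::runif(1, -0.3, 0.3))
      }
      sig[c_i, ] <- x
    }

    # resting band amplitude scales, measured on the first channel's
    # background (channels are exchangeable by construction)
    sd_theta <- .band_sd(sig[1, ], c(4, 8), fs)
    sd_beta <- .band_sd(sig[1, ], c(12, 40), fs)
    sd_hg <- .band_sd(sig[1, ], c(70, 200), fs)

    n_win <- as.integer(round(fs))          # 1 s response window
    ramp <- tukey_window(n_win, 0.2)
    t_win <- (seq_len(n_win) - 1L) / fs

    contra <- setdiff(c("left", "right"), hand)
    motor_active <- channels$hemisphere[mot_idx[1]] == contra

    add_ifg <- function(ch_scale, target) {
      for (tr in seq_len(nrow(events))) {
        cond <- events$cue_type[tr]
        idx <- events$onset_sample[tr] + seq_len(n_win) - 1L
        phi0 <- stats::runif(1, 0, 2 * pi)
        phase <- 2 * pi * sim$theta_freq * t_win + phi0
        theta <- sqrt(2) * g$theta[cond] * sd_theta * cos(phase)
        beta <- Re(fft_band_analytic(stats::rnorm(n_win), c(12, 40), fs))
        beta <- beta / stats::sd(beta) * g$beta[cond] * sd_beta
        carrier <- Re(fft_band_analytic(stats::rnorm(n_win),
                                        sim$hg_carrier_band, fs))
        carrier <- carrier / stats::sd(carrier)
        mdep <- if (target) m_pac[cond] else 0
        hg <- carrier * (1 + mdep * cos(phase))
        hg <- hg / stats::sd(hg) * g$hg[cond] * sd_hg
        sig[target_ch, idx] <<- sig[target_ch, idx] +
          ch_scale * ramp * (theta + beta + hg)
      }
    }
    # target IFG channel (full effect, with coupling)
    target_ch <- ifg_idx[1]
    add_ifg(1, TRUE)
    # secondary IFG channel (attenuated, no coupling)
    if (length(ifg_idx) > 1L) {
      target_ch <- ifg_idx[2]
      add_ifg(sim$secondary_gain_frac, FALSE)
    }

    # motor burst: responded Go trials, contralateral hand only
    if (motor_active) {
      b_len <- as.integer(round(0.5 * fs))
      b_ramp <- hann_window(b_len)
      go_resp <- which(events$cue_type == "go" & events$response)
      for (mi in seq_along(mot_idx)) {
        scale <- if (mi == 1L) 1 else sim$secondary_gain_frac
        for (tr in go_resp) {
          idx <- events$onset_sample[tr] + as.integer(round(0.05 * fs)) +
            seq_len(b_len) - 1L
          burst <- Re(fft_band_analytic(stats::rnorm(b_len), c(70, 200), fs))
          burst <- burst / stats::sd(burst) *
            sim$hg_burst_gain_motor * sd_hg * scale
          sig[mot_idx[mi], idx] <- sig[mot_idx[mi], idx] + b_ramp * burst
        }
      }
    }

    session <- new_ecog_session(sig, fs, channels, events)
    truth <- list(
      subject_id = profile$subject_id,
      age = profile$age,
      hand = hand,
      band_gains = g,
      pac_depth = m_pac,
      laterality_weight = w,
      ci_channel = ifg_idx[1],
      cm_channel = mot_idx[1],
      motor_active = motor_active,
      schedule = events
    )
    list(session = session, truth = truth)
  })
}

#' Default eight-subject synthetic cohort
#'
#' Subject profiles patterned on a pediatric epilepsy-monitoring cohort:
#' ages spanning 7-16 years, four right- and four left-sided grids, and
#' task accuracies in the 64-98% range.
#'
#' @param ages numeric vector of ages (one subject each).
#' @param grid_sides character vector of grid hemispheres.
#' @param accuracies behavioral accuracies.
#' @return list of [subject_profile()] objects.
#' @export
default_cohort <- function(ages = c(7, 8, 9, 11, 11, 12, 15, 16),
                           grid_sides = c("right", "left", "left", "right",
                                          "left", "right", "right", "left"),
                           accuracies = c(0.642, 0.939, 0.745, 0.959,
                                          0.750, 0.929, 0.663, 0.979)) {
  stopifnot(length(ages) == length(grid_sides),
            length(ages) == length(accuracies))
  lapply(seq_along(ages), function(i) {
    subject_profile(
      subject_id = sprintf("S%02d", i),
      age = ages[i],
      grid_side = grid_sides[i],
      hands_tested = setdiff(c("left", "right"), grid_sides[i]),
      behavioral_accuracy = accuracies[i]
    )
  })
}
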