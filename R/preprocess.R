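# Preprocessing: rereference, notch, band envelopes, epoching, baseline
# normalization.

#' Common-average rereference
#'
#' Subtracts the instantaneous mean across all grid channels from every
#' channel, so the per-sample channel mean of the output is zero.
#' Idempotent.
#'
#' @param session an `ecog_session` with at least two channels.
#' @return the rereferenced session.
#' @export
rereference_common_average <- function(session) {
  if (nrow(session$signal) < 2L)
    stop("common-average reference is undefined for a single-channel grid")
  session$signal <- sweep(session$signal, 2L, colMeans(session$signal))
  session
}

#' Notch out mains harmonics
#'
#' Second-order IIR notch per frequency (default quality factor 30),
#' applied forward-backward (zero phase) with reflect padding.
#'
#' @param session an `ecog_session`.
#' @param freqs notch frequencies in Hz; each must be below Nyquist.
#' @param q notch quality factor.
#' @return the filtered session.
#' @export
notch_line_noise <- function(session, freqs = c(60, 120, 180), q = 30) {
  nyq <- session$fs / 2
  if (any(freqs >= nyq))
    stop("notch frequency at or above Nyquist (", nyq, " Hz)")
  n <- ncol(session$signal)
  for (f0 in freqs) {
    filt <- notch_biquad(f0, session$fs, q)
    # pad past the notch settling time (~ q / (pi * f0) seconds)
    pad <- min(n - 1L, as.integer(ceiling(6 * q / (pi * f0) * session$fs)))
    for (ch in seq_len(nrow(session$signal)))
      session$signal[ch, ] <- zero_phase_filter(filt, session$signal[ch, ],
                                                pad = pad)
  }
  session
}

#' Band-limited Hilbert envelope of one channel
#'
#' Band-passes with a 4th-order zero-phase Butterworth filter and returns
#' the modulus of the analytic signal (instantaneous amplitude).
#'
#' @param x numeric vector (one channel).
#' @param band `c(low, high)` in Hz, inside `(0, fs/2)`.
#' @param fs sampling rate, Hz.
#' @param order Butterworth order (applied once per direction).
#' @return nonnegative numeric vector, `length(x)`.
#' @export
band_envelope <- function(x, band = c(70, 200), fs = 1200, order = 4) {
  if (length(band) != 2L || band[1] >= band[2])
    stop("band must be c(low, high) with low < high")
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band must lie strictly inside (0, Nyquist)")
  filt <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- zero_phase_filter(filt, x)
  Mod(analytic_signal(y))
}

#' Cut a session into cue-locked epochs
#'
#' One epoch per event over the half-open window `[window[1], window[2])`
#' seconds around the cue (cue sample belongs to the post-cue side).
#' Events without full window support are dropped with a warning.
#'
#' @param session an `ecog_session` with an event table.
#' @param window `c(pre, post)` seconds relative to the cue, default
#'   `c(-1, 1)`.
#' @param data optional channels x samples matrix to epoch in place of
#'   `session$signal` (e.g. a precomputed envelope); must share its
#'   dimensions.
#' @return an `ecog_epochs`: `data` (trials x channels x time), `time`
#'   (seconds, cue at 0), `fs`, `channels`, `labels` (per-trial
#'   `cue_type`, `outcome`, `response`, `hand`), `window`,
#'   `normalized = FALSE`.
#' @export
epoch_session <- function(session, window = c(-1, 1), data = NULL) {
  if (is.null(session$events)) stop("session carries no event table")
  if (is.null(data)) data <- session$signal
  stopifnot(all(dim(data) == dim(session$signal)))
  fs <- session$fs
  n_pre <- as.integer(round(-window[1] * fs))
  n_post <- as.integer(round(window[2] * fs))
  n_len <- n_pre + n_post
  ev <- session$events
  first <- ev$onset_sample - n_pre
  last <- ev$onset_sample + n_post - 1L
  keep <- first >= 1L & last <= ncol(data)
  if (!all(keep))
    warning(sum(!keep), " trial(s) dropped: cue too close to recording edge")
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no trial has full window support")
  arr <- array(NA_real_, dim = c(nrow(ev), nrow(data), n_len))
  for (i in seq_len(nrow(ev))) {
    idx <- (ev$onset_sample[i] - n_pre):(ev$onset_sample[i] + n_post - 1L)
    arr[i, , ] <- data[, idx]
  }
  labels <- ev[, intersect(c("trial", "cue_type", "outcome", "response",
                             "latency_s", "hand"), names(ev)), drop = FALSE]
  structure(list(
    data = arr,
    time = (seq_len(n_len) - n_pre - 1L) / fs,
    fs = fs,
    channels = session$channels,
    labels = labels,
    window = window,
    normalized = FALSE
  ), class = "ecog_epochs")
}

#' Z-normalize epochs to the pre-cue baseline
#'
#' Per channel, values become `(x - mu_b) / sigma_b` where `mu_b` and
#' `sigma_b` are the mean and SD of the baseline period (`time < 0`).
#' By default the baseline is pooled across all trials of the run, which
#' stabilizes `sigma_b` when one condition has few trials; per-trial
#' normalization is available behind `per_trial = TRUE`.
#'
#' @param epochs an `ecog_epochs` (not yet normalized).
#' @param per_trial normalize each trial against its own baseline.
#' @return the normalized `ecog_epochs` (`normalized = TRUE`).
#' @export
z_normalize_to_baseline <- function(epochs, per_trial = FALSE) {
  if (isTRUE(epochs$normalized)) stop("epochs are already normalized")
  b <- epochs$time < 0
  if (!any(b)) stop("no baseline samples (window starts at or after cue)")
  d <- epochs$data
  if (per_trial) {
    for (tr in seq_len(dim(d)[1])) for (ch in seq_len(dim(d)[2])) {
      base <- d[tr, ch, b]
      s <- stats::sd(base)
      if (s == 0) stop("degenerate baseline (zero variance) in trial ", tr,
                       ", channel ", ch)
      d[tr, ch, ] <- (d[tr, ch, ] - mean(base)) / s
    }
  } else {
    for (ch in seq_len(dim(d)[2])) {
      base <- as.vector(d[, ch, b])
      s <- stats::sd(base)
      if (s == 0) stop("degenerate baseline (zero variance) in channel ", ch)
      d[, ch, ] <- (d[, ch, ] - mean(base)) / s
    }
  }
  epochs$data <- d
  epochs$normalized <- TRUE
  epochs
}

#' Full preprocessing front end
#'
#' Common-average reference followed by mains notch filtering (the fixed
#' stage order of the pipeline).
#'
#' @param session an `ecog_session`.
#' @param notch_freqs mains harmonics to notch.
#' @param q notch quality factor.
#' @return the preprocessed session.
#' @export
preprocess_session <- function(session, notch_freqs = c(60, 120, 180),
                               q = 30) {
  notch_line_noise(rereference_common_average(session), notch_freqs, q)
}

#' High-gamma envelope epochs
#'
#' Convenience path of the activation-mapping stage: band-limited Hilbert
#' envelope per channel, epoched around cues and z-normalized to the
#' pooled pre-cue baseline.
#'
#' @param session a preprocessed `ecog_session`.
#' @param band envelope band in Hz (default high gamma, 70-200).
#' @param window epoch window in seconds.
#' @param per_trial per-trial baseline normalization flag.
#' @return a normalized `ecog_epochs` of envelopes.
#' @export
hg_envelope_epochs <- function(session, band = c(70, 200),
                               window = c(-1, 1), per_trial = FALSE) {
  env <- session$signal
  for (ch in seq_len(nrow(env)))
    env[ch, ] <- band_envelope(session$signal[ch, ], band, session$fs)
  z_normalize_to_baseline(epoch_session(session, window, data = env),
                          per_trial = per_trial)
}
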