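# Spectral power: Morlet event-related spectral perturbation, STFT band
# power peaks, and the No-Go/Go power ratio.

# Frequency-domain Morlet kernels (Gaussian of width f/n_cycles around
# each center frequency, positive-frequency side only).
.morlet_kernels <- function(freqs, m, fs, n_cycles) {
  faxis <- (seq_len(m) - 1L) * fs / m
  pos <- faxis <= fs / 2
  K <- matrix(0, nrow = m, ncol = length(freqs))
  for (j in seq_along(freqs)) {
    sf <- freqs[j] / n_cycles
    K[pos, j] <- exp(-0.5 * ((faxis[pos] - freqs[j]) / sf)^2)
  }
  K
}

#' Morlet-wavelet event-related spectral perturbation
#'
#' Time-frequency power of one electrode, computed per trial with
#' complex Morlet wavelets (default 6 cycles) at each center frequency,
#' z-normalized per frequency against the pooled pre-cue baseline of the
#' condition's correct trials, and averaged over those trials.
#'
#' @param epochs a raw (unnormalized signal) `ecog_epochs`.
#' @param channel electrode index (typically the selected Cm or Ci).
#' @param condition `"go"` or `"nogo"`; only correct trials enter.
#' @param freqs center frequencies in Hz (default 2-200 Hz every 3 Hz).
#' @param n_cycles wavelet width in cycles.
#' @return an `ersp_matrix` list: `power` (frequency x time, z units),
#'   `freqs`, `time`, `condition`, `n_trials`.
#' @export
morlet_ersp <- function(epochs, channel, condition = c("nogo", "go"),
                        freqs = seq(2, 200, by = 3), n_cycles = 6) {
  condition <- match.arg(condition)
  if (any(freqs >= epochs$fs / 2)) stop("wavelet frequency above Nyquist")
  trs <- which(epochs$labels$outcome == paste0(condition, "_correct"))
  if (length(trs) == 0L)
    stop("condition '", condition, "' has no correct trials")
  nt <- dim(epochs$data)[3]
  m <- stats::nextn(2L * nt, c(2, 3, 5))
  npad <- (m - nt) %/% 2L
  K <- .morlet_kernels(freqs, m, epochs$fs, n_cycles)
  pow <- array(NA_real_, dim = c(length(trs), length(freqs), nt))
  for (i in seq_along(trs)) {
    x <- epochs$data[trs[i], channel, ]
    xp <- .reflect_pad(x, npad, m - nt - npad)
    X <- stats::fft(xp)
    for (j in seq_along(freqs)) {
      cf <- stats::fft(X * K[, j], inverse = TRUE) / m
      pow[i, j, ] <- Mod(cf[(npad + 1L):(npad + nt)])^2
    }
  }
  b <- epochs$time < 0
  z <- matrix(NA_real_, length(freqs), nt)
  for (j in seq_along(freqs)) {
    base <- as.vector(pow[, j, b])
    mu <- mean(base); s <- stats::sd(base)
    if (s == 0) stop("degenerate baseline power at ", freqs[j], " Hz")
    # z-scoring single trials then averaging equals z-scoring the trial
    # mean, since the pooled (mu, s) are affine per frequency
    trial_mean <- colMeans(matrix(pow[, j, ], nrow = length(trs)))
    z[j, ] <- (trial_mean - mu) / s
  }
  structure(list(power = z, freqs = freqs, time = epochs$time,
                 condition = condition, n_trials = length(trs)),
            class = "ersp_matrix")
}

#' STFT band-power peaks per trial
#'
#' Short-time Fourier band power on one electrode with a Hann analysis
#' window (default 500 ms) advanced in 5 ms hops. The epoch is
#' reflect-padded by half a window so frame centers span the full epoch;
#' band power per frame is z-normalized against the pooled pre-cue
#' baseline frames of all trials, and the per-trial peak is the maximum
#' over post-cue frames.
#'
#' @param epochs a raw `ecog_epochs`.
#' @param channel electrode index.
#' @param bands named list of `c(low, high)` bands in Hz; defaults to
#'   theta 4-8, beta 12-40, high gamma 70-200.
#' @param window_s analysis window length, seconds.
#' @param hop_s hop between frames, seconds.
#' @param post_window `c(start, end)` seconds, half-open, over which the
#'   peak is taken.
#' @param correct_only keep only correct trials.
#' @return a `band_peaks` data.frame: `trial`, `cue_type`, `outcome`,
#'   `band`, `peak` (z units); frame times as `attr(, "frame_times")`.
#' @export
stft_band_peaks <- function(epochs, channel,
                            bands = list(theta = c(4, 8),
                                         beta = c(12, 40),
                                         hg = c(70, 200)),
                            window_s = 0.5, hop_s = 0.005,
                            post_window = c(0, 1),
                            correct_only = TRUE) {
  fs <- epochs$fs
  if (any(vapply(bands, function(b) b[2] >= fs / 2, logical(1))))
    stop("band above Nyquist")
  win_n <- as.integer(round(window_s * fs))
  hop_n <- max(1L, as.integer(round(hop_s * fs)))
  nt <- dim(epochs$data)[3]
  pad_n <- win_n %/% 2L
  starts <- seq(1L, nt, by = hop_n)          # frame centers = original idx
  frame_time <- epochs$time[starts]
  w <- hann_window(win_n)
  faxis <- (seq_len(win_n %/% 2L + 1L) - 1L) * fs / win_n
  bins <- lapply(bands, function(b) which(faxis >= b[1] & faxis <= b[2]))
  idx <- outer(seq_len(win_n) - 1L, starts, "+")   # win_n x n_frames

  n_trials <- dim(epochs$data)[1]
  bp <- array(NA_real_,
              dim = c(n_trials, length(bands), length(starts)))
  for (tr in seq_len(n_trials)) {
    x <- epochs$data[tr, channel, ]
    xp <- c(rev(x[seq_len(pad_n)]), x, rev(x[(nt - pad_n + 1L):nt]))
    Fm <- matrix(xp[idx], nrow = win_n) * w
    S <- Mod(stats::mvfft(Fm))^2
    for (b in seq_along(bands))
      bp[tr, b, ] <- colMeans(S[bins[[b]], , drop = FALSE])
  }
  base <- frame_time < 0
  post <- frame_time >= post_window[1] & frame_time < post_window[2]
  out <- vector("list", length(bands))
  for (b in seq_along(bands)) {
    bb <- as.vector(bp[, b, base])
    mu <- mean(bb); s <- stats::sd(bb)
    if (s == 0) stop("degenerate baseline band power in band ",
                     names(bands)[b])
    zpk <- apply((bp[, b, post, drop = FALSE] - mu) / s, 1L, max)
    out[[b]] <- data.frame(
      trial = epochs$labels$trial,
      cue_type = epochs$labels$cue_type,
      outcome = epochs$labels$outcome,
      band = names(bands)[b],
      peak = zpk,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (correct_only)
    res <- res[res$outcome %in% c("go_correct", "nogo_correct"), ]
  rownames(res) <- NULL
  attr(res, "frame_times") <- frame_time
  class(res) <- c("band_peaks", class(res))
  res
}

#' No-Go/Go band power ratio
#'
#' Per band, the ratio of the No-Go/Correct mean peak to the Go/Correct
#' mean peak (ratio of means, not mean of ratios), with a percentile
#' bootstrap confidence interval over trials. Because peaks are z-scores
#' the Go mean can be near zero or negative; bands whose Go mean falls at
#' or below `go_floor` are flagged undefined.
#'
#' @param peaks a `band_peaks` data.frame (correct trials of both
#'   conditions).
#' @param n_boot bootstrap resamples for the CI (default 2000).
#' @param conf confidence level.
#' @param go_floor minimum admissible Go mean (z units).
#' @param seed integer seed for the bootstrap.
#' @return data.frame per band: `band`, `mean_nogo`, `mean_go`, `ratio`,
#'   `ci_lo`, `ci_hi`, `defined`, `n_nogo`, `n_go`.
#' @export
power_ratio <- function(peaks, n_boot = 2000, conf = 0.95,
                        go_floor = 0.05, seed = NULL) {
  stopifnot(all(c("band", "outcome", "peak") %in% names(peaks)))
  with_seed(seed, {
    res <- lapply(unique(peaks$band), function(b) {
      pg <- peaks$peak[peaks$band == b & peaks$outcome == "go_correct"]
      pn <- peaks$peak[peaks$band == b & peaks$outcome == "nogo_correct"]
      if (length(pg) == 0L || length(pn) == 0L)
        stop("band ", b, ": a condition has no correct trials")
      mg <- mean(pg); mn <- mean(pn)
      defined <- mg > go_floor
      ratio <- if (defined) mn / mg else NA_real_
      ci <- c(NA_real_, NA_real_)
      if (defined && n_boot > 0) {
        bs <- vapply(seq_len(n_boot), function(i) {
          g <- mean(sample(pg, replace = TRUE))
          n <- mean(sample(pn, replace = TRUE))
          if (g > go_floor) n / g else NA_real_
        }, numeric(1))
        ci <- unname(stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                     na.rm = TRUE))
      }
      if (!defined)
        warning("band ", b, ": Go mean peak ", signif(mg, 3),
                " at or below floor ", go_floor, "; ratio undefined")
      data.frame(band = b, mean_nogo = mn, mean_go = mg, ratio = ratio,
                 ci_lo = ci[1], ci_hi = ci[2], defined = defined,
                 n_nogo = length(pn), n_go = length(pg),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
}
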