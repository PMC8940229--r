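# Phase-amplitude coupling: composite-signal modulation index,
# comodulogram grids, circular-shift permutation significance, and the
# No-Go/Go PAC ratio map.

#' Default PAC frequency bins
#'
#' Phase bins: centers 2-20 Hz every 3 Hz, each 3 Hz wide (clipped to
#' stay above 0.5 Hz). Amplitude bins: 20 Hz wide, hopped every 10 Hz
#' over 40-200 Hz.
#'
#' @param phase_centers phase-bin center frequencies, Hz.
#' @param phase_width phase-bin width, Hz.
#' @param amp_range amplitude coverage `c(low, high)`, Hz.
#' @param amp_width,amp_hop amplitude bin width and hop, Hz.
#' @return list with matrices `phase` and `amp` (rows = bins, columns =
#'   low/high edges) and center vectors.
#' @export
pac_bins <- function(phase_centers = seq(2, 20, by = 3), phase_width = 3,
                     amp_range = c(40, 200), amp_width = 20, amp_hop = 10) {
  ph <- cbind(low = pmax(phase_centers - phase_width / 2, 0.5),
              high = phase_centers + phase_width / 2)
  alo <- seq(amp_range[1], amp_range[2] - amp_width, by = amp_hop)
  am <- cbind(low = alo, high = alo + amp_width)
  list(phase = ph, phase_centers = phase_centers,
       amp = am, amp_centers = alo + amp_width / 2)
}

#' Composite-signal modulation index
#'
#' The modulus of the time average of `A_high(t) * exp(i * phi_low(t))`,
#' where `A_high` is the high-band Hilbert envelope (by default
#' normalized by its own mean, so the index reads as a relative
#' modulation depth) and `phi_low` is the low-band Hilbert phase. Zero
#' for amplitude independent of phase; equals `m/2` when
#' `A(t) = A0 * (1 + m * cos(phi(t)))` with phase uniformly covered.
#'
#' @param x numeric vector (raw trace), at least one low-band cycle long.
#' @param fs sampling rate, Hz.
#' @param phase_band low-frequency band `c(low, high)`, Hz.
#' @param amp_band high-frequency band `c(low, high)`, Hz; must lie above
#'   the phase band.
#' @param normalize divide the envelope by its mean (default `TRUE`).
#' @return nonnegative modulation-index scalar.
#' @export
modulation_index <- function(x, fs, phase_band = c(4, 8),
                             amp_band = c(70, 200), normalize = TRUE) {
  if (length(x) / fs < 1 / phase_band[1])
    stop("trace shorter than one low-band cycle")
  if (phase_band[2] > amp_band[1])
    stop("phase band must lie below the amplitude band")
  phi <- Arg(fft_band_analytic(x, phase_band, fs))
  A <- Mod(fft_band_analytic(x, amp_band, fs))
  if (normalize) A <- A / mean(A)
  Mod(mean(A * exp(1i * phi)))
}

# Per-trial phase/envelope decomposition of one electrode over the
# post-cue second. Returns, per (phase bin, amplitude bin), what the grid
# and permutation stages need: unit phasors E and mean-normalized
# envelopes A, each a trials x time matrix.
pac_decompose <- function(epochs, channel, bins = pac_bins(),
                          post_window = c(0, 1), normalize = TRUE) {
  fs <- epochs$fs
  if (any(bins$amp[, 2] >= fs / 2)) stop("amplitude bin above Nyquist")
  post <- epochs$time >= post_window[1] & epochs$time < post_window[2]
  n_tr <- dim(epochs$data)[1]
  np <- nrow(bins$phase); na <- nrow(bins$amp)
  E <- vector("list", np)
  A <- vector("list", na)
  for (p in seq_len(np)) E[[p]] <- matrix(0i, n_tr, sum(post))
  for (a in seq_len(na)) A[[a]] <- matrix(0, n_tr, sum(post))
  for (tr in seq_len(n_tr)) {
    x <- epochs$data[tr, channel, ]
    for (p in seq_len(np)) {
      z <- fft_band_analytic(x, bins$phase[p, ], fs)
      E[[p]][tr, ] <- exp(1i * Arg(z[post]))
    }
    for (a in seq_len(na)) {
      env <- Mod(fft_band_analytic(x, bins$amp[a, ], fs))[post]
      A[[a]][tr, ] <- if (normalize) env / mean(env) else env
    }
  }
  list(E = E, A = A, bins = bins, n_trials = n_tr,
       labels = epochs$labels, fs = fs)
}

# Trials to use for a condition (correct only).
.cond_trials <- function(labels, condition) {
  which(labels$outcome == paste0(condition, "_correct"))
}

#' Comodulogram of modulation indices
#'
#' Modulation index per (phase bin, amplitude bin): the composite signal
#' `A(t) e^{i phi(t)}` is averaged over each trial's post-cue second,
#' the complex per-trial means are averaged across the condition's
#' correct trials, and the modulus is taken last. Averaging complex
#' means (rather than per-trial moduli) keeps the estimator's null level
#' shrinking as `1/sqrt(n_trials)` and preserves genuine coupling, whose
#' preferred phase is consistent across trials.
#'
#' @param epochs a raw `ecog_epochs`.
#' @param channel electrode index (typically the selected Ci).
#' @param condition `"go"` or `"nogo"`.
#' @param bins frequency-bin layout from [pac_bins()].
#' @param post_window post-cue analysis window, seconds (half-open).
#' @param decomp optional precomputed [pac_decompose()] result (shared
#'   with [permutation_mask()] to avoid refiltering).
#' @return a `pac_grid`: `mi` (phase bins x amplitude bins), `bins`,
#'   `condition`, `n_trials`, `masked = FALSE`.
#' @export
pac_grid <- function(epochs, channel, condition = c("nogo", "go"),
                     bins = pac_bins(), post_window = c(0, 1),
                     decomp = NULL) {
  condition <- match.arg(condition)
  if (is.null(decomp))
    decomp <- pac_decompose(epochs, channel, bins, post_window)
  trs <- .cond_trials(decomp$labels, condition)
  if (length(trs) == 0L)
    stop("condition '", condition, "' has no correct trials")
  np <- nrow(decomp$bins$phase); na <- nrow(decomp$bins$amp)
  mi <- matrix(NA_real_, np, na)
  for (p in seq_len(np)) for (a in seq_len(na)) {
    z <- decomp$A[[a]][trs, , drop = FALSE] *
      decomp$E[[p]][trs, , drop = FALSE]
    mi[p, a] <- Mod(mean(rowMeans(z)))
  }
  dimnames(mi) <- list(paste0("ph", decomp$bins$phase_centers),
                       paste0("am", decomp$bins$amp_centers))
  structure(list(mi = mi, bins = decomp$bins, condition = condition,
                 n_trials = length(trs), masked = FALSE),
            class = "pac_grid")
}

#' Permutation significance mask for a comodulogram
#'
#' Builds the null by circularly time-shifting each trial's amplitude
#' envelope relative to its phase series (shift surrogates preserve both
#' series' amplitude spectra and autocorrelation, unlike sample
#' shuffling) and recomputing the trial-averaged modulation index. A bin
#' is significant when the observed index exceeds the null's
#' `1 - alpha` quantile. The full circular cross-correlation gives every
#' shifted index at once, so the null costs one FFT pair per trial and
#' bin.
#'
#' @param epochs,channel,condition,bins,post_window as in [pac_grid()].
#' @param n_shuffles permutation count (default 1000; fewer than 100
#'   triggers a warning about quantile stability).
#' @param alpha significance level.
#' @param seed integer seed for the shift draws.
#' @param decomp optional precomputed [pac_decompose()] result.
#' @return list: logical `mask` (TRUE = significant), `threshold` matrix
#'   of null quantiles, `observed` grid matrix, `n_shuffles`, `alpha`.
#' @export
permutation_mask <- function(epochs, channel, condition = c("nogo", "go"),
                             bins = pac_bins(), n_shuffles = 1000,
                             alpha = 0.05, seed = NULL,
                             post_window = c(0, 1), decomp = NULL) {
  condition <- match.arg(condition)
  if (n_shuffles < 100)
    warning("n_shuffles < 100 gives an unstable null quantile")
  if (is.null(decomp))
    decomp <- pac_decompose(epochs, channel, bins, post_window)
  trs <- .cond_trials(decomp$labels, condition)
  if (length(trs) == 0L)
    stop("condition '", condition, "' has no correct trials")
  np <- nrow(decomp$bins$phase); na <- nrow(decomp$bins$amp)
  nT <- ncol(decomp$E[[1]])
  observed <- matrix(NA_real_, np, na)
  threshold <- matrix(NA_real_, np, na)
  mask <- matrix(FALSE, np, na)
  with_seed(seed, {
    for (p in seq_len(np)) {
      FE <- stats::mvfft(t(decomp$E[[p]][trs, , drop = FALSE]))
      for (a in seq_len(na)) {
        FA <- stats::mvfft(t(decomp$A[[a]][trs, , drop = FALSE]))
        # cc[tau+1, trial] = mean_t A(t+tau) e^{-i phi(t)} (complex);
        # per-trial complex means are averaged across trials before the
        # modulus, matching the observed-grid estimator
        cc <- stats::mvfft(FA * Conj(FE), inverse = TRUE) / (nT^2)
        observed[p, a] <- Mod(mean(cc[1L, ]))
        shifts <- matrix(sample.int(nT - 1L, n_shuffles * length(trs),
                                    replace = TRUE) + 1L,
                         nrow = n_shuffles)
        null_mi <- Mod(rowMeans(matrix(
          cc[cbind(as.vector(shifts),
                   rep(seq_along(trs), each = n_shuffles))],
          nrow = n_shuffles)))
        threshold[p, a] <- if (alpha >= 1) -Inf else
          stats::quantile(null_mi, 1 - alpha)
        mask[p, a] <- observed[p, a] > threshold[p, a]
      }
    }
  })
  dn <- list(paste0("ph", decomp$bins$phase_centers),
             paste0("am", decomp$bins$amp_centers))
  dimnames(observed) <- dimnames(threshold) <- dimnames(mask) <- dn
  list(mask = mask, threshold = threshold, observed = observed,
       n_shuffles = n_shuffles, alpha = alpha, condition = condition)
}

#' Zero the non-significant bins of a comodulogram
#'
#' @param grid a `pac_grid`.
#' @param mask a significance mask from [permutation_mask()] (or any
#'   logical matrix of the grid's shape).
#' @return the grid with non-significant bins set to 0 and
#'   `masked = TRUE`.
#' @export
apply_pac_mask <- function(grid, mask) {
  m <- if (is.list(mask)) mask$mask else mask
  if (!all(dim(m) == dim(grid$mi))) stop("mask shape mismatch")
  grid$mi[!m] <- 0
  grid$masked <- TRUE
  grid
}

#' No-Go/Go PAC ratio map
#'
#' Elementwise ratio of two permutation-masked comodulograms (No-Go over
#' Go). Cells whose Go average is zero after masking are flagged
#' undefined (NA) rather than infinite.
#'
#' @param grid_nogo,grid_go masked `pac_grid`s of matching shape.
#' @return a `pac_ratio_map`: `ratio` matrix (NA where undefined),
#'   logical `defined`, and the two input grids' conditions.
#' @export
pac_ratio <- function(grid_nogo, grid_go) {
  if (!all(dim(grid_nogo$mi) == dim(grid_go$mi)))
    stop("grid shape mismatch")
  if (!isTRUE(grid_nogo$masked) || !isTRUE(grid_go$masked))
    stop("pac_ratio expects permutation-masked grids")
  defined <- grid_go$mi > 0
  ratio <- matrix(NA_real_, nrow(grid_go$mi), ncol(grid_go$mi),
                  dimnames = dimnames(grid_go$mi))
  ratio[defined] <- grid_nogo$mi[defined] / grid_go$mi[defined]
  structure(list(ratio = ratio, defined = defined),
            class = "pac_ratio_map")
}

#' Median of the defined cells of a PAC ratio map
#'
#' @param x a `pac_ratio_map`.
#' @return median ratio over defined cells (NA when none are defined).
#' @export
median_defined_ratio <- function(x) {
  if (!any(x$defined)) return(NA_real_)
  stats::median(x$ratio[x$defined])
}

#' Comodulogram heat map
#'
#' @param grid a `pac_grid` (masked or not).
#' @param ... passed to [graphics::image()].
#' @return invisibly, the grid.
#' @export
plot_comodulogram <- function(grid, ...) {
  graphics::image(x = grid$bins$phase_centers, y = grid$bins$amp_centers,
                  z = grid$mi, xlab = "phase frequency (Hz)",
                  ylab = "amplitude frequency (Hz)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = paste0("MI, ", grid$condition), ...)
  invisible(grid)
}
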