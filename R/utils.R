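# Low-level signal primitives shared across modules.
#
# All long FFTs run at 5-smooth (2^a 3^b 5^c) lengths: R's mixed-radix
# transform degrades towards O(n^2) on lengths with large prime factors,
# which arbitrary recording durations routinely hit.

# Reflective (mirror-tiled) padding: values of the even periodic
# extension of x at positions 1-left .. n+right.
.reflect_pad <- function(x, left, right) {
  n <- length(x)
  j <- (1L - left):(n + right)
  idx <- ((j - 1L) %% (2L * n)) + 1L
  idx <- ifelse(idx > n, 2L * n - idx + 1L, idx)
  x[idx]
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Returns the complex analytic signal of a real series: same length,
#' real part equal to the input, imaginary part its Hilbert transform.
#' `Mod()` of the result is the instantaneous envelope, `Arg()` the
#' instantaneous phase.
#'
#' @param x numeric vector.
#' @return complex vector, `length(x)`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("analytic_signal() needs at least 2 samples")
  m <- stats::nextn(n, c(2, 3, 5))
  if (m != n) {
    # reflect-pad to an FFT-friendly length, then trim; the perturbation
    # is confined to the padded tail
    z <- analytic_signal(.reflect_pad(x, 0L, m - n))
    return(z[seq_len(n)])
  }
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Raised-cosine band window on a frequency axis (positive frequencies).
# Unity inside [lo, hi], cosine roll-off over a transition width outside.
.band_window <- function(f, lo, hi, trans_lo, trans_hi) {
  w <- numeric(length(f))
  core <- f >= lo & f <= hi
  w[core] <- 1
  up <- f > (lo - trans_lo) & f < lo
  w[up] <- 0.5 * (1 + cos(pi * (lo - f[up]) / trans_lo))
  dn <- f > hi & f < (hi + trans_hi)
  w[dn] <- 0.5 * (1 + cos(pi * (f[dn] - hi) / trans_hi))
  w
}

#' Zero-phase FFT band-pass returning the band-limited analytic signal
#'
#' Band-passes `x` in the frequency domain with raised-cosine transition
#' edges and simultaneously zeroes negative frequencies, so the result is
#' the analytic signal of the band-limited series. Zero-phase by
#' construction. The input is reflect-padded by half its length before the
#' transform to suppress wrap-around transients. Used for the narrow
#' low-frequency phase bands of the coupling analysis, where IIR
#' transfer-function filters are numerically fragile.
#'
#' @param x numeric vector.
#' @param band `c(low, high)` in Hz, `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @param transition fractional transition width relative to each band edge
#'   (default 0.15, floored at 0.5 Hz).
#' @return complex vector, `length(x)`: band-limited analytic signal.
#' @export
fft_band_analytic <- function(x, band, fs, transition = 0.15) {
  if (length(band) != 2L || band[1] >= band[2])
    stop("band must be c(low, high) with low < high")
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band must lie strictly inside (0, Nyquist)")
  n <- length(x)
  m <- stats::nextn(n + max(256L, n %/% 4L), c(2, 3, 5))
  left <- (m - n) %/% 2L
  xp <- .reflect_pad(x, left, m - n - left)
  npad <- left
  f <- (seq_len(m) - 1L) * fs / m
  # negative-frequency half of the axis
  neg <- f > fs / 2
  trans_lo <- max(band[1] * transition, 0.5)
  trans_hi <- max(band[2] * transition, 0.5)
  w <- .band_window(f, band[1], band[2], trans_lo, trans_hi)
  w[neg] <- 0
  w <- w * 2           # analytic-signal doubling of positive frequencies
  z <- stats::fft(stats::fft(xp) * w, inverse = TRUE) / m
  z[(npad + 1L):(npad + n)]
}

# Zero-phase IIR filtering with reflect padding: forward and reverse passes
# of signal::filter, trimmed back to the input support. The series is
# offset by its first padded value (restored through the filter's DC
# gain) so a zero initial filter state sees no step transient.
zero_phase_filter <- function(filt, x, pad = NULL) {
  n <- length(x)
  order <- max(length(filt$b), length(filt$a)) - 1L
  if (is.null(pad)) pad <- min(n - 1L, max(3L * 10L * order, 300L))
  g_dc <- sum(filt$b) / sum(filt$a)
  one_pass <- function(z) {
    z0 <- z[1L]
    as.numeric(signal::filter(filt, z - z0)) + g_dc * z0
  }
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1L):(pad + n)]
}

# Biquad notch at f0 with quality factor q (Audio-EQ-cookbook design).
notch_biquad <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Gaussian 1/f^alpha background noise by spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain so its power
#' spectral density falls as `1/f^exponent`, then rescaled to the requested
#' standard deviation. Frequencies below `f_floor` are held at the
#' `f_floor` amplitude to keep the variance finite.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param exponent spectral exponent alpha (PSD slope is `-alpha` in
#'   log-log coordinates). Default 2 (Brownian-like, typical of ECoG).
#' @param sd target standard deviation of the output.
#' @param f_floor low-frequency amplitude floor in Hz.
#' @return numeric vector of length `n`. Uses the current RNG stream.
#' @export
pink_noise <- function(n, fs, exponent = 2, sd = 1, f_floor = 0.5) {
  m <- stats::nextn(n, c(2, 3, 5))
  f <- (seq_len(m) - 1L) * fs / m
  f[f > fs / 2] <- fs - f[f > fs / 2]   # fold to two-sided axis
  shape <- pmax(f, f_floor)^(-exponent / 2)
  shape[1L] <- 0                         # no DC
  w <- stats::rnorm(m)
  X <- stats::fft(w) * shape
  x <- Re(stats::fft(X, inverse = TRUE) / m)
  x <- x[seq_len(n)]
  x * sd / stats::sd(x)
}

# Hann window of length n.
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

# Tukey (tapered-cosine) window, taper fraction r per side pair.
tukey_window <- function(n, r = 0.1) {
  if (r <= 0) return(rep(1, n))
  t <- (seq_len(n) - 1L) / (n - 1L)
  w <- rep(1, n)
  lo <- t < r / 2
  hi <- t > 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / r - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / r - 2 / r + 1)))
  w
}

# Run code under a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
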