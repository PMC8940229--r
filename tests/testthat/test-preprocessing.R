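make_session <- function(sig, fs = 1200, events = NULL) {
  new_ecog_session(sig, fs, small_channels(n = nrow(sig)), events)
}

test_that("common-average reference removes the channel mean and is
          idempotent", {
  s <- make_session(matrix(5, nrow = 4, ncol = 100))
  expect_equal(rereference_common_average(s)$signal,
               matrix(0, 4, 100))
  x <- rnorm(1000)
  s2 <- make_session(rbind(x, -x, deparse.level = 0))
  expect_equal(rereference_common_average(s2)$signal, s2$signal)
  set.seed(1)
  s3 <- make_session(matrix(rnorm(8 * 1000), 8))
  r1 <- rereference_common_average(s3)
  expect_true(max(abs(colMeans(r1$signal))) < 1e-10)
  r2 <- rereference_common_average(r1)
  expect_equal(r1$signal, r2$signal)
  expect_error(rereference_common_average(
    make_session(matrix(1, 1, 50))), "single-channel")
})

test_that("notch attenuates line frequencies and passes the passband", {
  fs <- 1200
  t <- (0:(4 * fs - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  s60 <- make_session(rbind(sin(2 * pi * 60 * t), sin(2 * pi * 60 * t)))
  out60 <- notch_line_noise(s60)
  mid <- (fs + 1):(3 * fs)
  expect_lt(rms(out60$signal[1, mid]), 0.1 * rms(s60$signal[1, mid]))
  s10 <- make_session(rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t)))
  out10 <- notch_line_noise(s10)
  expect_lt(abs(rms(out10$signal[1, mid]) / rms(s10$signal[1, mid]) - 1),
            0.01)
  sdc <- make_session(matrix(1, 2, 1000))
  expect_equal(notch_line_noise(sdc)$signal, sdc$signal, tolerance = 1e-6)
  expect_error(notch_line_noise(s10, freqs = 700), "Nyquist")
})

test_that("band envelope tracks tone amplitude and rejects the stopband", {
  fs <- 1200
  t <- (0:(4 * fs - 1)) / fs
  mid <- (fs + 1):(3 * fs)
  env100 <- band_envelope(3.5 * sin(2 * pi * 100 * t), c(70, 200), fs)
  expect_lt(max(abs(env100[mid] - 3.5)), 0.1)
  env10 <- band_envelope(sin(2 * pi * 10 * t), c(70, 200), fs)
  expect_lt(max(env10[mid]), 0.02)
  # AM tone: envelope recovers the modulator within 5% mid-signal
  am <- (1 + 0.5 * cos(2 * pi * 4 * t)) * sin(2 * pi * 100 * t)
  env <- band_envelope(am, c(70, 200), fs)
  target <- 1 + 0.5 * cos(2 * pi * 4 * t)
  expect_lt(max(abs(env[mid] - target[mid]) / target[mid]), 0.05)
  expect_error(band_envelope(t, c(200, 70), fs), "low < high")
  expect_error(band_envelope(t, c(70, 700), fs), "Nyquist")
})

test_that("zero-phase filtering introduces no lag", {
  set.seed(7)
  fs <- 1200
  x <- Re(fft_band_analytic(rnorm(6000), c(80, 120), fs))
  filt <- signal::butter(4, c(70, 200) / (fs / 2), "pass")
  y <- ecogng:::zero_phase_filter(filt, x)
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("epoching follows the half-open window convention and drops
          edge trials", {
  sr <- small_session(seed = 2, n_trials = 21)
  ep <- epoch_session(sr$session)
  expect_equal(dim(ep$data), c(21L, 4L, 2400L))
  expect_equal(ep$time[1], -1)
  expect_equal(ep$time[1201], 0)
  expect_equal(ep$time[2400], 1 - 1 / 1200)
  # label conservation
  expect_equal(table(ep$labels$outcome), table(sr$session$events$outcome))
  # cue too close to the start is dropped
  s2 <- sr$session
  s2$events$onset_sample[1] <- 100L
  expect_warning(ep2 <- epoch_session(s2), "dropped")
  expect_equal(dim(ep2$data)[1], 20L)
  # epoch content matches the raw signal slice
  ev1 <- ep$labels$trial[1]
  on <- sr$session$events$onset_sample[sr$session$events$trial == ev1]
  expect_equal(ep$data[1, 2, ], sr$session$signal[2, (on - 1200):(on + 1199)])
})

test_that("baseline z-normalization centers the pooled baseline and is
          affine invariant", {
  set.seed(3)
  n_tr <- 49; n_t <- 2400
  dat <- array(rnorm(n_tr * 2 * n_t, mean = 5, sd = 2), c(n_tr, 2, n_t))
  ep <- manual_epochs(dat, fs = 1200, time = ((1:n_t) - 1201) / 1200)
  z <- z_normalize_to_baseline(ep)
  b <- z$time < 0
  expect_lt(abs(mean(z$data[, 1, b])), 0.05)
  expect_lt(abs(sd(z$data[, 1, b]) - 1), 0.05)
  # a post-cue value equal to the baseline mean maps to 0
  ep2 <- ep
  ep2$data[1, 1, 1300] <- mean(ep$data[, 1, b])
  z2 <- z_normalize_to_baseline(ep2)
  expect_equal(z2$data[1, 1, 1300], 0, tolerance = 1e-9)
  # scaling the raw data leaves z-scores unchanged
  ep3 <- ep
  ep3$data <- ep3$data * 7.3
  expect_equal(z_normalize_to_baseline(ep3)$data, z$data, tolerance = 1e-9)
  # degenerate baseline errors
  ep4 <- ep
  ep4$data[, 1, ] <- 1
  expect_error(z_normalize_to_baseline(ep4), "zero variance")
  expect_error(z_normalize_to_baseline(z), "already normalized")
})
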