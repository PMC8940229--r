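# Shared small session with a clear injected spectral contrast.
spec_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sr <- small_session(seed = 31, n_trials = 21)
      pre <- preprocess_session(sr$session)
      cache <<- list(sr = sr, epochs = epoch_session(pre))
    }
    cache
  }
})

test_that("ERSP baseline rows are centered and injected high-gamma shows
          post-cue", {
  fx <- spec_fixture()
  ci <- fx$sr$truth$ci_channel
  er <- morlet_ersp(fx$epochs, ci, "nogo")
  b <- er$time < 0
  expect_lt(max(abs(rowMeans(er$power[, b]))), 0.05)
  # strongest post-cue response sits in the injected carrier band
  post <- er$time >= 0
  peak_freq <- er$freqs[which.max(apply(er$power[, post], 1, max))]
  expect_gte(peak_freq, 70)
  expect_lte(peak_freq, 200)
  expect_error(morlet_ersp(fx$epochs, ci, "nogo", freqs = c(10, 700)),
               "Nyquist")
})

test_that("ERSP is invariant to rescaling the raw signal", {
  fx <- spec_fixture()
  ci <- fx$sr$truth$ci_channel
  er1 <- morlet_ersp(fx$epochs, ci, "go", freqs = seq(5, 100, 15))
  ep2 <- fx$epochs
  ep2$data <- ep2$data * 2
  er2 <- morlet_ersp(ep2, ci, "go", freqs = seq(5, 100, 15))
  expect_equal(er1$power, er2$power, tolerance = 1e-8)
})

test_that("STFT evaluates 200 post-cue frames at the 5 ms hop and ranks
          injected bands", {
  fx <- spec_fixture()
  ci <- fx$sr$truth$ci_channel
  pk <- stft_band_peaks(fx$epochs, ci)
  ft <- attr(pk, "frame_times")
  expect_equal(sum(ft >= 0 & ft < 1), 200L)
  # one peak per retained trial and band
  expect_equal(nrow(pk), 3L * sum(fx$epochs$labels$outcome %in%
                                    c("go_correct", "nogo_correct")))
  # injected No-Go gains exceed Go gains in every band
  agg <- tapply(pk$peak, list(pk$band, pk$outcome), mean)
  expect_true(all(agg[, "nogo_correct"] > agg[, "go_correct"]))
  expect_error(stft_band_peaks(fx$epochs, ci,
                               bands = list(bad = c(100, 700))), "Nyquist")
})

test_that("STFT band power stays flat for a stationary signal and tracks
          a power step", {
  set.seed(41)
  fs <- 1200
  nt <- 2 * fs
  tm <- ((1:nt) - fs - 1) / fs
  post <- tm >= 0
  n_tr <- 4
  mk <- function(band) Re(fft_band_analytic(rnorm(nt), band, fs))
  dat <- array(0, c(n_tr, 1, nt))
  dat2 <- dat
  for (tr in seq_len(n_tr)) {
    theta_part <- 3 * mk(c(4, 8))
    hg_part <- mk(c(90, 130))
    dat[tr, 1, ] <- theta_part + hg_part + rnorm(nt, sd = 0.2)
    stepped <- hg_part
    stepped[post] <- stepped[post] * sqrt(3)   # 3x HG power step post-cue
    dat2[tr, 1, ] <- theta_part + stepped + rnorm(nt, sd = 0.2)
  }
  labels <- data.frame(trial = seq_len(n_tr), cue_type = "go",
                       outcome = "go_correct")
  ep <- manual_epochs(dat, fs = fs, time = tm, labels = labels)
  ep$channels <- small_channels(n = 1)
  pk <- stft_band_peaks(ep, 1)
  # stationary signal: post-cue peaks stay near the baseline level
  expect_lt(max(abs(pk$peak)), 6)
  ep2 <- ep; ep2$data <- dat2
  pk2 <- stft_band_peaks(ep2, 1)
  hg2 <- pk2$peak[pk2$band == "hg"]
  th2 <- pk2$peak[pk2$band == "theta"]
  # the step registers in HG on every trial and dominates the theta peaks
  expect_true(all(hg2 > th2))
  expect_gt(mean(hg2), mean(th2) + 4)
  expect_gt(mean(hg2), mean(pk$peak[pk$band == "hg"]) + 3)
})

test_that("power ratio is the ratio of condition means with Eq.-style
          scaling", {
  mk <- function(go, nogo, band = "hg") {
    data.frame(trial = seq_len(length(go) + length(nogo)),
               cue_type = rep(c("go", "nogo"), c(length(go), length(nogo))),
               outcome = rep(c("go_correct", "nogo_correct"),
                             c(length(go), length(nogo))),
               band = band, peak = c(go, nogo))
  }
  pr <- power_ratio(mk(c(1, 1), c(2, 2)), n_boot = 200, seed = 1)
  expect_equal(pr$ratio, 2)
  pr1 <- power_ratio(mk(c(1, 2, 3), c(1, 2, 3)), n_boot = 0)
  expect_equal(pr1$ratio, 1)
  # multiplying No-Go peaks by k multiplies the ratio by k
  base <- mk(c(1.2, 0.8, 1), c(1.5, 2.5))
  k <- 3.7
  scaled <- base
  scaled$peak[scaled$outcome == "nogo_correct"] <-
    scaled$peak[scaled$outcome == "nogo_correct"] * k
  expect_equal(power_ratio(scaled, n_boot = 0)$ratio,
               k * power_ratio(base, n_boot = 0)$ratio)
  # Go mean at/below the floor flags the band undefined
  expect_warning(und <- power_ratio(mk(c(0.01, -0.01), c(1, 2)), n_boot = 0),
                 "undefined")
  expect_false(und$defined)
  expect_true(is.na(und$ratio))
  # bootstrap CI brackets the point estimate
  set.seed(5)
  prb <- power_ratio(mk(rnorm(30, 1, 0.1), rnorm(10, 2, 0.1)),
                     n_boot = 500, seed = 2)
  expect_true(prb$ci_lo <= prb$ratio && prb$ratio <= prb$ci_hi)
})
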