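# Clean synthetic trace with known sinusoidal amplitude modulation:
# theta carrier for phase plus a 110 Hz carrier whose envelope is
# 1 + m*cos(theta phase).
pac_trace <- function(m, dur = 100, fs = 1200, f_phase = 6, f_amp = 110) {
  tt <- (0:(dur * fs - 1)) / fs
  phase <- 2 * pi * f_phase * tt
  2 * cos(phase) + (1 + m * cos(phase)) * cos(2 * pi * f_amp * tt)
}

test_that("modulation index matches the analytic m/2 for sinusoidal
          modulation", {
  for (m in c(0.2, 0.5, 1)) {
    mi <- modulation_index(pac_trace(m), 1200, c(4, 8), c(70, 200))
    expect_lt(abs(mi - m / 2) / (m / 2), 0.1)
  }
  mi0 <- modulation_index(pac_trace(0), 1200, c(4, 8), c(70, 200))
  expect_lt(mi0, 0.02)
})

test_that("modulation index validates its inputs", {
  x <- pac_trace(0.5, dur = 2)
  expect_error(modulation_index(x[1:100], 1200, c(4, 8), c(70, 200)),
               "one low-band cycle")
  expect_error(modulation_index(x, 1200, c(4, 80), c(70, 200)),
               "below the amplitude band")
})

test_that("default comodulogram grid is 7 phase x 15 amplitude bins", {
  bins <- pac_bins()
  expect_equal(nrow(bins$phase), 7L)
  expect_equal(bins$phase_centers, seq(2, 20, 3))
  expect_equal(nrow(bins$amp), 15L)
  expect_equal(bins$amp[1, ], c(low = 40, high = 60))
  expect_equal(bins$amp[15, ], c(low = 180, high = 200))
})

# Shared fixture: session with strong No-Go coupling on the IFG target.
pac_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sr <- small_session(seed = 55, n_trials = 35,
                          sim = sim_config(n_channels = 8))
      pre <- preprocess_session(sr$session)
      cache <<- list(sr = sr, epochs = epoch_session(pre))
    }
    cache
  }
})

test_that("comodulogram localizes the injected theta-to-HG coupling", {
  fx <- pac_fixture()
  ci <- fx$sr$truth$ci_channel
  g <- pac_grid(fx$epochs, ci, "nogo")
  expect_true(all(g$mi >= 0))
  idx <- which(g$mi == max(g$mi), arr.ind = TRUE)
  ph <- g$bins$phase[idx[1], ]
  am <- g$bins$amp[idx[2], ]
  expect_true(ph["low"] <= 6 && 6 <= ph["high"])
  # argmax amplitude bin overlaps the coupled support: the 90-130 Hz
  # carrier plus the +/- 6 Hz modulation sidebands
  expect_true(am["low"] < 136 && am["high"] > 84)
  expect_error(pac_grid(fx$epochs, 2, "nogo",
                        bins = pac_bins(amp_range = c(40, 700))), "Nyquist")
})

test_that("permutation mask flags injected coupling, zeroes grids, and
          degenerates sensibly", {
  fx <- pac_fixture()
  ci <- fx$sr$truth$ci_channel
  bins <- pac_bins()
  decomp <- ecogng:::pac_decompose(fx$epochs, ci, bins)
  g <- pac_grid(fx$epochs, ci, "nogo", bins, decomp = decomp)
  msk <- permutation_mask(fx$epochs, ci, "nogo", bins, n_shuffles = 200,
                          seed = 8, decomp = decomp)
  # observed grid recomputed by the permutation path matches pac_grid
  expect_equal(msk$observed, g$mi, tolerance = 1e-9)
  # the coupled bin is significant
  idx <- which(g$mi == max(g$mi), arr.ind = TRUE)
  expect_true(msk$mask[idx])
  # alpha = 1 declares every bin significant
  msk_all <- permutation_mask(fx$epochs, ci, "nogo", bins, n_shuffles = 100,
                              alpha = 1, seed = 8, decomp = decomp)
  expect_true(all(msk_all$mask))
  expect_warning(permutation_mask(fx$epochs, ci, "nogo", bins,
                                  n_shuffles = 50, seed = 1,
                                  decomp = decomp), "unstable")
  gm <- apply_pac_mask(g, msk)
  expect_true(all(gm$mi[!msk$mask] == 0))
  expect_true(gm$masked)
})

test_that("circular shifts preserve the amplitude spectrum of a series", {
  set.seed(6)
  x <- rnorm(512)
  xs <- c(x[101:512], x[1:100])
  expect_equal(Mod(fft(xs)), Mod(fft(x)), tolerance = 1e-10)
})

test_that("PAC ratio map defines cells by the Go grid and flags the rest", {
  mk_grid <- function(mi) {
    structure(list(mi = mi, bins = pac_bins(), condition = "x",
                   n_trials = 5, masked = TRUE), class = "pac_grid")
  }
  m <- matrix(0, 7, 15)
  m[2, 5] <- 0.2; m[3, 6] <- 0.1
  g_go <- mk_grid(m)
  g_ng <- mk_grid(m * 3)
  r <- pac_ratio(g_ng, g_go)
  expect_equal(sum(r$defined), 2L)
  expect_equal(r$ratio[2, 5], 3)
  expect_equal(median_defined_ratio(r), 3)
  # identical grids give ratio 1 wherever defined
  r1 <- pac_ratio(g_go, g_go)
  expect_true(all(r1$ratio[r1$defined] == 1))
  # all-zero Go grid -> nothing defined, median NA
  r0 <- pac_ratio(g_ng, mk_grid(matrix(0, 7, 15)))
  expect_false(any(r0$defined))
  expect_true(is.na(median_defined_ratio(r0)))
  bad <- mk_grid(matrix(0, 3, 3))
  expect_error(pac_ratio(g_ng, bad), "shape")
  expect_error(pac_ratio(g_ng, structure(list(mi = m, masked = FALSE),
                                         class = "pac_grid")), "masked")
})

test_that("No-Go coupling beats Go coupling in the masked ratio map", {
  fx <- pac_fixture()
  ci <- fx$sr$truth$ci_channel
  res <- subject_pac_analysis(fx$epochs, ci,
                              pipeline_config(n_shuffles = 200), seed = 3)
  expect_gt(res$median_ratio, 1)
})
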