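test_that("task sequence honors trial count, ratio, jitter, and seed", {
  ev <- generate_task_sequence(task_config(), seed = 3)
  expect_equal(nrow(ev), 49L)
  expect_equal(sum(ev$cue_type == "nogo"), 7L)
  expect_equal(sum(ev$cue_type == "go"), 42L)
  expect_true(all(ev$iti_s >= 0.75 & ev$iti_s <= 1.25))
  # onsets strictly increasing with cue + ITI spacing
  expect_true(all(diff(ev$onset_s) >= 1 + 0.75 - 1e-9))
  ev2 <- generate_task_sequence(task_config(), seed = 3)
  expect_identical(ev, ev2)
  ev3 <- generate_task_sequence(task_config(), seed = 4)
  expect_false(identical(ev$cue_type, ev3$cue_type))
})

test_that("indivisible cue ratio errors unless rounding is allowed", {
  expect_error(generate_task_sequence(task_config(n_trials = 50), seed = 1),
               "does not divide")
  ev <- generate_task_sequence(
    task_config(n_trials = 50, allow_rounding = TRUE), seed = 1)
  expect_equal(nrow(ev), 50L)
  expect_equal(sum(ev$cue_type == "nogo"), round(50 / 7))
})

test_that("behavior simulation matches the requested accuracy", {
  ev <- generate_task_sequence(task_config(), seed = 1)
  prof1 <- small_profile(acc = 1)
  b1 <- simulate_behavior(ev, prof1, seed = 2)
  expect_true(all(b1$outcome[b1$cue_type == "go"] == "go_correct"))
  expect_true(all(b1$outcome[b1$cue_type == "nogo"] == "nogo_correct"))
  prof0 <- small_profile(acc = 0)
  b0 <- simulate_behavior(ev, prof0, seed = 2)
  expect_true(all(grepl("_wrong$", b0$outcome)))
  # large-sample empirical accuracy within the ~3-sigma binomial band
  evbig <- generate_task_sequence(
    task_config(n_trials = 9996, iti_mean = 1), seed = 5)
  bbig <- simulate_behavior(evbig, small_profile(acc = 0.939), seed = 6)
  expect_lt(abs(attr(classify_trials(bbig), "accuracy") - 0.939), 0.01)
})

test_that("simulation is deterministic and records ground truth", {
  a <- small_session(seed = 9)
  b <- small_session(seed = 9)
  expect_identical(a$session$signal, b$session$signal)
  expect_identical(a$session$events, b$session$events)
  expect_named(a$truth, c("subject_id", "age", "hand", "band_gains",
                          "pac_depth", "laterality_weight", "ci_channel",
                          "cm_channel", "motor_active", "schedule"),
               ignore.order = TRUE)
  expect_true(a$truth$pac_depth["nogo"] >= a$truth$pac_depth["go"])
  c <- small_session(seed = 10)
  expect_false(identical(a$session$signal, c$session$signal))
})

test_that("simulation requires IFG and motor channel labels", {
  ch <- small_channels()
  ch$roi <- "other"
  expect_error(
    simulate_session(small_profile(), task_config(n_trials = 7),
                     sim_config(n_channels = 4), seed = 1, channels = ch),
    "IFG")
})

test_that("background spectrum recovers the configured 1/f exponent", {
  sim <- sim_config(
    n_channels = 4, hg_burst_gain_motor = 0,
    band_gains_ifg = list(theta = c(go = 0, nogo = 0),
                          beta = c(go = 0, nogo = 0),
                          hg = c(go = 0, nogo = 0)),
    pac_depth = c(go = 0, nogo = 0),
    line_noise_amplitudes = c("60" = 0, "120" = 0, "180" = 0))
  sr <- small_session(seed = 21, sim = sim)
  x <- sr$session$signal[1, ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = 1200), spans = 11,
                          plot = FALSE, taper = 0)
  sel <- sp$freq >= 2 & sp$freq <= 200
  fit <- stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel]))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 2), 0.3)
})

test_that("laterality weight is bounded, monotone, and collapses the left
          No-Go excess at high age", {
  sim <- sim_config()
  ages <- seq(4, 20, by = 2)
  w <- laterality_weight(ages, sim)
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(diff(w) > 0))
  old_left <- small_session(seed = 4, age = 30, side = "left")
  expect_lt(abs(old_left$truth$band_gains$hg["nogo"] -
                  old_left$truth$band_gains$hg["go"]), 0.01)
  old_right <- small_session(seed = 4, age = 30, side = "right")
  expect_equal(unname(old_right$truth$band_gains$hg["nogo"]),
               unname(sim$band_gains_ifg$hg["nogo"]))
})
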