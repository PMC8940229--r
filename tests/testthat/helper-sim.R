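# Shared fixtures: reduced-size synthetic sessions for fast tests.

small_channels <- function(side = "right", n = 4L) {
  roi <- rep("other", n)
  roi[seq_len(min(n, 2L))] <- "IFG"
  if (n >= 3L) roi[3L] <- "motor"
  data.frame(channel = seq_len(n), label = sprintf("C%02d", seq_len(n)),
             roi = roi, hemisphere = side, stringsAsFactors = FALSE)
}

small_profile <- function(age = 11, side = "right", acc = 1) {
  subject_profile("T01", age = age, grid_side = side,
                  hands_tested = setdiff(c("left", "right"), side),
                  behavioral_accuracy = acc)
}

# 21 trials keeps 3 No-Go trials at the 1:6 ratio while shortening the
# recording to ~50 s
small_session <- function(seed = 1, age = 11, side = "right", acc = 1,
                          n_trials = 21L, sim = sim_config(n_channels = 4L),
                          task = task_config(n_trials = n_trials)) {
  simulate_session(small_profile(age, side, acc), task, sim, seed = seed,
                   channels = small_channels(side, n = sim$n_channels))
}

# Hand-built epochs container for unit tests that need exact values.
manual_epochs <- function(data, fs, time, channels = NULL, labels = NULL,
                          normalized = FALSE) {
  if (is.null(channels))
    channels <- small_channels(n = dim(data)[2])[seq_len(dim(data)[2]), ]
  structure(list(data = data, time = time, fs = fs, channels = channels,
                 labels = labels, window = range(time), normalized = normalized),
            class = "ecog_epochs")
}
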