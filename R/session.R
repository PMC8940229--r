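# Containers: continuous recording session and epoched data.

#' Construct an ECoG recording session
#'
#' @param signal numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate, Hz.
#' @param channels data.frame with columns `channel`, `label`, `roi`
#'   (`"IFG"`, `"motor"`, or `"other"`), `hemisphere`.
#' @param events event table (see [generate_task_sequence()]); may be
#'   `NULL` for task-free recordings.
#' @return an `ecog_session`.
#' @export
new_ecog_session <- function(signal, fs, channels, events = NULL) {
  stopifnot(is.matrix(signal), nrow(signal) == nrow(channels), fs > 0)
  if (anyNA(signal)) stop("signal contains NA values")
  structure(list(signal = signal, fs = fs, channels = channels,
                 events = events),
            class = "ecog_session")
}

#' @export
print.ecog_session <- function(x, ...) {
  cat(sprintf("<ecog_session> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  cat("  ROIs:", paste(sprintf("%s=%d", names(table(x$channels$roi)),
                               table(x$channels$roi)), collapse = ", "), "\n")
  if (!is.null(x$events))
    cat(sprintf("  events: %d (%d go / %d nogo)\n", nrow(x$events),
                sum(x$events$cue_type == "go"),
                sum(x$events$cue_type == "nogo")))
  invisible(x)
}

#' @export
print.ecog_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ecog_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  window [%g, %g) s; normalized: %s\n",
              x$window[1], x$window[2], x$normalized))
  invisible(x)
}
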