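# Session I/O: minimal EDF (European Data Format) writer/reader and
# BIDS-style TSV event tables. Channel ROI and hemisphere ride in the EDF
# label field as "<label> <roi> <L|R>".

.edf_num <- function(x) formatC(signif(x, 6), width = 8, format = "g",
                                digits = 6)
.edf_pad <- function(x, width) formatC(substr(x, 1, width), width = -width)

#' Write a session to an EDF file
#'
#' One data record per second, 16-bit samples, physical units microvolts,
#' per-channel symmetric physical range. The sampling rate must be an
#' integer. The true sample count is recorded in the reserved header
#' field so the trailing zero-padded partial record can be stripped on
#' read.
#'
#' @param session an `ecog_session`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_edf <- function(session, path) {
  fs <- session$fs
  if (fs != round(fs)) stop("EDF export needs an integer sampling rate")
  sig <- session$signal
  nch <- nrow(sig)
  n <- ncol(sig)
  n_rec <- ceiling(n / fs)
  pad <- n_rec * fs - n
  if (pad > 0) sig <- cbind(sig, matrix(0, nch, pad))
  pmax <- apply(abs(sig), 1L, max)
  pmax[pmax == 0] <- 1
  # quantize the physical range through its 8-character header rendering
  # so writer and reader share the exact same scale factor
  pmax <- as.numeric(.edf_num(pmax * (1 + 1e-5)))
  dig <- round(sweep(sig, 1L, pmax, "/") * 32767)

  ch <- session$channels
  labels <- sprintf("%s %s %s", ch$label, ch$roi,
                    toupper(substr(ch$hemisphere, 1, 1)))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad("X", 80),
    .edf_pad(sprintf("Startdate X NSAMP=%d", n), 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(as.character(256L * (nch + 1L)), 8),
    .edf_pad("", 44),
    .edf_pad(as.character(n_rec), 8),
    .edf_pad("1", 8),
    .edf_pad(as.character(nch), 4)
  )
  sig_hdr <- paste0(
    paste(vapply(labels, .edf_pad, "", width = 16), collapse = ""),
    paste(rep(.edf_pad("", 80), nch), collapse = ""),
    paste(rep(.edf_pad("uV", 8), nch), collapse = ""),
    paste(vapply(-pmax, .edf_num, ""), collapse = ""),
    paste(vapply(pmax, .edf_num, ""), collapse = ""),
    paste(rep(.edf_pad("-32767", 8), nch), collapse = ""),
    paste(rep(.edf_pad("32767", 8), nch), collapse = ""),
    paste(rep(.edf_pad("", 80), nch), collapse = ""),
    paste(rep(.edf_pad(as.character(fs), 8), nch), collapse = ""),
    paste(rep(.edf_pad("", 32), nch), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL, useBytes = TRUE)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx])), con, size = 2L, endian = "little")
  }
  invisible(path)
}

.edf_read_field <- function(con, width, n = 1L) {
  vapply(seq_len(n), function(i)
    trimws(readChar(con, width, useBytes = TRUE)), "")
}

#' Read an EDF file written by [write_edf()]
#'
#' Parses channel ROI and hemisphere from the label field; a label that
#' does not carry both fields raises a schema error naming the absent
#' fields.
#'
#' @param path EDF file path.
#' @return an `ecog_session` without events (attach via
#'   [read_session()]).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  .edf_read_field(con, 8)                    # version
  .edf_read_field(con, 80)                   # patient
  rec_id <- .edf_read_field(con, 80)
  .edf_read_field(con, 8); .edf_read_field(con, 8)
  .edf_read_field(con, 8)                    # header bytes
  .edf_read_field(con, 44)
  n_rec <- as.integer(.edf_read_field(con, 8))
  rec_dur <- as.numeric(.edf_read_field(con, 8))
  nch <- as.integer(.edf_read_field(con, 4))
  labels <- .edf_read_field(con, 16, nch)
  .edf_read_field(con, 80, nch)
  .edf_read_field(con, 8, nch)               # phys dim
  pmin <- as.numeric(.edf_read_field(con, 8, nch))
  pmax <- as.numeric(.edf_read_field(con, 8, nch))
  dmin <- as.numeric(.edf_read_field(con, 8, nch))
  dmax <- as.numeric(.edf_read_field(con, 8, nch))
  .edf_read_field(con, 80, nch)
  nr <- as.integer(.edf_read_field(con, 8, nch))
  .edf_read_field(con, 32, nch)
  if (length(unique(nr)) != 1L)
    stop("mixed per-channel sampling rates are not supported")
  fs <- nr[1] / rec_dur
  sig <- matrix(0, nch, n_rec * nr[1])
  for (r in seq_len(n_rec)) {
    d <- readBin(con, "integer", n = nch * nr[1], size = 2L,
                 endian = "little")
    sig[, ((r - 1L) * nr[1] + 1L):(r * nr[1])] <-
      matrix(d, nrow = nch, byrow = TRUE)
  }
  for (c_i in seq_len(nch))
    sig[c_i, ] <- (sig[c_i, ] - dmin[c_i]) *
      (pmax[c_i] - pmin[c_i]) / (dmax[c_i] - dmin[c_i]) + pmin[c_i]
  nsamp <- regmatches(rec_id, regexpr("NSAMP=[0-9]+", rec_id))
  if (length(nsamp) == 1L) {
    n_true <- as.integer(sub("NSAMP=", "", nsamp))
    sig <- sig[, seq_len(n_true), drop = FALSE]
  }
  parts <- strsplit(labels, "\\s+")
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad))
    stop("channel metadata incomplete: label(s) ",
         paste(labels[bad], collapse = ", "),
         " lack the required fields <label> <roi> <hemisphere>")
  channels <- data.frame(
    channel = seq_len(nch),
    label = vapply(parts, `[`, "", 1L),
    roi = vapply(parts, `[`, "", 2L),
    hemisphere = ifelse(vapply(parts, `[`, "", 3L) == "L", "left", "right"),
    stringsAsFactors = FALSE
  )
  new_ecog_session(sig, fs, channels, events = NULL)
}

#' Write an event table to TSV
#'
#' @param events event table data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_events_tsv <- function(events, path) {
  first <- intersect(c("onset_sample", "cue_type", "response", "latency_s",
                       "outcome"), names(events))
  cols <- c(first, setdiff(names(events), first))
  utils::write.table(events[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an event table from TSV
#'
#' @param path TSV path with at least `onset_sample` and `cue_type`.
#' @return event table data.frame.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("onset_sample", "cue_type")
  missing <- setdiff(need, names(ev))
  if (length(missing) > 0)
    stop("events file lacks required column(s): ",
         paste(missing, collapse = ", "))
  if ("response" %in% names(ev)) ev$response <- as.logical(ev$response)
  ev
}

#' Read and validate a full session (signal + events)
#'
#' @param path_signal EDF file.
#' @param path_events events TSV.
#' @return a validated `ecog_session`.
#' @export
read_session <- function(path_signal, path_events) {
  session <- read_edf(path_signal)
  ev <- read_events_tsv(path_events)
  bad <- which(ev$onset_sample < 1L | ev$onset_sample > ncol(session$signal))
  if (length(bad) > 0)
    stop("event row(s) ", paste(bad, collapse = ", "),
         ": onset outside the recorded signal")
  session$events <- ev
  session
}

#' Write a full session (signal + events)
#'
#' @param session an `ecog_session` with events.
#' @param path_signal EDF output path.
#' @param path_events events TSV output path.
#' @return invisibly, a list of both paths.
#' @export
write_session <- function(session, path_signal, path_events) {
  write_edf(session, path_signal)
  if (!is.null(session$events)) write_events_tsv(session$events, path_events)
  invisible(list(signal = path_signal, events = path_events))
}
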