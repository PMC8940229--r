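# Trial classification, high-gamma activation mapping, and selection of
# the representative motor (Cm) and inferior-frontal (Ci) electrodes.

#' Classify trials into the four Go/No-Go outcome categories
#'
#' Mapping: (go, response) -> `go_correct`; (go, no response) ->
#' `go_wrong`; (nogo, no response) -> `nogo_correct`; (nogo, response) ->
#' `nogo_wrong`.
#'
#' @param events event table with `cue_type` and logical `response`.
#' @return the event table with an `outcome` column; overall accuracy is
#'   attached as `attr(, "accuracy")`.
#' @export
classify_trials <- function(events) {
  if (!"response" %in% names(events) || anyNA(events$response))
    stop("every event needs a non-missing response flag")
  if (!all(events$cue_type %in% c("go", "nogo")))
    stop("cue_type must be 'go' or 'nogo'")
  correct <- ifelse(events$cue_type == "go", events$response,
                    !events$response)
  events$outcome <- paste0(events$cue_type,
                           ifelse(correct, "_correct", "_wrong"))
  attr(events, "accuracy") <- mean(correct)
  events
}

#' Per-electrode high-gamma activation map
#'
#' For each electrode and condition, the activation scalar is the mean
#' over that condition's *correct* trials of the per-trial maximum of the
#' z-normalized high-gamma envelope in the post-cue second.
#'
#' @param epochs a normalized `ecog_epochs` of high-gamma envelopes
#'   (see [hg_envelope_epochs()]), with outcome labels.
#' @param post_window `c(start, end)` seconds of the response period
#'   (half-open) over which the per-trial maximum is taken.
#' @return an `activation_map` data.frame: `channel`, `label`, `roi`,
#'   `hemisphere`, `go_correct`, `nogo_correct` (NA when a condition has
#'   no correct trials).
#' @export
hg_activation_map <- function(epochs, post_window = c(0, 1)) {
  if (!isTRUE(epochs$normalized))
    stop("epochs must be z-normalized envelopes")
  if (!"outcome" %in% names(epochs$labels))
    stop("epochs carry no outcome labels; run classify_trials() upstream")
  tsel <- epochs$time >= post_window[1] & epochs$time < post_window[2]
  cond_trials <- list(
    go_correct = which(epochs$labels$outcome == "go_correct"),
    nogo_correct = which(epochs$labels$outcome == "nogo_correct")
  )
  out <- epochs$channels
  for (cond in names(cond_trials)) {
    trs <- cond_trials[[cond]]
    if (length(trs) == 0L) {
      warning("no correct trials for condition ", cond,
              "; activation flagged missing")
      out[[cond]] <- NA_real_
      next
    }
    peaks <- apply(epochs$data[trs, , tsel, drop = FALSE], c(1, 2), max)
    out[[cond]] <- colMeans(peaks)
  }
  class(out) <- c("activation_map", class(out))
  out
}

#' Select the representative motor and IFG electrodes
#'
#' `cm` is the motor-ROI electrode with the highest Go/Correct activation;
#' `ci` the IFG-ROI electrode with the highest No-Go/Correct activation.
#' Exact ties are broken toward the lowest electrode index with a warning.
#'
#' @param map an `activation_map` from [hg_activation_map()].
#' @return list with elements `cm` and `ci` (electrode indices into
#'   `map$channel`) and the corresponding activation values.
#' @export
select_electrodes <- function(map) {
  pick <- function(roi, col) {
    rows <- which(map$roi == roi)
    if (length(rows) == 0L)
      stop("no electrode labeled '", roi, "' in the activation map")
    vals <- map[[col]][rows]
    if (all(is.na(vals)))
      stop("activation undefined for all '", roi, "' electrodes")
    best <- rows[which(vals == max(vals, na.rm = TRUE))]
    if (length(best) > 1L) {
      warning("activation tie in ROI '", roi, "'; choosing lowest index")
      best <- best[which.min(map$channel[best])]
    }
    best
  }
  i_cm <- pick("motor", "go_correct")
  i_ci <- pick("IFG", "nogo_correct")
  list(cm = map$channel[i_cm], ci = map$channel[i_ci],
       cm_activation = map$go_correct[i_cm],
       ci_activation = map$nogo_correct[i_ci])
}

#' Bar plot of per-electrode activation by condition
#'
#' Simple per-electrode visualization (no cortical surface rendering).
#'
#' @param map an `activation_map`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot_activation_map <- function(map, ...) {
  h <- t(as.matrix(map[, c("go_correct", "nogo_correct")]))
  mids <- graphics::barplot(h, beside = TRUE, names.arg = map$label,
                            las = 2, col = c("grey60", "firebrick"),
                            ylab = "HG activation (z)", ...)
  graphics::legend("topright", c("Go/Correct", "No-Go/Correct"),
                   fill = c("grey60", "firebrick"), bty = "n")
  invisible(mids)
}
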