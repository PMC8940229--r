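# Cross-patient statistics: Tukey-Kramer-corrected condition comparisons
# and rank-based age trends of the No-Go/Go ratios.

#' Cross-patient No-Go vs Go comparison with Tukey-Kramer correction
#'
#' Band-power peaks are pooled across patients (trial-level pooling, the
#' default) and the No-Go/Correct vs Go/Correct difference is tested per
#' (hemisphere, band) stratum. Correction uses the Tukey-Kramer
#' studentized-range procedure, which remains valid for the unequal group
#' sizes the 1:6 cue ratio produces. The default family is per band: the
#' (hemisphere x condition) cell means of one band form a one-way layout
#' with a pooled mean square error, and each hemisphere's condition
#' contrast is referred to the studentized range over that family.
#' `family = "global"` instead pools every (hemisphere x band x condition)
#' cell into a single family (use with care: peak variance differs
#' strongly between bands). An unadjusted Welch t-test accompanies every
#' contrast.
#'
#' @param peaks data.frame with columns `patient`, `hemisphere`, `band`,
#'   `outcome` (`go_correct` / `nogo_correct`), `peak`.
#' @param family `"band"` (default) or `"global"`.
#' @param per_patient_means if `TRUE`, patient-mean peaks replace trials
#'   as the analysis unit (sensitivity mode).
#' @param conf confidence level for the condition-mean CIs.
#' @return a `group_comparison` data.frame per stratum: condition means
#'   with CIs, Welch `t` and `p_uncorrected`, Tukey-Kramer `p_corrected`,
#'   `q` statistic, group sizes, family size `k`.
#' @export
compare_conditions <- function(peaks, family = c("band", "global"),
                               per_patient_means = FALSE, conf = 0.95) {
  family <- match.arg(family)
  need <- c("patient", "hemisphere", "band", "outcome", "peak")
  stopifnot(all(need %in% names(peaks)))
  peaks <- peaks[peaks$outcome %in% c("go_correct", "nogo_correct"), ]
  if (per_patient_means) {
    agg <- stats::aggregate(
      peak ~ patient + hemisphere + band + outcome, data = peaks, FUN = mean)
    peaks <- agg
  }
  strata <- unique(peaks[, c("hemisphere", "band")])
  res <- list()
  for (i in seq_len(nrow(strata))) {
    hemi <- strata$hemisphere[i]; band <- strata$band[i]
    fam <- switch(family,
      band = peaks[peaks$band == band, ],
      global = peaks)
    fam$cell <- interaction(fam$hemisphere, fam$band, fam$outcome,
                            drop = TRUE)
    k <- nlevels(fam$cell)
    n_tot <- nrow(fam)
    if (n_tot - k < 1L) { warning("stratum ", hemi, "/", band,
                                  " skipped: no residual df"); next }
    cell_means <- tapply(fam$peak, fam$cell, mean)
    mse <- sum((fam$peak - cell_means[fam$cell])^2) / (n_tot - k)
    df <- n_tot - k

    sg <- peaks$peak[peaks$hemisphere == hemi & peaks$band == band &
                       peaks$outcome == "go_correct"]
    sn <- peaks$peak[peaks$hemisphere == hemi & peaks$band == band &
                       peaks$outcome == "nogo_correct"]
    if (length(sg) < 2L || length(sn) < 2L) {
      warning("stratum ", hemi, "/", band,
              " skipped: fewer than 2 trials in a condition")
      next
    }
    q <- abs(mean(sn) - mean(sg)) /
      sqrt(mse / 2 * (1 / length(sn) + 1 / length(sg)))
    p_corr <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    wt <- stats::t.test(sn, sg)
    ci_half <- function(x) stats::qt(1 - (1 - conf) / 2, length(x) - 1L) *
      stats::sd(x) / sqrt(length(x))
    res[[length(res) + 1L]] <- data.frame(
      hemisphere = hemi, band = band,
      mean_go = mean(sg), ci_go = ci_half(sg),
      mean_nogo = mean(sn), ci_nogo = ci_half(sn),
      t = unname(wt$statistic), p_uncorrected = wt$p.value,
      q = q, p_corrected = p_corr,
      n_go = length(sg), n_nogo = length(sn), k = k,
      stringsAsFactors = FALSE
    )
  }
  if (length(res) == 0L) stop("no stratum had enough data")
  out <- do.call(rbind, res)
  class(out) <- c("group_comparison", class(out))
  out
}

#' Age trend of a per-patient ratio
#'
#' Spearman rank correlation of a No-Go/Go ratio (band power or PAC)
#' against patient age, two-sided. Rank-based, so robust at small n; the
#' sign of rho is the trend direction.
#'
#' @param ratios numeric vector, one ratio per patient.
#' @param ages numeric vector of matching length.
#' @param min_n minimum patients with the ratio defined (default 4).
#' @return list: `rho`, `p`, `n`, `direction` (`"decreasing"`,
#'   `"increasing"`, or `"flat"`); `rho` is NA with a warning when the
#'   ratios are constant.
#' @export
age_trend <- function(ratios, ages, min_n = 4L) {
  stopifnot(length(ratios) == length(ages))
  ok <- is.finite(ratios) & is.finite(ages)
  ratios <- ratios[ok]; ages <- ages[ok]
  if (length(ratios) < min_n)
    stop("need at least ", min_n, " patients with a defined ratio")
  if (stats::sd(ratios) == 0) {
    warning("constant ratios: trend undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(ratios),
                direction = "flat"))
  }
  ct <- suppressWarnings(
    stats::cor.test(ratios, ages, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  list(rho = rho, p = ct$p.value, n = length(ratios),
       direction = if (rho < 0) "decreasing" else
         if (rho > 0) "increasing" else "flat")
}
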