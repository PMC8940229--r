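# Run-level configuration and the end-to-end pipeline.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain. Defaults follow the
#' acquisition and analysis settings of the clinical protocol the package
#' models: 1.2 kHz sampling, notches at 60/120/180 Hz, 4th-order
#' zero-phase Butterworth high-gamma envelope, 2 s epochs around the cue,
#' 3 Hz wavelet steps, 5 ms STFT hop, 1000 permutation shuffles at
#' alpha = 0.05.
#'
#' @param ... named overrides of any default element.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sampling_rate = 1200,
    notch_freqs = c(60, 120, 180),
    notch_q = 30,
    hg_band = c(70, 200),
    butter_order = 4,
    epoch_window = c(-1, 1),
    per_trial_baseline = FALSE,
    wavelet_freqs = seq(2, 200, by = 3),
    wavelet_cycles = 6,
    stft_window_s = 0.5,
    stft_hop_s = 0.005,
    bands = list(theta = c(4, 8), beta = c(12, 40), hg = c(70, 200)),
    pac_phase_centers = seq(2, 20, by = 3),
    pac_phase_width = 3,
    pac_amp_range = c(40, 200),
    pac_amp_width = 20,
    pac_amp_hop = 10,
    n_shuffles = 1000,
    alpha = 0.05,
    n_boot = 2000,
    family = "band",
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips losslessly through the file.
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config`: invisibly, `path`; `read_config`: the
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  lst <- lapply(raw, function(v) if (is.list(v)) lapply(v, unlist) else unlist(v))
  do.call(pipeline_config, lst)
}

.pac_bins_from_config <- function(config) {
  pac_bins(phase_centers = config$pac_phase_centers,
           phase_width = config$pac_phase_width,
           amp_range = config$pac_amp_range,
           amp_width = config$pac_amp_width,
           amp_hop = config$pac_amp_hop)
}

#' Single-subject power analysis
#'
#' Preprocess, map high-gamma activation, select Cm/Ci, extract STFT band
#' peaks on Ci, and compute the No-Go/Go power ratios.
#'
#' @param session an `ecog_session` with classified events.
#' @param config a [pipeline_config()].
#' @param seed integer seed (bootstrap CIs).
#' @return list: `map`, `selection`, `peaks` (with `hemisphere` column),
#'   `ratios`, `epochs_raw` (for reuse by the PAC stage).
#' @export
subject_power_analysis <- function(session, config = pipeline_config(),
                                   seed = NULL) {
  pre <- preprocess_session(session, config$notch_freqs, config$notch_q)
  hg <- hg_envelope_epochs(pre, config$hg_band, config$epoch_window,
                           per_trial = config$per_trial_baseline)
  map <- hg_activation_map(hg)
  sel <- select_electrodes(map)
  epochs_raw <- epoch_session(pre, config$epoch_window)
  peaks <- stft_band_peaks(epochs_raw, sel$ci, config$bands,
                           config$stft_window_s, config$stft_hop_s)
  peaks$hemisphere <- session$channels$hemisphere[sel$ci]
  ratios <- power_ratio(peaks, n_boot = config$n_boot, seed = seed)
  list(map = map, selection = sel, peaks = peaks, ratios = ratios,
       epochs_raw = epochs_raw)
}

#' Single-subject PAC analysis on the selected IFG electrode
#'
#' Comodulograms for both conditions, permutation masks, and the
#' No-Go/Go PAC ratio map.
#'
#' @param epochs_raw raw `ecog_epochs` (from [subject_power_analysis()]).
#' @param ci selected IFG electrode index.
#' @param config a [pipeline_config()].
#' @param seed integer seed for the permutation draws.
#' @return list: `grid_go`, `grid_nogo` (masked), `mask_go`, `mask_nogo`,
#'   `ratio` (a `pac_ratio_map`), `median_ratio`.
#' @export
subject_pac_analysis <- function(epochs_raw, ci,
                                 config = pipeline_config(), seed = NULL) {
  bins <- .pac_bins_from_config(config)
  decomp <- pac_decompose(epochs_raw, ci, bins)
  g_go <- pac_grid(epochs_raw, ci, "go", bins, decomp = decomp)
  g_ng <- pac_grid(epochs_raw, ci, "nogo", bins, decomp = decomp)
  seeds <- if (is.null(seed)) c(NA, NA) else seed + c(0L, 1L)
  m_go <- permutation_mask(epochs_raw, ci, "go", bins,
                           n_shuffles = config$n_shuffles,
                           alpha = config$alpha,
                           seed = if (is.null(seed)) NULL else seeds[1],
                           decomp = decomp)
  m_ng <- permutation_mask(epochs_raw, ci, "nogo", bins,
                           n_shuffles = config$n_shuffles,
                           alpha = config$alpha,
                           seed = if (is.null(seed)) NULL else seeds[2],
                           decomp = decomp)
  g_go <- apply_pac_mask(g_go, m_go)
  g_ng <- apply_pac_mask(g_ng, m_ng)
  ratio <- pac_ratio(g_ng, g_go)
  list(grid_go = g_go, grid_nogo = g_ng, mask_go = m_go, mask_nogo = m_ng,
       ratio = ratio, median_ratio = median_defined_ratio(ratio))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> preprocess -> activation/selection -> band power ->
#' (optional) PAC -> group statistics, with every artifact written as TSV
#' under `out_dir` together with a JSON manifest (versions, seed, config
#' hash) that makes the run reproducible.
#'
#' @param cohort list of [subject_profile()]s (default: [default_cohort()]).
#' @param task a [task_config()].
#' @param sim a [sim_config()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @param seed master seed; per-subject and per-stage seeds are derived
#'   from it and recorded in the manifest.
#' @param stages subset of `c("power", "pac", "group")`.
#' @return invisibly, a list with per-subject results, group tables, and
#'   the manifest.
#' @export
run_pipeline <- function(cohort = default_cohort(),
                         task = task_config(), sim = sim_config(),
                         config = pipeline_config(),
                         out_dir = tempfile("ecogng_run"),
                         seed = config$seed,
                         stages = c("power", "pac", "group")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subject_seeds <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, 3L * length(cohort)),
           ncol = 3L))
  per_subject <- vector("list", length(cohort))
  all_peaks <- list()
  all_ratios <- list()
  pac_medians <- rep(NA_real_, length(cohort))
  for (i in seq_along(cohort)) {
    prof <- cohort[[i]]
    simres <- .stage("simulate",
                     simulate_session(prof, task, sim,
                                      seed = subject_seeds[i, 1]))
    pw <- .stage("power",
                 subject_power_analysis(simres$session, config,
                                        seed = subject_seeds[i, 2]))
    pw$peaks$patient <- prof$subject_id
    all_peaks[[i]] <- pw$peaks
    r <- pw$ratios
    r$patient <- prof$subject_id
    r$age <- prof$age
    r$hemisphere <- prof$grid_side
    all_ratios[[i]] <- r
    pacres <- NULL
    if ("pac" %in% stages) {
      pacres <- .stage("pac",
                       subject_pac_analysis(pw$epochs_raw, pw$selection$ci,
                                            config,
                                            seed = subject_seeds[i, 3]))
      pac_medians[i] <- pacres$median_ratio
    }
    utils::write.table(pw$map, file.path(out_dir,
                       sprintf("%s_activation.tsv", prof$subject_id)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    per_subject[[i]] <- list(profile = prof, truth = simres$truth,
                             power = pw[c("map", "selection", "ratios")],
                             pac = pacres)
  }
  peaks <- do.call(rbind, all_peaks)
  ratios <- do.call(rbind, all_ratios)
  utils::write.table(peaks, file.path(out_dir, "band_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ratios, file.path(out_dir, "power_ratios.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comparison <- NULL
  trends <- NULL
  if ("group" %in% stages) {
    comparison <- .stage("group",
                         compare_conditions(peaks, family = config$family))
    utils::write.table(comparison, file.path(out_dir, "group_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    trends <- .stage("group", {
      out <- list()
      for (hemi in unique(ratios$hemisphere)) {
        for (b in unique(ratios$band)) {
          sub <- ratios[ratios$hemisphere == hemi & ratios$band == b &
                          ratios$defined, ]
          if (nrow(sub) >= 4L) {
            tr <- age_trend(sub$ratio, sub$age)
            out[[length(out) + 1L]] <- data.frame(
              hemisphere = hemi, band = b, rho = tr$rho, p = tr$p,
              n = tr$n, direction = tr$direction, stringsAsFactors = FALSE)
          }
        }
      }
      if (length(out) > 0) do.call(rbind, out) else NULL
    })
    if (!is.null(trends))
      utils::write.table(trends, file.path(out_dir, "age_trends.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(
    package = "ecogng",
    package_version = as.character(utils::packageVersion("ecogng")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    subject_seeds = apply(subject_seeds, 1L, paste, collapse = ","),
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_subjects = length(cohort),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(per_subject = per_subject, peaks = peaks, ratios = ratios,
                 comparison = comparison, trends = trends,
                 pac_medians = pac_medians, manifest = manifest,
                 out_dir = out_dir))
}
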