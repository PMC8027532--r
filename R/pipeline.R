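default_config <- function() {
  list(
    cohort = list(
      groups = list(
        list(label = "younger", n_subjects = 10, beta_mean = 1.8,
             beta_sd = 0.2, irregularity_mix = 0.1, alpha_amp = 0.5,
             alpha_freq_hz = 10),
        list(label = "older", n_subjects = 10, beta_mean = 1.5,
             beta_sd = 0.2, irregularity_mix = 0.4, alpha_amp = 0.5,
             alpha_freq_hz = 10)),
      n_channels = 96, fs = 512, duration_s = 60,
      effect_channels = NULL),
    preprocessing = list(epoch_len_s = 20, lowpass_hz = 30,
                         amp_thresh = 150, jp_sd = 5,
                         condition = "both"),
    mse = list(m = 2, r_frac = 0.5, scales = 1:20,
               r_mode = "sd_scale1"),
    welch = list(win_len = 1024, overlap_frac = 0.5, fmin = 1,
                 fmax = 30),
    surrogates = list(n_surrogates = 19, max_iter = 100),
    tfce = list(E = 0.66, H = 2, n_perm = 2000, alpha = 0.05),
    robust = list(n_boot = 2000, trim = 0.2, short_scales = 1:5,
                  long_scales = 16:20),
    seed = 1L)
}

#' Validate and complete a pipeline configuration
#'
#' Fills every omitted field with the pipeline defaults (m = 2, r = 0.5,
#' scales 1-20, E = 0.66, H = 2, 2000 permutations, 20-s epochs, 30-Hz
#' low-pass, ±150 µV amplitude and 5-SD joint-probability rejection,
#' IAAFT max 100 iterations) and reports every violation at once. Unknown
#' keys at any level are rejected.
#'
#' @param raw named list (e.g. parsed from JSON/YAML); an empty list
#'   yields the pure-defaults configuration.
#' @return A completed `pipeline_config` list.
#' @export
validate_config <- function(raw = list()) {
  defaults <- default_config()
  errors <- character(0)
  bad_top <- setdiff(names(raw), names(defaults))
  if (length(bad_top))
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(bad_top, collapse = ", ")))
  cfg <- defaults
  for (sec in intersect(names(raw), names(defaults))) {
    if (sec == "seed") { cfg$seed <- raw$seed; next }
    bad <- setdiff(names(raw[[sec]]), names(defaults[[sec]]))
    if (length(bad))
      errors <- c(errors, paste0("unknown key(s) in ", sec, ": ",
                                 paste(bad, collapse = ", ")))
    for (k in intersect(names(raw[[sec]]), names(defaults[[sec]])))
      cfg[[sec]][[k]] <- raw[[sec]][[k]]
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1,
      "seed: must be a single integer")
  chk(cfg$mse$m >= 1, "mse.m: must be >= 1")
  chk(cfg$mse$r_frac > 0, "mse.r_frac: must be positive")
  chk(all(cfg$mse$scales >= 1) &&
        !is.unsorted(cfg$mse$scales, strictly = TRUE),
      "mse.scales: must be strictly increasing positive integers")
  chk(cfg$mse$r_mode %in% c("sd_scale1", "sd_per_scale", "absolute"),
      "mse.r_mode: invalid value")
  chk(cfg$preprocessing$epoch_len_s > 0,
      "preprocessing.epoch_len_s: must be positive")
  chk(cfg$preprocessing$lowpass_hz > 0,
      "preprocessing.lowpass_hz: must be positive")
  chk(cfg$preprocessing$amp_thresh > 0,
      "preprocessing.amp_thresh: must be positive")
  chk(cfg$preprocessing$jp_sd > 0, "preprocessing.jp_sd: must be positive")
  chk(cfg$preprocessing$condition %in%
        c("both", "eyes_open", "eyes_closed"),
      "preprocessing.condition: invalid value")
  chk(cfg$welch$win_len >= 8, "welch.win_len: must be >= 8")
  chk(cfg$welch$overlap_frac >= 0 && cfg$welch$overlap_frac < 1,
      "welch.overlap_frac: must be in [0, 1)")
  chk(cfg$welch$fmin > 0 && cfg$welch$fmax > cfg$welch$fmin,
      "welch.fmin/fmax: need 0 < fmin < fmax")
  chk(cfg$surrogates$n_surrogates >= 1,
      "surrogates.n_surrogates: must be >= 1")
  chk(cfg$surrogates$max_iter >= 1, "surrogates.max_iter: must be >= 1")
  chk(cfg$tfce$E > 0, "tfce.E: must be positive")
  chk(cfg$tfce$H > 0, "tfce.H: must be positive")
  chk(cfg$tfce$n_perm >= 1, "tfce.n_perm: must be >= 1")
  chk(cfg$tfce$alpha > 0 && cfg$tfce$alpha < 1,
      "tfce.alpha: must be in (0, 1)")
  chk(cfg$robust$n_boot >= 1, "robust.n_boot: must be >= 1")
  chk(cfg$robust$trim >= 0 && cfg$robust$trim < 0.5,
      "robust.trim: must be in [0, 0.5)")
  chk(cfg$cohort$fs > 0, "cohort.fs: must be positive")
  chk(cfg$cohort$duration_s >= 20, "cohort.duration_s: must be >= 20")
  chk(cfg$cohort$n_channels >= 2, "cohort.n_channels: must be >= 2")
  for (g in cfg$cohort$groups) {
    chk(g$n_subjects >= 2,
        sprintf("cohort.groups[%s].n_subjects: must be >= 2", g$label))
    chk(g$irregularity_mix >= 0 && g$irregularity_mix <= 1,
        sprintf("cohort.groups[%s].irregularity_mix: must be in [0, 1]",
                g$label))
  }
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a cohort, preprocess every recording, compute MSE
#' and spectral maps, contrast the first two groups with TFCE permutation
#' testing, and run the robust topography and slope-entropy linkage
#' analyses. All tables plus a JSON parameter/seed summary are written
#' under `out_dir`; reruns with the same config are identical given the
#' same seed.
#'
#' @param config a `pipeline_config` from [validate_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param recordings optional list of `eeg_recording` objects to analyse
#'   instead of a simulated cohort.
#' @return List with `qc`, `mse_maps`, `psd_maps`, `slope_maps`,
#'   `contrast` (`tfce_result`), `proportions`, `topography`, `linkage`,
#'   `config`.
#' @export
run_pipeline <- function(config = validate_config(), out_dir = NULL,
                         recordings = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.null(recordings)) {
    cohort <- stage("simulate", {
      spec <- cohort_spec(config$cohort$groups, config$cohort$n_channels,
                          config$cohort$fs, config$cohort$duration_s,
                          config$cohort$effect_channels, config$seed)
      generate_cohort(spec)
    })
    recordings <- cohort$recordings
    montage <- cohort$montage
  } else {
    montage <- recordings[[1]]$montage
  }
  pp <- config$preprocessing
  use <- if (pp$condition == "both") recordings else
    Filter(function(r) r$condition == pp$condition, recordings)
  if (!length(use)) stop("[stage preprocess] no recordings in condition ",
                         pp$condition)
  ess <- stage("preprocess", lapply(use, preprocess,
                                    lowpass_hz = pp$lowpass_hz,
                                    epoch_len_s = pp$epoch_len_s,
                                    amp_thresh = pp$amp_thresh,
                                    jp_sd = pp$jp_sd))
  qc <- do.call(rbind, lapply(ess, qc_table))
  params <- mse_params(config$mse$m, config$mse$r_frac,
                       config$mse$scales, config$mse$r_mode)
  mse_maps <- stage("mse", lapply(ess, subject_mse, params = params))
  spectra <- stage("psd", lapply(ess, function(es)
    subject_spectra(es, config$welch$win_len, config$welch$overlap_frac,
                    config$welch$fmin, config$welch$fmax)))
  psd_maps <- lapply(spectra, `[[`, "psd")
  slope_maps <- lapply(spectra, `[[`, "slope")

  groups <- vapply(mse_maps, function(m) as.character(m$group),
                   character(1))
  glev <- unique(groups)
  contrast <- proportions <- NULL
  if (length(glev) >= 2) {
    contrast <- stage("contrast", permutation_test(
      mse_maps[groups == glev[1]], mse_maps[groups == glev[2]],
      montage$adjacency, E = config$tfce$E, H = config$tfce$H,
      n_perm = config$tfce$n_perm, alpha = config$tfce$alpha,
      seed = config$seed))
    proportions <- proportion_significant(contrast, config$tfce$alpha,
                                          montage)
  }
  cells <- stage("topography", region_hemisphere_cells(mse_maps, montage))
  topo <- if (nrow(cells) >= 10)
    stage("topography", ww_trimmed_bootstrap(cells, config$robust$n_boot,
                                             config$robust$trim,
                                             seed = config$seed))
  else NULL
  linkage <- stage("linkage", slope_mse_linkage(
    slope_maps, mse_maps, config$robust$short_scales,
    config$robust$long_scales))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(tab, name) if (!is.null(tab))
      write.table(tab, file.path(out_dir, name), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    wr(qc, "qc.tsv")
    wr(results_table(mse_maps), "mse.tsv")
    wr(results_table(psd_maps), "psd.tsv")
    wr(topo, "topography.tsv")
    wr(proportions, "proportions.tsv")
    wr(linkage, "linkage.tsv")
    jsonlite::write_json(
      list(config = unclass(config),
           package_version =
             as.character(utils::packageVersion("eegcomplexity"))),
      file.path(out_dir, "run_summary.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(qc = qc, mse_maps = mse_maps, psd_maps = psd_maps,
       slope_maps = slope_maps, contrast = contrast,
       proportions = proportions, topography = topo, linkage = linkage,
       config = config)
}
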