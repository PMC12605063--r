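# Run configuration and the end-to-end pipeline: simulate -> preprocess ->
# ERP statistics -> band dynamics -> behavioural statistics -> accuracy
# GLMM, with a structured report.

#' Default run configuration
#'
#' Defaults mirror the recording and analysis parameters of the protocol:
#' 500 Hz acquisition downsampled to 250 Hz, 45-55 Hz notch and 1-45 Hz
#' band-pass, 100 uV bad-channel threshold, 5 presentations of each of the
#' 42 chord + 14 click stimuli with 200-300 ms ISIs, GFP windows of
#' +/- 10 ms around the three most prominent peaks, 800 permutations at
#' alpha 0.05, DFA over 5-50 s, and a gamma-amplitude accuracy model.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_subjects Number of simulated subjects.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1, n_subjects = 30) {
  structure(list(
    seed = seed,
    n_subjects = n_subjects,
    sample_rate = 500,
    target_rate = 250,
    repetitions = 5,
    n_neutral = 14,
    snr = 1,
    notch_hz = c(45, 55),
    bandpass_hz = c(1, 45),
    bad_threshold_uv = 100,
    run_ica = TRUE,
    n_peaks = 3,
    window_half_width_ms = 10,
    n_perm = 800,
    cluster_alpha = 0.05,
    dfa_range_s = c(5, 50),
    dfa_n_windows = 10,
    band_channels = NULL,
    glmm_band = "gamma",
    glmm_predictor = "amplitude",
    contrasts = list(c("dissonant", "neutral"),
                     c("consonant", "neutral"),
                     c("consonant", "dissonant"))
  ), class = c("run_config", "list"))
}

#' Validate a run configuration
#'
#' @param config A list of configuration values.
#' @return The config (classed), or an error naming the missing/invalid
#'   field.
#' @export
validate_config <- function(config) {
  required <- names(default_config())
  missing <- setdiff(required, names(config))
  stop_if_not(length(missing) == 0, "config is missing field(s): %s",
              paste(missing, collapse = ", "))
  stop_if_not(config$n_subjects >= 1, "config field n_subjects must be >= 1")
  stop_if_not(config$target_rate <= config$sample_rate,
              "config field target_rate exceeds sample_rate")
  stop_if_not(config$n_perm >= 1, "config field n_perm must be >= 1")
  structure(config, class = c("run_config", "list"))
}

#' Read a run configuration from JSON
#'
#' Fields present in the file override the defaults.
#'
#' @param path JSON file.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (nm in names(user)) {
    cfg[[nm]] <- if (nm == "contrasts") {
      lapply(seq_len(nrow(user$contrasts)), function(i) user$contrasts[i, ])
    } else user[[nm]]
  }
  validate_config(cfg)
}

# deterministic per-stage, per-subject seed stream (kept below 2^31)
derive_seed <- function(seed, stage, i = 0) {
  (seed * 1009 + stage * 9973 + i * 101) %% .Machine$integer.max
}

#' Simulate a multi-subject study
#'
#' Builds the stimulus set once, draws one randomised schedule per subject,
#' and simulates one recording per subject from a shared ground truth.
#'
#' @param config A `run_config`.
#' @param truth A `ground_truth` (default built from `config$snr`).
#' @return List: `stimuli`, `montage`, `truth`, and `subjects` — a list of
#'   per-subject lists with `id`, `schedule`, `recording`.
#' @export
simulate_study <- function(config = default_config(), truth = NULL) {
  config <- validate_config(config)
  truth <- truth %||% default_ground_truth(snr = config$snr)
  stimuli <- build_stimulus_set(n_neutral = config$n_neutral)
  montage <- standard_montage()
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    sched <- make_schedule(stimuli, repetitions = config$repetitions,
                           seed = derive_seed(config$seed, 1, i))
    rec <- simulate_recording(montage, sched, truth,
                              sample_rate = config$sample_rate,
                              seed = derive_seed(config$seed, 2, i))
    list(id = sprintf("S%02d", i), schedule = sched, recording = rec)
  })
  list(stimuli = stimuli, montage = montage, truth = truth, subjects = subjects)
}

#' Run the end-to-end pipeline on simulated data
#'
#' Executes simulate -> preprocess -> GFP window selection -> cluster
#' contrasts -> band amplitude/DFA -> behavioural statistics -> accuracy
#' GLMM, and optionally writes a report bundle (JSON + TSV) to `out_dir`.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param stages Character subset of `c("erp", "bands", "behav", "glmm")`;
#'   preprocessing always runs.
#' @return A `pipeline_report` list with one entry per stage plus the
#'   resolved config.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         stages = c("erp", "bands", "behav", "glmm")) {
  config <- validate_config(config)
  t0 <- Sys.time()
  study <- simulate_study(config)
  log_stage("simulate", sprintf("%d subjects, %d trials each",
                                length(study$subjects), nrow(study$subjects[[1]]$schedule)))
  prep <- lapply(seq_along(study$subjects), function(i) {
    s <- study$subjects[[i]]
    preprocess_recording(s$recording, target_rate = config$target_rate,
                         notch_hz = config$notch_hz,
                         bandpass_hz = config$bandpass_hz,
                         bad_threshold_uv = config$bad_threshold_uv,
                         run_ica = config$run_ica,
                         seed = derive_seed(config$seed, 3, i))
  })
  log_stage("preprocess", sprintf("%d recordings", length(prep)))
  epochs_list <- lapply(prep, `[[`, "epochs")
  report <- list(config = unclass(config))

  if ("erp" %in% stages) {
    ga <- Reduce(`+`, lapply(epochs_list, grand_average)) / length(epochs_list)
    attr(ga, "times_ms") <- epochs_list[[1]]$times_ms
    curve <- gfp_curve(ga)
    windows <- select_windows(curve, n_peaks = config$n_peaks,
                              half_width_ms = config$window_half_width_ms)
    adjacency <- channel_adjacency(study$montage)
    contrasts <- list()
    for (ct in config$contrasts) {
      for (w in seq_len(nrow(windows))) {
        win <- c(windows$start_ms[w], windows$end_ms[w])
        maps_a <- window_mean_maps(epochs_list, ct[1], win)
        maps_b <- window_mean_maps(epochs_list, ct[2], win)
        res <- cluster_permutation(maps_a, maps_b, adjacency,
                                   n_perm = config$n_perm,
                                   cluster_alpha = config$cluster_alpha,
                                   seed = derive_seed(config$seed, 4, w))
        contrasts[[sprintf("%s_vs_%s_%g-%gms", ct[1], ct[2], win[1], win[2])]] <- res
      }
    }
    report$erp <- list(gfp = curve, windows = windows, contrasts = contrasts)
    log_stage("erp", sprintf("%d windows, %d contrasts", nrow(windows),
                             length(config$contrasts)))
  }

  if (any(c("bands", "glmm", "behav") %in% stages)) {
    channels <- config$band_channels %||% study$montage$name
    band_stats <- lapply(seq_along(prep), function(i) {
      st <- envelope_stats(prep[[i]]$recording,
                           channels = intersect(channels, prep[[i]]$recording$ch_names),
                           window_range_s = config$dfa_range_s,
                           n_windows = config$dfa_n_windows)
      cbind(subject = study$subjects[[i]]$id, subject_band_summary(st))
    })
    band_summary <- do.call(rbind, band_stats)
    report$bands <- band_summary
    log_stage("bands", sprintf("%d subject x band summaries", nrow(band_summary)))

    measure <- band_summary[band_summary$band == config$glmm_band,
                            config$glmm_predictor]
    neural <- stats::setNames(as.numeric(scale(measure)),
                              unique(band_summary$subject))
    items <- unique(study$subjects[[1]]$schedule$stimulus_id)
    item_effects <- with_seed(derive_seed(config$seed, 5), {
      stats::setNames(stats::rnorm(length(items), 0,
                                   study$truth$behaviour$accuracy_model$sd_item), items)
    })
    trials <- do.call(rbind, lapply(seq_along(study$subjects), function(i) {
      simulate_behaviour(study$subjects[[i]]$schedule, study$truth,
                         neural = neural[[i]],
                         subject = study$subjects[[i]]$id,
                         seed = derive_seed(config$seed, 6, i),
                         item_effects = item_effects)
    }))
    report$trials <- trials

    if ("behav" %in% stages) {
      report$behav <- behavioural_report(trials,
                                         seed = derive_seed(config$seed, 7))
      log_stage("behav", sprintf("association p = %.3g", report$behav$association$p))
    }
    if ("glmm" %in% stages) {
      full <- fit_mixed_logit(trials, neural = neural, spec = glmm_spec())
      reduced <- fit_mixed_logit(trials, neural = neural,
                                 spec = glmm_spec(interaction = FALSE))
      report$glmm <- list(fit = full,
                          lrt = likelihood_ratio_test(full, reduced),
                          odds_ratios = odds_ratio_table(full))
      log_stage("glmm", sprintf("LRT p = %.3g", report$glmm$lrt$p))
    }
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- c("pipeline_report", "list")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Write a pipeline report bundle
#'
#' JSON summary plus TSV tables (GFP curve, windows, cluster results, band
#' summaries, trial table).
#'
#' @param report A `pipeline_report`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  summary <- list(config = report$config, elapsed_s = report$elapsed_s)
  if (!is.null(report$erp)) {
    tsv(report$erp$gfp, "gfp.tsv")
    tsv(report$erp$windows, "windows.tsv")
    cl <- do.call(rbind, lapply(names(report$erp$contrasts), function(nm) {
      df <- as.data.frame(report$erp$contrasts[[nm]])
      if (nrow(df)) cbind(contrast = nm, df) else NULL
    }))
    if (!is.null(cl)) tsv(cl, "clusters.tsv")
    summary$windows <- report$erp$windows
  }
  if (!is.null(report$bands)) tsv(report$bands, "bands.tsv")
  if (!is.null(report$trials)) tsv(report$trials, "trials.tsv")
  if (!is.null(report$behav)) {
    summary$behav <- list(association_p = report$behav$association$p,
                          kruskal = report$behav$kruskal,
                          rt_means = as.list(report$behav$rt_means))
  }
  if (!is.null(report$glmm)) {
    tsv(cbind(report$glmm$fit$coefficients,
              report$glmm$odds_ratios[, c("or", "ci_low", "ci_high")]),
        "glmm.tsv")
    summary$glmm_lrt <- report$glmm$lrt
  }
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
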