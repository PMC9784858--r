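# End-to-end orchestration: preprocess -> features -> rank -> train ->
# predict -> evaluate, with a validated config and artifacts on disk.

.config_schema <- list(
  seed = NULL,
  out_dir = NULL,
  input = c("edf", "channel", "hypnogram", "window_start_s", "window_end_s"),
  synth = c("n", "counts", "separation", "noise_sd", "spindle_rate"),
  wavelet = c("wtd_levels", "wpt_levels", "threshold_rule"),
  features = c("msen_tau", "denoise"),
  selection = c("n_bins"),
  classifier = c("k1", "k2", "Const", "cv_folds"),
  holdout = c("n_repeats", "test_fraction", "stratify")
)

#' Default pipeline configuration
#'
#' Nested list of every tunable pipeline parameter with its default.
#' Unknown keys are rejected by [run_pipeline()] before any computation.
#'
#' @return named list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "sleepcascade_out",
    input = list(),                       # empty: use the synthetic generator
    synth = list(n = 200L, separation = 1),
    wavelet = list(wtd_levels = 7L, wpt_levels = 7L, threshold_rule = "sure"),
    features = list(msen_tau = 11L, denoise = TRUE),
    selection = list(n_bins = 10L),
    classifier = list(k1 = 32L, k2 = 30L, Const = 1, cv_folds = 10L),
    holdout = list(n_repeats = 5L, test_fraction = 0.1, stratify = TRUE)
  )
}

#' @keywords internal
.validate_config <- function(config) {
  base <- default_pipeline_config()
  bad <- setdiff(names(config), names(.config_schema))
  if (length(bad) > 0L)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in names(config)) {
    allowed <- .config_schema[[sec]]
    if (is.null(allowed)) next
    extra <- setdiff(names(config[[sec]]), allowed)
    if (length(extra) > 0L)
      stop("unknown config key(s) in '", sec, "': ",
           paste(extra, collapse = ", "))
  }
  for (sec in names(base)) {
    if (is.list(base[[sec]])) {
      for (k in names(config[[sec]])) base[[sec]][[k]] <- config[[sec]][[k]]
      if (sec == "input") base[[sec]] <- config[[sec]] %||% list()
      if (sec == "synth" && !is.null(config[[sec]]$counts))
        base[[sec]]$counts <- config[[sec]]$counts
    } else if (!is.null(config[[sec]])) {
      base[[sec]] <- config[[sec]]
    }
  }
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full classification pipeline
#'
#' Loads epochs (from an EDF recording plus hypnogram if configured,
#' otherwise from the synthetic generator), extracts the 51-feature table,
#' evaluates the cascade by repeated stratified holdout (features are
#' ranked on each training split only), refits a final model on all
#' epochs, and writes every artifact to `config$out_dir`:
#' `features.csv`, `ranking.csv`, `metrics.csv`, `confusion.csv`,
#' `hypnogram_pred.csv` (true vs predicted stage per epoch),
#' `model.rds`, and `config_used.txt` (the full config with the seed, for
#' provenance).
#'
#' @param config nested list as from [default_pipeline_config()]; partial
#'   configs are completed with defaults, unknown keys are an error.
#' @param dataset optional pre-built `sleep_dataset` (overrides input/synth
#'   config).
#' @param verbose print per-stage progress to stderr (default TRUE).
#' @return invisibly, a list with `dataset`, `features`, `holdout`,
#'   `model`, `config`.
#' @export
run_pipeline <- function(config = list(), dataset = NULL, verbose = TRUE) {
  cfg <- .validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(dataset)) {
    if (!is.null(cfg$input$edf)) {
      say("[input] reading EDF %s", cfg$input$edf)
      rec <- read_edf_signal(cfg$input$edf, cfg$input$channel %||% "EEG Fpz-Cz")
      hyp <- read_hypnogram(cfg$input$hypnogram)
      win <- if (!is.null(cfg$input$window_start_s))
        c(cfg$input$window_start_s, cfg$input$window_end_s) else NULL
      dataset <- segment_epochs(rec, hyp, window = win)
    } else {
      say("[input] synthesizing %s epochs (seed %d)",
          if (!is.null(cfg$synth$counts)) "per-stage" else cfg$synth$n,
          cfg$seed)
      params <- stage_synthesis_params(
        separation = cfg$synth$separation %||% 1,
        noise_sd = cfg$synth$noise_sd %||% 1,
        spindle_rate = cfg$synth$spindle_rate %||% 3)
      dataset <- synth_dataset(counts = cfg$synth$counts,
                               n = cfg$synth$n %||% 200L,
                               params = params, seed = cfg$seed)
    }
  }

  say("[features] extracting 51 features from %d epochs", nrow(dataset$epochs))
  feats <- extract_feature_table(dataset, denoise = cfg$features$denoise,
                                 verbose = verbose)
  utils::write.csv(feats, file.path(cfg$out_dir, "features.csv"),
                   row.names = FALSE)

  say("[evaluate] repeated holdout (%d repeats)", cfg$holdout$n_repeats)
  x <- feats[feature_names()]
  ho <- repeated_holdout(x, feats$stage,
                         n_repeats = cfg$holdout$n_repeats,
                         test_fraction = cfg$holdout$test_fraction,
                         seed = cfg$seed,
                         stratify = cfg$holdout$stratify,
                         k1 = cfg$classifier$k1, k2 = cfg$classifier$k2,
                         Const = cfg$classifier$Const,
                         n_bins = cfg$selection$n_bins,
                         cv_folds = 0L)

  say("[train] final model on all epochs")
  model <- cascade_svm(x, feats$stage,
                       k1 = cfg$classifier$k1, k2 = cfg$classifier$k2,
                       Const = cfg$classifier$Const,
                       n_bins = cfg$selection$n_bins,
                       seed = cfg$seed, cv_folds = cfg$classifier$cv_folds)
  utils::write.csv(model$ranking, file.path(cfg$out_dir, "ranking.csv"),
                   row.names = FALSE)
  saveRDS(model, file.path(cfg$out_dir, "model.rds"))

  pred <- predict(model, x)
  utils::write.csv(
    data.frame(epoch_index = dataset$index,
               true = as.character(feats$stage),
               predicted = as.character(pred)),
    file.path(cfg$out_dir, "hypnogram_pred.csv"), row.names = FALSE)

  metrics <- data.frame(
    metric = c("mean_accuracy", "sd_accuracy",
               "mean_n1_accuracy", "sd_n1_accuracy"),
    value = c(ho$mean_accuracy, ho$sd_accuracy,
              ho$mean_n1_accuracy, ho$sd_n1_accuracy))
  utils::write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(ho$last$matrix),
                   file.path(cfg$out_dir, "confusion.csv"), row.names = FALSE)

  cfg_txt <- file.path(cfg$out_dir, "config_used.txt")
  writeLines(deparse(cfg), cfg_txt)

  say("[done] holdout accuracy %.3f (sd %.3f), N1 accuracy %.3f",
      ho$mean_accuracy, ho$sd_accuracy, ho$mean_n1_accuracy)
  invisible(list(dataset = dataset, features = feats, holdout = ho,
                 model = model, config = cfg))
}
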