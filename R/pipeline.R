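# Single entry point chaining labelling and the prediction grid, with
# config echoing, logging and report files mirroring the study's tables.

#' Assemble a pipeline run configuration
#'
#' @param cohort path to the cohort CSV (see [read_cohort()]).
#' @param out output directory (created; must not silently overwrite a
#'   previous run's files).
#' @param metrics optional path to a wide normalized metric table CSV
#'   (`dataset_id` + ten metric columns) enabling feature set 5.
#' @param srd optional named list overriding [srd_thresholds()].
#' @param feature_sets list of integer vectors.
#' @param models,outcomes model families and outcome scales to run.
#' @param seed integer seed.
#' @param nonresponder `c(participant_id, side)` of the designated
#'   unexpected non-responder.
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort, out, metrics = NULL, srd = NULL,
                       feature_sets = list(1, 2, 6, c(1, 2), c(1, 6)),
                       models = c("linreg", "tree", "knn", "rf"),
                       outcomes = c("arat", "bbt", "nhpt"),
                       seed = 17L, nonresponder = c("02", "right")) {
  cfg <- list(cohort = cohort, out = out, metrics = metrics, srd = srd,
              feature_sets = feature_sets, models = models,
              outcomes = outcomes, seed = as.integer(seed),
              nonresponder = nonresponder)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Recognized fields match the arguments of [run_config()];
#' `feature_sets` entries may be comma-separated strings such as
#' `"1,6"`.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    msr_error(sprintf("config file not found: %s", path),
              "msrehab_configuration_error")
  }
  y <- yaml::read_yaml(path)
  fs <- y$feature_sets
  if (!is.null(fs)) {
    fs <- lapply(fs, function(x) {
      as.integer(strsplit(as.character(x), ",")[[1L]])
    })
  }
  args <- list(cohort = y$cohort, out = y$out)
  for (nm in c("metrics", "srd", "models", "outcomes", "seed",
               "nonresponder")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(fs)) args$feature_sets <- fs
  do.call(run_config, args)
}

#' Run the full labelling and prediction pipeline
#'
#' Validates the configuration, labels the cohort against the SRDs, runs
#' the feature-set-by-model grid under leave-one-subject-out
#' cross-validation, and writes `labels.csv`, `grid.csv` (with the
#' frozen hyperparameters and package version in `#` header comments),
#' `best_models.json` (the best configuration per outcome by balanced
#' accuracy among those that predicted the non-responder correctly),
#' `summary.txt`, the echoed `config.yaml` and a `run.log`. For a fixed
#' seed the outputs are a pure function of the inputs; only the log
#' carries a timestamp. Any startup error aborts before output files are
#' created.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return The grid result, invisibly; side effect: files under
#'   `config$out`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$cohort)) {
    msr_error(sprintf("cohort file not found: %s", config$cohort),
              "msrehab_configuration_error")
  }
  if (!is.null(config$metrics) && !file.exists(config$metrics)) {
    msr_error(sprintf("metrics file not found: %s", config$metrics),
              "msrehab_configuration_error")
  }
  cohort <- read_cohort(config$cohort)
  metrics <- if (!is.null(config$metrics)) read.csv(config$metrics,
                                                    stringsAsFactors = FALSE)
  th <- do.call(srd_thresholds, as.list(config$srd %||% list()))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out, "run.log")
  logline <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(...)), file = logfile, append = TRUE)
  }
  cat("", file = logfile)
  logline("pipeline start: msrehab %s, seed %d",
          as.character(packageVersion("msrehab")), config$seed)
  logline("cohort: %s (%d datasets, %d participants)", config$cohort,
          nrow(cohort), length(unique(cohort$participant_id)))
  t0 <- proc.time()[["elapsed"]]
  labels <- label_cohort(cohort, th)
  write_labels(labels, file.path(config$out, "labels.csv"))
  cc <- responder_counts(labels)
  logline("labels: responders arat=%d bbt=%d nhpt=%d (%.2fs)",
          cc["arat"], cc["bbt"], cc["nhpt"],
          proc.time()[["elapsed"]] - t0)
  t0 <- proc.time()[["elapsed"]]
  grid <- run_grid(cohort, labels, feature_sets = config$feature_sets,
                   models = config$models, outcomes = config$outcomes,
                   metrics = metrics, seed = config$seed,
                   nonresponder = config$nonresponder)
  logline("grid: %d configurations (%.2fs)", nrow(grid),
          proc.time()[["elapsed"]] - t0)
  grid_path <- file.path(config$out, "grid.csv")
  hdr <- c(sprintf("# msrehab %s | seed %d | SRD arat=%.2f bbt=%.2f nhpt=%.2f",
                   as.character(packageVersion("msrehab")), config$seed,
                   th$arat, th$bbt, th$nhpt),
           paste0("# ", attr(grid, "hyperparameters")),
           sprintf("# non-responder dataset: %s", attr(grid, "nonresponder")))
  writeLines(hdr, grid_path)
  suppressWarnings(write.table(as.data.frame(grid), grid_path, sep = ",",
                               row.names = FALSE, quote = FALSE,
                               append = TRUE))
  ok <- grid[grid$status == "ok" & !is.na(grid$nonresponder_correct) &
               grid$nonresponder_correct, , drop = FALSE]
  best <- lapply(split(ok, ok$outcome), function(g) {
    g <- g[order(-g$balanced_accuracy, g$feature_set), , drop = FALSE][1L, ]
    list(model = g$model, feature_set = g$feature_set,
         balanced_accuracy = g$balanced_accuracy,
         sensitivity = g$sensitivity, specificity = g$specificity,
         precision = g$precision,
         nonresponder_correct = g$nonresponder_correct)
  })
  jsonlite::write_json(best, file.path(config$out, "best_models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  smry <- summarize_cohort(cohort)
  txt <- c(sprintf("Cohort: %d participants, %d datasets; age %.1f +/- %.1f yrs, EDSS %.1f +/- %.1f",
                   smry$n_participants, smry$n_datasets,
                   smry$age["mean"], smry$age["sd"],
                   smry$edss["mean"], smry$edss["sd"]),
           sprintf("Responders (SRD %.2f/%.2f/%.2f): ARAT %d, BBT %d, NHPT %d of %d",
                   th$arat, th$bbt, th$nhpt, cc["arat"], cc["bbt"],
                   cc["nhpt"], nrow(cohort)),
           "Best models (balanced accuracy %, rounded; among non-responder-correct):",
           vapply(names(best), function(o) {
             b <- best[[o]]
             sprintf("  %-4s %s on set {%s}: BA %.0f%% (sens %.0f%%, spec %.0f%%, prec %.0f%%)",
                     toupper(o), b$model, b$feature_set,
                     b$balanced_accuracy, b$sensitivity, b$specificity,
                     b$precision)
           }, character(1)))
  writeLines(txt, file.path(config$out, "summary.txt"))
  cfg_echo <- config
  cfg_echo$feature_sets <- vapply(config$feature_sets,
                                  function(x) paste(x, collapse = ","),
                                  character(1))
  yaml::write_yaml(unclass(cfg_echo), file.path(config$out, "config.yaml"))
  logline("pipeline done")
  invisible(grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
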