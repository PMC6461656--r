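#' Run configuration with study defaults
#'
#' Central container of every tunable parameter, each defaulting to the
#' values fixed in the generator and quantification modules.  Overrides
#' are supplied as `key = value` pairs; unknown keys raise an error naming
#' the offending key.  The serialised configuration is embedded in every
#' output directory for provenance.
#'
#' @param ... overrides of the defaults.
#' @return list of class `RunConfig`.
#' @examples
#' cfg <- runConfig(master_seed = 7, groups = list(control = 3))
#' @export
runConfig <- function(...) {
  defaults <- list(
    master_seed = 42,
    groups = list(control = 10, sunitinib = 7, AZD4547 = 7, combo = 7),
    structural_sessions_dpt = seq(3.5, 6.5, by = 0.5),
    perfusion_sessions_dpt = c(4, 6, 8),
    p_perfused = 2 / 3,
    birth_rate_per_day = 1.5,
    elongation_um_per_day = 10.4,
    elongation_cv = 0.3,
    k_sd = 3,
    min_consecutive = 2,
    anastomosis_threshold_s = 1.3,
    perfusion_window_s = 66.66,
    trace_snr = 20,
    write_traces = TRUE,
    log_level = "info")
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("malformed config: unknown key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (cfg$birth_rate_per_day < 0)
    stop("malformed config: birth_rate_per_day must be >= 0")
  if (cfg$elongation_um_per_day < 0)
    stop("malformed config: elongation_um_per_day must be >= 0")
  if (cfg$p_perfused < 0 || cfg$p_perfused > 1)
    stop("malformed config: p_perfused must be in [0, 1]")
  structure(cfg, class = "RunConfig")
}

logMsg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S "), ...)
}

#' Simulate a synthetic study to disk
#'
#' @param config a [runConfig()].
#' @param outDir output directory.
#' @return the `SyntheticCohort`, invisibly; files under `outDir`.
#' @export
runSimulate <- function(config = runConfig(), outDir) {
  t0 <- Sys.time()
  logMsg(config, "simulate: seed ", config$master_seed)
  coh <- simulateCohort(
    groups = unlist(config$groups),
    structuralSessions = config$structural_sessions_dpt,
    perfusionSessions = config$perfusion_sessions_dpt,
    seed = config$master_seed, pPerfused = config$p_perfused,
    outDir = outDir, writeTraces = config$write_traces,
    params = list(birthRate = config$birth_rate_per_day,
                  elongation = config$elongation_um_per_day,
                  cv = config$elongation_cv))
  jsonlite::write_json(unclass(config), file.path(outDir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  logMsg(config, sprintf("simulate: done in %.1f s",
                         as.numeric(Sys.time() - t0, units = "secs")))
  invisible(coh)
}

#' Quantify a simulated study directory
#'
#' Reads the perfusion trace CSVs, runs arrival detection and writes the
#' per-session metrics CSV next to the ground truth.
#'
#' @param studyDir directory produced by [runSimulate()].
#' @param config a [runConfig()].
#' @return the metrics data.frame, invisibly.
#' @export
runQuantify <- function(studyDir, config = runConfig()) {
  need <- c("ground_truth.csv", "traces")
  missing <- need[!file.exists(file.path(studyDir, need))]
  if (length(missing))
    stop("partial study layout; missing: ", paste(missing, collapse = ", "))
  files <- list.files(file.path(studyDir, "traces"),
                      pattern = "^perfusion_.*\\.csv$", full.names = TRUE)
  fp <- 2 / 3
  rows <- lapply(files, function(f) {
    tr <- read.csv(f)
    meta <- regmatches(basename(f),
                       regexec("^perfusion_(.*)_dpt([0-9.]+)\\.csv$", basename(f)))[[1]]
    arr <- vapply(c("A", "B", "C", "D"), function(r)
      detectArrival(tr[[paste0("roi_", r)]], framePeriodS = fp,
                    kSd = config$k_sd,
                    minConsecutive = config$min_consecutive), 0)
    m <- computeMetrics(arr, recordingWindowS = max(tr$time_s) + fp,
                        perfusionWindowS = config$perfusion_window_s,
                        anastomosisThresholdS = config$anastomosis_threshold_s)
    data.frame(animal_id = meta[2], dpt = as.numeric(meta[3]),
               dt_ba_s = m@dtBA, dt_cb_s = m@dtCB, dt_dc_s = m@dtDC,
               integral_s = m@integralDt,
               perf_prox = m@perfused["proximal"],
               perf_wound = m@perfused["wound"],
               perf_dist = m@perfused["distal"],
               ana_prox = m@anastomosis["proximal"],
               ana_dist = m@anastomosis["distal"], stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  gt <- read.csv(file.path(studyDir, "ground_truth.csv"))
  grp <- unique(gt[c("animal_id", "group")])
  metrics <- merge(metrics, grp, by = "animal_id", sort = TRUE)
  metrics <- metrics[order(metrics$animal_id, metrics$dpt), ]
  write.csv(metrics, file.path(studyDir, "perfusion_metrics.csv"),
            row.names = FALSE)
  invisible(metrics)
}

#' Fit the cohort statistics and write a fits JSON
#'
#' @param studyDir directory with `ground_truth.csv` (and optionally
#'   `perfusion_metrics.csv`).
#' @param config a [runConfig()].
#' @return named list of [ModelFit-class] objects, invisibly.
#' @export
runStats <- function(studyDir, config = runConfig()) {
  gt <- read.csv(file.path(studyDir, "ground_truth.csv"))
  fits <- list()
  counts <- cohortMetric(gt, "sprout_count", side = "distal")
  counts <- counts[counts$group == "control", ]
  if (nrow(counts)) {
    names(counts)[names(counts) == "value"] <- "count"
    fits$sprout_count <- fitPoissonGlmm(counts)
  }
  lens <- cohortMetric(gt, "mean_length_um", side = "distal")
  lens <- lens[lens$group == "control", ]
  if (nrow(lens)) {
    names(lens)[names(lens) == "value"] <- "mean_length"
    fits$sprout_length <- fitLmm(lens)
  }
  pv <- cohortMetric(gt, "n_perfused_true")
  tv <- cohortMetric(gt, "n_sprouts_true")
  at8 <- pv$dpt == max(pv$dpt)
  if (any(at8)) {
    dat <- data.frame(animal_id = pv$animal_id[at8],
                      perfused = pv$value[at8], total = tv$value[at8])
    fits$perfused_ratio <- fitPerfusedRatio(dat)
  }
  mfile <- file.path(studyDir, "perfusion_metrics.csv")
  if (file.exists(mfile)) {
    pm <- read.csv(mfile)
    for (m in c("dt_ba_s", "integral_s")) {
      d <- data.frame(animal_id = pm$animal_id, group = pm$group,
                      dpt = pm$dpt, value = pm[[m]])
      d <- d[!is.na(d$value), ]
      ## the interaction model needs several sessions and more rows than
      ## animals (random intercept identifiability)
      if (length(unique(d$dpt)) >= 2 &&
          nrow(d) > length(unique(d$animal_id)) + 2)
        fits[[paste0("mlmr_", m)]] <- tryCatch(fitMlmrInteraction(d),
                                               error = function(e) {
          message("skipping mlmr_", m, ": ", conditionMessage(e))
          NULL
        })
    }
  }
  json <- lapply(fits, function(f) list(
    model_kind = f@modelKind, formula = f@formulaText,
    coefficients = f@coefficients,
    omnibus = if (length(f@omnibus)) as.list(f@omnibus) else NULL))
  jsonlite::write_json(json, file.path(studyDir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(fits)
}

#' Build report panels for a study directory
#'
#' @param studyDir study directory.
#' @param config a [runConfig()].
#' @return panel names, invisibly.
#' @export
runReport <- function(studyDir, config = runConfig()) {
  gt <- read.csv(file.path(studyDir, "ground_truth.csv"))
  mfile <- file.path(studyDir, "perfusion_metrics.csv")
  pm <- if (file.exists(mfile)) read.csv(mfile) else NULL
  invisible(buildReport(gt, perfMetrics = pm,
                        outDir = file.path(studyDir, "report")))
}

#' Run the full chain: simulate, quantify, stats, report
#'
#' @param config a [runConfig()].
#' @param outDir study directory.
#' @return named list with the cohort, metrics and fits, invisibly.
#' @export
runAll <- function(config = runConfig(), outDir) {
  coh <- runSimulate(config, outDir)
  metrics <- runQuantify(outDir, config)
  fits <- runStats(outDir, config)
  panels <- runReport(outDir, config)
  invisible(list(cohort = coh, metrics = metrics, fits = fits,
                 panels = panels))
}
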