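#' Simulate a full synthetic study cohort
#'
#' Generates per-animal scenes, sprouting/perfusion/calcium ground truth
#' for the emulated design: structural + calcium sessions twice daily from
#' 3.5 to 6.5 dpt and perfusion sessions at 4, 6 and 8 dpt, with group
#' sizes defaulting to 10 control and 7 per drug arm.  Per-animal RNG
#' streams are derived by hashing the master seed with the animal id, so
#' enlarging the cohort never perturbs existing animals.  With `outDir`
#' the study is written to disk (tidy ground-truth CSV, per-session ROI
#' trace CSVs, config JSON); re-running with the same seed reproduces the
#' files byte-identically.
#'
#' @param groups named integer vector of group sizes; names from
#'   `control`, `AZD4547`, `sunitinib`, `combo`.
#' @param structuralSessions dpt grid for sprout/calcium sessions.
#' @param perfusionSessions dpt grid for perfusion sessions (subset of
#'   4, 6, 8).
#' @param seed master seed.
#' @param pPerfused sprout perfusion probability.
#' @param outDir optional output directory.
#' @param writeTraces write per-session perfusion ROI trace CSVs (only
#'   with `outDir`).
#' @param params generator parameter overrides: a list with optional
#'   elements `birthRate`, `elongation`, `cv`, `perfusion` (see
#'   [perfusionParams()]), `calcium` (see [calciumParams()]).
#' @return an object of class `SyntheticCohort`: a list with `table` (tidy
#'   CohortTable: animal_id, group, dpt, metric, side, value, censored),
#'   `animals` (per-animal scene/sprouts), `perfusion` (per-session
#'   ground-truth rows) and `seed`.
#' @examples
#' coh <- simulateCohort(groups = c(control = 3), seed = 1)
#' head(coh$table)
#' @export
simulateCohort <- function(groups = c(control = 10, sunitinib = 7,
                                      AZD4547 = 7, combo = 7),
                           structuralSessions = seq(3.5, 6.5, by = 0.5),
                           perfusionSessions = c(4, 6, 8),
                           seed = 42, pPerfused = 2 / 3, outDir = NULL,
                           writeTraces = FALSE, params = list()) {
  known <- c("control", "AZD4547", "sunitinib", "combo")
  bad <- setdiff(names(groups), known)
  if (length(bad)) stop("unknown group name(s): ", paste(bad, collapse = ", "))
  birthRate <- params$birthRate %||% 1.5
  elongation <- params$elongation %||% 10.4
  cv <- params$cv %||% 0.3
  perfPar <- params$perfusion %||% perfusionParams()
  calPar <- params$calcium %||% calciumParams()
  maxDpt <- max(c(structuralSessions, perfusionSessions))

  rows <- list()
  animals <- list()
  perfRows <- list()
  addRow <- function(animal, group, dpt, metric, side, value, censored = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      animal_id = animal, group = group, dpt = dpt, metric = metric,
      side = side, value = value, censored = censored, stringsAsFactors = FALSE)
  }

  for (g in names(groups)) {
    trt <- treatmentSpec(g)
    for (i in seq_len(groups[[g]])) {
      id <- sprintf("%s_%02d", g, i)
      sA <- deriveSeed(seed, id)
      scene <- makeScene(sA, nArteries = 1)
      sprouts <- simulateSprouting(scene, structuralSessions,
                                   birthRate = birthRate,
                                   elongation = elongation, cv = cv,
                                   treatment = trt, maxDpt = maxDpt,
                                   seed = deriveSeed(sA, "sprout"))
      sprouts <- assignPerfusion(sprouts, pPerfused,
                                 seed = deriveSeed(sA, "perfassign"))
      animals[[id]] <- list(animal_id = id, group = g, scene = scene,
                            sprouts = sprouts, treatment = trt)

      for (d in structuralSessions) {
        lens <- lengthAt(sprouts, d)
        alive <- lens > 0
        addRow(id, g, d, "sprout_count", "distal", sum(alive))
        addRow(id, g, d, "sprout_count", "proximal",
               sum(alive & sprouts$side == "proximal"))
        addRow(id, g, d, "mean_length_um", "distal",
               if (any(alive)) mean(lens[alive]) else NA_real_)
        for (reg in c("proximal", "distal")) {
          ev <- simulateCalciumEvents(d, reg, calPar,
                                      seed = deriveSeed(sA, paste0("ca", reg, d)))
          addRow(id, g, d, "ca_transients", reg, length(ev$event_times_s))
        }
      }

      for (d in perfusionSessions) {
        truth <- simulatePerfusionTruth(scene, sprouts, dpt = d, n = 1,
                                        params = perfPar, treatment = trt,
                                        pPerfused = pPerfused,
                                        seed = deriveSeed(sA, paste0("perf", d)))
        truth$animal_id <- id
        truth$group <- g
        perfRows[[length(perfRows) + 1L]] <- truth
        addRow(id, g, d, "ana_prox", "", as.numeric(truth$anastomosis_proximal))
        addRow(id, g, d, "ana_dist", "", as.numeric(truth$anastomosis_distal))
        addRow(id, g, d, "wound_connected", "", as.numeric(truth$wound_connected))
        for (roi in c("A", "B", "C", "D")) {
          v <- truth[[paste0("t_", roi)]]
          addRow(id, g, d, paste0("t_", roi), "", v, censored = is.na(v))
        }
        lens <- lengthAt(sprouts, d)
        addRow(id, g, d, "n_sprouts_true", "", sum(lens > 0))
        addRow(id, g, d, "n_perfused_true", "",
               sum(lens > 0 & sprouts$perfused %in% TRUE))
      }
    }
  }

  table <- do.call(rbind, rows)
  perfusion <- do.call(rbind, perfRows)
  cohort <- structure(list(table = table, animals = animals,
                           perfusion = perfusion, seed = seed,
                           pPerfused = pPerfused,
                           params = list(birthRate = birthRate,
                                         elongation = elongation, cv = cv)),
                      class = "SyntheticCohort")

  if (!is.null(outDir)) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", outDir)
    write.csv(table, file.path(outDir, "ground_truth.csv"), row.names = FALSE)
    cfg <- list(master_seed = seed, groups = as.list(groups),
                structural_sessions_dpt = structuralSessions,
                perfusion_sessions_dpt = perfusionSessions,
                p_perfused = pPerfused,
                birth_rate_per_day = birthRate,
                elongation_um_per_day = elongation, cv = cv)
    jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    if (writeTraces) {
      tdir <- file.path(outDir, "traces")
      dir.create(tdir, showWarnings = FALSE)
      for (k in seq_len(nrow(perfusion))) {
        tr <- renderRoiTraces(perfusion[k, , drop = FALSE],
                              framePeriodS = perfPar$framePeriodS,
                              seed = deriveSeed(seed, paste0("trace_",
                                perfusion$animal_id[k], "_", perfusion$dpt[k])))
        write.csv(tr, file.path(tdir, sprintf("perfusion_%s_dpt%g.csv",
                                              perfusion$animal_id[k],
                                              perfusion$dpt[k])),
                  row.names = FALSE)
      }
    }
  }
  cohort
}

#' Extract one metric from a tidy cohort table
#'
#' @param table tidy CohortTable data.frame.
#' @param metric metric name.
#' @param side optional side/region filter.
#' @return data.frame `animal_id`, `group`, `dpt`, `value`, `censored`.
#' @export
cohortMetric <- function(table, metric, side = NULL) {
  sel <- table$metric == metric
  if (!is.null(side)) sel <- sel & table$side == side
  out <- table[sel, c("animal_id", "group", "dpt", "value", "censored")]
  rownames(out) <- NULL
  out
}

#' Quantify perfusion sessions end-to-end from rendered ROI traces
#'
#' For every session in a cohort's perfusion ground truth, renders the four
#' ROI tracer traces, runs arrival detection and assembles the delta-t
#' metrics — the image-free end-to-end route from ground truth to measured
#' perfusion readouts.
#'
#' @param cohort a `SyntheticCohort` (or its `$perfusion` data.frame).
#' @param seed master seed for trace noise.
#' @param snr trace signal-to-noise ratio.
#' @return data.frame with one row per session: identifiers, detected
#'   `dt_ba_s`, `dt_cb_s`, `dt_dc_s`, `integral_s`, perfusion and
#'   anastomosis booleans, and the ground-truth booleans for comparison.
#' @export
quantifyPerfusion <- function(cohort, seed = 1, snr = 20) {
  perf <- if (inherits(cohort, "SyntheticCohort")) cohort$perfusion else cohort
  fp <- 2 / 3
  out <- lapply(seq_len(nrow(perf)), function(k) {
    row <- perf[k, , drop = FALSE]
    tr <- renderRoiTraces(row, snr = snr, framePeriodS = fp,
                          seed = deriveSeed(seed, paste0(row$animal_id, "_",
                                                         row$dpt, "_", k)))
    arr <- vapply(c("A", "B", "C", "D"), function(r)
      detectArrival(tr[[paste0("roi_", r)]], framePeriodS = fp), 0)
    m <- computeMetrics(arr, recordingWindowS = row$window_s)
    data.frame(animal_id = row$animal_id %||% NA_character_,
               group = row$group %||% NA_character_, dpt = row$dpt,
               dt_ba_s = m@dtBA, dt_cb_s = m@dtCB, dt_dc_s = m@dtDC,
               integral_s = m@integralDt,
               perf_prox = m@perfused["proximal"],
               perf_wound = m@perfused["wound"],
               perf_dist = m@perfused["distal"],
               ana_prox = m@anastomosis["proximal"],
               ana_dist = m@anastomosis["distal"],
               true_ana_prox = row$anastomosis_proximal,
               true_ana_dist = row$anastomosis_distal,
               true_wound_connected = row$wound_connected,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count perfused sprouts per animal by red-channel colocalization
#'
#' Renders the post-fill red projection of each animal at the given day
#' and counts sprouts whose skeletons colocalize with tracer signal
#' ([countPerfusedSprouts()]).
#'
#' @param cohort a `SyntheticCohort`.
#' @param dpt session day (default 8).
#' @param res render resolution.
#' @param seed master seed for render noise.
#' @param minLengthUm sprouts shorter than this are not counted: after the
#'   ~12 µm root trim they retain no skeleton clear of the perfused parent
#'   wall's tracer halo, so their perfusion cannot be assessed by
#'   colocalization.  Perfusion is assigned independently of length, so
#'   the perfused/total ratio is unaffected.
#' @return data.frame `animal_id`, `group`, `perfused`, `total`.
#' @export
quantifyPerfusedSprouts <- function(cohort, dpt = 8, res = 256, seed = 1,
                                    minLengthUm = 15) {
  out <- lapply(cohort$animals, function(an) {
    lens <- lengthAt(an$sprouts, dpt)
    alive <- lens >= minLengthUm
    sp <- an$sprouts[alive, , drop = FALSE]
    if (!nrow(sp))
      return(data.frame(animal_id = an$animal_id, group = an$group,
                        perfused = 0L, total = 0L, stringsAsFactors = FALSE))
    img <- renderRedProjection(an$scene, sp, dpt, res = res,
                               seed = deriveSeed(seed, an$animal_id))
    ps <- an$scene@fovUm[1] / res
    paths <- lapply(sproutPathsAt(sp, dpt), function(p) {
      px <- densifyPolyline(p, ps)           # one vertex per pixel step
      ## trim the root: the first ~12 µm sit on the perfused parent wall
      ## and would colocalize with tracer regardless of sprout perfusion
      nSkip <- min(ceiling(12 / (ps / 2)), nrow(px) - 3L)
      if (nSkip > 0) px <- px[-seq_len(nSkip), , drop = FALSE]
      cbind(px[, 2], px[, 1]) / ps           # (row, col) = (y, x) / px
    })
    cnt <- countPerfusedSprouts(paths, img)
    data.frame(animal_id = an$animal_id, group = an$group,
               perfused = unname(cnt["n_perfused"]),
               total = unname(cnt["n_total"]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

densifyPolyline <- function(path, stepUm) {
  seg <- sqrt(rowSums(diff(path)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0) return(path)
  s <- seq(0, total, by = max(stepUm / 2, 1e-3))
  cbind(stats::approx(cum, path[, 1], s)$y, stats::approx(cum, path[, 2], s)$y)
}
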