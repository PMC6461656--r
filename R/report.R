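#' @import ggplot2
NULL

groupColors <- c(control = "#1f77b4", AZD4547 = "#d62728",
                 sunitinib = "#DAA520", combo = "#ff7f0e")

ciSummary <- function(df, level = 0.90) {
  z <- qnorm(1 - (1 - level) / 2)
  agg <- aggregate(value ~ group + dpt, data = df, FUN = function(v)
    c(mean = mean(v), se = sd(v) / sqrt(length(v)), n = length(v)))
  out <- cbind(agg[c("group", "dpt")], as.data.frame(agg$value))
  out$lo <- out$mean - z * out$se
  out$hi <- out$mean + z * out$se
  out
}

savePanel <- function(plt, dat, outDir, name) {
  write.csv(dat, file.path(outDir, paste0(name, ".csv")), row.names = FALSE)
  ## grDevices::svg needs cairo; fall back to pdf (both vector formats)
  if (capabilities("cairo")) {
    ggsave(file.path(outDir, paste0(name, ".svg")), plt,
           width = 5, height = 4, device = grDevices::svg)
  } else {
    ggsave(file.path(outDir, paste0(name, ".pdf")), plt,
           width = 5, height = 4, device = grDevices::pdf)
  }
  invisible(name)
}

#' Build summary figure panels and tables for a cohort
#'
#' Writes one vector-graphics panel plus a CSV of the exact plotted values
#' per available readout: sprout counts and mean lengths over time (90%
#' CI), the delta-t metrics over perfusion sessions (95% CI), perfused
#' versus total sprouts with the through-origin slope, and calcium
#' transient counts by side.  Panels whose metric is absent are skipped
#' with a log message.
#'
#' @param table tidy CohortTable data.frame (see [simulateCohort()]).
#' @param perfMetrics optional data.frame from [quantifyPerfusion()].
#' @param perfusedCounts optional data.frame from
#'   [quantifyPerfusedSprouts()].
#' @param outDir output directory (created if needed).
#' @return character vector of panel names written.
#' @export
buildReport <- function(table, perfMetrics = NULL, perfusedCounts = NULL,
                        outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  skip <- function(name) message("panel ", name, " skipped: metric missing")
  cols <- scale_colour_manual(values = groupColors)

  counts <- cohortMetric(table, "sprout_count", side = "distal")
  if (nrow(counts)) {
    s <- ciSummary(counts, 0.90)
    plt <- ggplot(s, aes(dpt, mean, colour = group)) +
      geom_line() + geom_point() +
      geom_errorbar(aes(ymin = lo, ymax = hi), width = 0.1) + cols +
      labs(x = "days post-transection", y = "distal sprout count",
           title = "Sprout number (90% CI)")
    written <- c(written, savePanel(plt, s, outDir, "sprout_counts"))
  } else skip("sprout_counts")

  lens <- cohortMetric(table, "mean_length_um", side = "distal")
  lens <- lens[!is.na(lens$value), ]
  if (nrow(lens)) {
    s <- ciSummary(lens, 0.90)
    plt <- ggplot(s, aes(dpt, mean, colour = group)) +
      geom_line() + geom_point() +
      geom_errorbar(aes(ymin = lo, ymax = hi), width = 0.1) + cols +
      labs(x = "days post-transection", y = "mean sprout length (um)",
           title = "Sprout length (90% CI)")
    written <- c(written, savePanel(plt, s, outDir, "sprout_lengths"))
  } else skip("sprout_lengths")

  ca <- cohortMetric(table, "ca_transients")
  caTab <- table[table$metric == "ca_transients", ]
  if (nrow(caTab)) {
    agg <- aggregate(value ~ side + dpt, caTab, mean)
    plt <- ggplot(agg, aes(dpt, value, linetype = side)) +
      geom_line() + geom_point() +
      labs(x = "days post-transection", y = "transients / 22 min",
           title = "Ca transients by side")
    written <- c(written, savePanel(plt, agg, outDir, "calcium_counts"))
  } else skip("calcium_counts")

  if (!is.null(perfMetrics) && nrow(perfMetrics)) {
    for (m in c("dt_ba_s", "dt_cb_s", "dt_dc_s", "integral_s")) {
      d <- perfMetrics[!is.na(perfMetrics[[m]]),
                       c("group", "dpt", m)]
      if (!nrow(d)) { skip(m); next }
      names(d)[3] <- "value"
      s <- ciSummary(d, 0.95)
      plt <- ggplot(s, aes(dpt, mean, colour = group)) +
        geom_line() + geom_point() +
        geom_errorbar(aes(ymin = lo, ymax = hi), width = 0.1) + cols +
        labs(x = "days post-transection", y = paste(m, "(s)"),
             title = paste("Perfusion metric", m, "(95% CI)"))
      written <- c(written, savePanel(plt, s, outDir, paste0("perfusion_", m)))
    }
  }

  if (!is.null(perfusedCounts) && nrow(perfusedCounts)) {
    fitDat <- perfusedCounts[c("animal_id", "perfused", "total", "group")]
    slope <- modelCoef(fitPerfusedRatio(fitDat))$estimate[1]
    plt <- ggplot(perfusedCounts, aes(total, perfused, colour = group)) +
      geom_abline(slope = slope, intercept = 0, linetype = 2) +
      geom_point(alpha = 0.7) + cols +
      labs(x = "total sprouts", y = "perfused sprouts",
           title = sprintf("Perfused fraction (slope %.3f)", slope))
    written <- c(written, savePanel(plt, perfusedCounts, outDir,
                                    "perfused_vs_total"))
  }
  written
}
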