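test_that("a control cohort has one row per animal, session and metric", {
  coh <- simulateCohort(groups = c(control = 10), seed = 3,
                        perfusionSessions = numeric(0))
  counts <- cohortMetric(coh$table, "sprout_count", side = "distal")
  expect_equal(nrow(counts), 10 * 7)
  lens <- cohortMetric(coh$table, "mean_length_um", side = "distal")
  expect_equal(nrow(lens), 10 * 7)
  ca <- cohortMetric(coh$table, "ca_transients", side = "distal")
  expect_equal(nrow(ca), 10 * 7)
})

test_that("cohorts are byte-identical under the same master seed", {
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  simulateCohort(groups = c(control = 3), seed = 11, outDir = d1,
                 writeTraces = TRUE)
  simulateCohort(groups = c(control = 3), seed = 11, outDir = d2,
                 writeTraces = TRUE)
  f1 <- file.path(d1, "ground_truth.csv"); f2 <- file.path(d2, "ground_truth.csv")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  tr1 <- list.files(file.path(d1, "traces"), full.names = TRUE)
  tr2 <- list.files(file.path(d2, "traces"), full.names = TRUE)
  expect_identical(unname(tools::md5sum(tr1)), unname(tools::md5sum(tr2)))
  ## adding animals never perturbs existing ones
  cohBig <- simulateCohort(groups = c(control = 5), seed = 11)
  cohSmall <- simulateCohort(groups = c(control = 3), seed = 11)
  expect_identical(cohSmall$animals$control_02$sprouts$birth_dpt,
                   cohBig$animals$control_02$sprouts$birth_dpt)
})

test_that("unknown groups and malformed configs are rejected by name", {
  expect_error(simulateCohort(groups = c(placebo = 3), seed = 1),
               "unknown group")
  expect_error(runConfig(birth_rate_per_day = -2), "birth_rate_per_day")
  expect_error(runConfig(nonsense_key = 1), "nonsense_key")
})

test_that("treatment suppression orders the groups at 6.5 dpt", {
  coh <- simulateCohort(groups = c(control = 20, sunitinib = 20, combo = 20),
                        seed = 77, perfusionSessions = numeric(0))
  counts <- cohortMetric(coh$table, "sprout_count", side = "distal")
  m <- tapply(counts$value[counts$dpt == 6.5], counts$group[counts$dpt == 6.5],
              mean)
  expect_lt(m["combo"], m["sunitinib"])
  expect_lt(m["sunitinib"], m["control"])
  lens <- cohortMetric(coh$table, "mean_length_um", side = "distal")
  ml <- tapply(lens$value[lens$dpt == 6.5], lens$group[lens$dpt == 6.5],
               function(v) mean(v, na.rm = TRUE))
  expect_lt(ml["combo"], ml["sunitinib"])
  expect_lt(ml["sunitinib"], ml["control"])
})

test_that("the full pipeline chain runs, reproduces and reports", {
  out <- file.path(tempdir(), "chain")
  on.exit(unlink(out, recursive = TRUE))
  cfg <- runConfig(master_seed = 5, groups = list(control = 3),
                   structural_sessions_dpt = c(4, 5, 6),
                   perfusion_sessions_dpt = c(4, 8), log_level = "quiet")
  res <- runAll(cfg, out)
  expect_true(file.exists(file.path(out, "ground_truth.csv")))
  expect_true(file.exists(file.path(out, "perfusion_metrics.csv")))
  expect_true(file.exists(file.path(out, "fits.json")))
  expect_true(file.exists(file.path(out, "run_config.json")))
  expect_gt(length(list.files(file.path(out, "report"))), 0)
  metrics <- read.csv(file.path(out, "perfusion_metrics.csv"))
  expect_true(all(c("dt_ba_s", "integral_s", "ana_prox") %in% names(metrics)))
  ## rerunning simulate reproduces the ground truth byte-for-byte
  md5 <- tools::md5sum(file.path(out, "ground_truth.csv"))
  runSimulate(cfg, out)
  expect_identical(unname(tools::md5sum(file.path(out, "ground_truth.csv"))),
                   unname(md5))
  ## quantify refuses a partial study layout, naming the missing pieces
  empty <- file.path(tempdir(), "empty_study")
  dir.create(empty, showWarnings = FALSE)
  expect_error(runQuantify(empty, cfg), "missing")
})
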