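# angioQuant

Quantification of wound-healing angiogenesis from longitudinal intravital
two-photon imaging — together with a synthetic-data generator that makes
every stage of the pipeline testable against known ground truth.

## The problem

After a transsecting cut through an ear arteriole, new vessel sprouts grow
exclusively from the **distal** arterial stump into the wound; about two
thirds of them become perfused, artery-to-vein anastomoses re-perfuse both
stumps within days, and tracer crosses the wound again by 8 days
post-transection (dpt). Imaging studies of this model report, per animal
and session:

* sprout **number** (≈ 1.5 new sprouts/day) and **mean length**
  (≈ 10.4 µm/day), twice daily over 3.5–6.5 dpt;
* tracer **arrival-time differences** between ROIs A, B (proximal stump)
  and C, D (distal stump) at 4/6/8 dpt:
  Δt<sub>B−A</sub>, Δt<sub>C−B</sub>, Δt<sub>D−C</sub>, the integral flow
  measure |Δt<sub>B−A</sub>| + |Δt<sub>C−B</sub>| + |Δt<sub>D−C</sub>|,
  anastomoses (|Δt| < 1.3 s) and perfusion (Δt < 66.66 s);
* endothelial **Ca²⁺ transients** per 22-min session (peak ≈ 5 at 5 dpt,
  strongly distal-dominant);
* effects of anti-angiogenic treatment (sunitinib, AZD4547, combination)
  on all of the above.

angioQuant implements the full analysis chain — bolus arrival detection
with censoring, anastomosis/perfusion classification, vessel segmentation,
skeleton-based sprout morphometry, perfused-sprout colocalization
counting, ΔF/F transient detection — and the longitudinal statistics
(Poisson GLMM by Laplace approximation, linear mixed models,
treatment-by-time interaction models with Holm-corrected post-hocs,
through-origin perfused-fraction regression, Fisher/Wilcoxon/Mann-Whitney
tests). A first-class synthetic module simulates vascular scenes, cohorts,
two-channel image series (multi-page TIFF + JSON sidecar) and ROI traces
under the study's design, with all defaults set to the published effect
sizes.

## Worked example

```r
library(angioQuant)

## a default control cohort: 10 animals, twice-daily sessions 3.5-6.5 dpt
coh <- simulateCohort(groups = c(control = 10), seed = 42,
                      perfusionSessions = numeric(0))
counts <- cohortMetric(coh$table, "sprout_count", side = "distal")
names(counts)[names(counts) == "value"] <- "count"
fitPoissonGlmm(counts)
#> ModelFit <poisson_glmm> count ~ dpt + (1 | animal_id), family poisson
#>           term   estimate        se            p
#>  log_intercept -3.3117588 0.5890397 1.884305e-08
#>        log_dpt   0.7255236 0.1008779 6.380364e-13
#>    count_slope   1.2810483 0.2454013 6.380364e-13
```

The `count_slope` row is the log-link slope converted to the count scale
(sprouts per day, here 1.28 ± 0.25 against the generating 1.5/day — a
recovery within two standard errors on one 10-animal cohort).

```r
## perfusion sessions: ground truth -> ROI traces -> arrival detection
scene <- makeScene(1, nArteries = 1)
truth <- simulatePerfusionTruth(scene, dpt = 4, n = 1, seed = 5)
traces <- renderRoiTraces(truth, seed = 5)
arr <- vapply(c("A", "B", "C", "D"), function(r)
  detectArrival(traces[[paste0("roi_", r)]]), 0)
computeMetrics(arr)
#> ArrivalResult
#>   t: A 29.64 s  B 30.70 s  C 31.39 s  D 30.17 s
#>   dtBA=1.06 s dtCB=0.69 s dtDC=-1.22 s integral=2.96 s
#>   perfused: proximal TRUE wound TRUE distal TRUE
#>   anastomosis: proximal TRUE distal TRUE
```

A session at 4 dpt: both stumps are vein-anastomosed — sub-1.3 s delays
on both sides, with the distal delay *negative* because that stump fills
retrogradely from its vein (D before C). The wound itself is not yet
bridged by sprouts; the distal compartment is reachable only through the
anastomosis, and across many sessions the wound-crossing delay
Δt<sub>C−B</sub> at 4 dpt averages 4.7 s before collapsing to 0 by
8 dpt.

The orchestration layer runs the whole study from a single config:

```r
cfg <- runConfig(master_seed = 42)
res <- runAll(cfg, "study_run")   # simulate -> quantify -> stats -> report
```

which writes `ground_truth.csv`, per-session ROI trace CSVs,
`perfusion_metrics.csv`, `fits.json` and report panels (vector graphics +
the exact plotted values as CSV) under `study_run/`. The same commands are
available from a shell via `inst/cli/angioquant.R`. Re-running with the
same seed reproduces every file byte-identically.

## Acceptance script

`scripts/acceptance.R` regenerates the default synthetic study from
scratch at a given seed, runs the full pipeline on it (mixed-model slopes
for sprout number and length; perfused-sprout fractions by red-channel
colocalization, control-only and pooled across treatment groups;
end-to-end wound-transit means at 4 and 8 dpt; anastomosis prevalence
over 10,000 classified sessions; detected Ca²⁺ transient rates; control
time slopes of Δt<sub>B−A</sub> and the integral flow measure from the
treatment-by-time interaction model) and writes the resulting numbers as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Runtime is about one minute on one CPU.
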