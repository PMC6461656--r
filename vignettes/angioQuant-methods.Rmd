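---
title: "angioQuant: models and methods"
author: "angioQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{angioQuant: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioQuant)
```

# The problem

After a transsecting cut through an arteriole in the mouse ear, the vessel
heals by angiogenic sprouting: new branches grow from the *distal* arterial
stump into the wound, about two thirds of them become perfused, and by
8 days post-transection (dpt) tracer again crosses the wound. Intravital
two-photon imaging of mice expressing the calcium indicator GCaMP2 in
arterial endothelium yields three longitudinal readouts per animal:

1. **Structural**: number and length of sprouts, twice daily from 3.5 to
   6.5 dpt (green channel).
2. **Functional**: arrival times of an injected red tracer (Texas
   Red-class dextran) in four ROIs — A, B in the proximal stump, C, D in
   the distal stump — at 4, 6 and 8 dpt, yielding the delays
   $\Delta t_{B-A}$, $\Delta t_{C-B}$, $\Delta t_{D-C}$ and the integral
   flow measure $|\Delta t_{B-A}| + |\Delta t_{C-B}| + |\Delta t_{D-C}|$.
3. **Signalling**: endothelial Ca^2+^ transients per 22-minute session,
   proximal versus distal.

angioQuant implements both the *quantification* (arrival detection,
anastomosis/perfusion classification, sprout segmentation and
morphometry, transient detection, longitudinal mixed models) and a
*synthetic-data generator* that emulates the full study design, so every
stage of the pipeline can be validated against known ground truth without
animal data.

# The synthetic world

## Scene geometry

A `VascularScene` is a calibrated 1 × 1 mm field of view with a 300 µm
wound band across its middle. Each transsected artery contributes a
proximal stump ending on the proximal band edge and a distal stump ending
on the distal edge; a thin cut-wall arm runs along each edge (the sliced
vessel end from which sprouts emerge), and a vein runs alongside each
stump within anastomosis reach. Veins carry no GCaMP signal and are
visible only in the tracer channel — this is what lets artery-to-vein
connections be recognised in the real experiment.

The 300 µm band width is a scene-layout constant (it defines the
proximal/wound/distal region masks). The *functional bridging distance*
`woundGapUm` (default 30 µm) is deliberately much smaller: sprouts form
perfused connections "to the proximal segment or to other vessels in the
vicinity", and observed sprout lengths at the time the wound becomes
crossable (30–60 µm) fix the scale. A wound connection requires at least
one *perfused* sprout longer than this gap.

## Sprouting

Sprouts arise **only from distal stumps** — a deliberate invariant of the
generator, asserted by tests on every cohort. Births follow a homogeneous
Poisson process at `birthRate` (default 1.5/day) from `onsetDpt` (3.5).
Each sprout elongates linearly at a per-sprout tip speed drawn
lognormally (CV 0.3) around `tipSpeedFactor * elongation`.

The calibration constant `tipSpeedFactor = 1.7` deserves explanation.
The reported observable is the slope of the per-animal *mean* sprout
length fitted by a random-intercept linear mixed model (LMM), and the
package's `elongation` parameter (default 10.4 µm/day) is defined as that
observable. Two opposing effects connect it to the tip speed:

* ongoing births dilute the mean with newborn (short) sprouts — under
  uniform birth times the cross-sectional mean grows at only *half* the
  tip speed;
* the random-intercept LMM up-weights within-animal contrasts, and since
  a session enters the model only once the animal has a sprout
  (informative early missingness) the within-animal slope exceeds the
  cross-sectional one.

The net factor, derived once from a 1000-animal calibration simulation of
the fixed twice-daily design, is 1.7; it is a property of the stated
design and is not revisited. A consequence worth knowing: because the
same sprouts are re-measured at every session, cohort-level errors are
within-animal correlated and the LMM's naive slope standard error
(~0.75 µm/day at n = 10) understates the true across-cohort sampling SD
(~1.4 µm/day). The estimator itself is calibrated (mean recovery 10.4).

Perfusion status is assigned per sprout once (Bernoulli, default
p = 2/3), constant over time, matching the observed constancy of the
perfused/total ratio.

## Tracer arrivals

Arrival times are *sampled along feeding paths*, not solved
hydrodynamically. ROI A receives the bolus a lognormal circulation delay
(~10 s) after the 30-frame baseline. Each compartment then takes the
earliest of its candidate feeds:

* **B** follows A through the proximal stump: a fast delay (mean
  0.7/0.5/0.3 s at 4/6/8 dpt, truncated to [0.05, 1.0] s) when the stump
  is vein-anastomosed (probability 0.9/1.0/1.0), otherwise a *slow
  capillary backfill* arrival (69 ± 3 s). The slow route is measurable
  within the extended 300-frame recording but falls beyond the 66.66 s
  perfusion window, so such stumps classify as not perfused and not
  anastomosed — yet their uncensored delays drive the negative time
  slope of $\Delta t_{B-A}$ reported for controls, which is arithmetically
  impossible if every uncensored delay obeyed the 1.3 s rule.
* **D** is fed retrogradely from its adjacent vein (probability 0.8/1.0/
  1.0); at 4 dpt this delay is Gamma-distributed with mean 4.74 s and SD
  6.62 s, so that the wound-crossing delay among connected sessions
  reproduces the reported 4.74 ± 6.62 s.
* **C** is reached either retrogradely from D (D before C, negative
  $\Delta t_{D-C}$ — the typical early pattern) or anterogradely from B
  across bridging sprouts once the wound is connected (delay 2 ± 2 s at
  6 dpt, 0 ± 0.05 s at 8 dpt).

Compartments whose arrival exceeds the recording window are censored;
recordings extend from 100 to 300 frames exactly when the standard window
would miss a reachable compartment, as in the emulated protocol. The
min-over-feeds construction makes path consistency automatic: removing a
feed can only delay or censor downstream arrivals.

## Calcium

Transients are a within-session homogeneous Poisson process whose session
mean follows a triangular profile: zero at 3.0 dpt, 5 events/22 min at
the 5.0 dpt peak, zero again at 8.0 dpt; proximal activity is 10% of
distal. Events have fixed amplitude (ΔF/F = 0.5) with instantaneous rise
and 5 s exponential decay; rendered traces carry Gaussian noise of
SD 0.05 ΔF/F (10× below the amplitude).

## Rendering

Vessels are rasterised as Gaussian-profile tubes whose cross-section has
half-maximum near the lumen radius, convolved with a pixel-scale PSF
(mass-preserving) so sub-pixel sprouts dim rather than vanish and
off-axis halos stay compact. The green channel carries the weak intrinsic
GCaMP baseline of arteries (never veins); the red channel fills each
segment from its arrival time with a compact linear front **starting at
the arrival time** — arrival is the onset of intensity change, and the
compact front guarantees that a threshold crossing at *any* detection
threshold lies within the 0.5 s rise of the truth, which is what bounds
the end-to-end detection error within one frame period at any SNR (a
logistic front does not have this property; its crossing bias grows with
SNR). Poisson shot noise plus Gaussian read noise are added; ROI-trace
noise is likewise shot-scaled, so baselines are quieter than plateaus.

# Quantification

## Arrival detection

`detectArrival()` implements a sustained-crossing rule: baseline mean m
and SD s over the first 30 frames; arrival is the first post-baseline
frame from which the trace stays at or above m + 3s for 2 consecutive
frames, refined by linear interpolation to sub-frame precision. A flat
baseline falls back to an absolute SD floor; traces that never cross are
censored. Two properties matter in practice:

* raising the threshold multiplier can only delay the arrival
  (tested); and
* the estimator has a small (~0.1–0.3%) per-trace early-trigger rate at
  the default 3 SD / 2-frame setting, because the baseline SD is
  estimated from only 30 frames. Recovery tests therefore assert the
  within-one-frame *fraction* (≥ 98%) rather than a zero-failure
  absolute, which no threshold detector can honestly guarantee.

Delta-t pairs keep their sign (negative $\Delta t_{D-C}$ = retrograde
distal flow); a pair is missing iff either endpoint is censored, and the
integral flow measure exists iff all three pairs do. Perfusion uses the
66.66 s window (the 100-frame minimum recording, applied uniformly even
to 300-frame recordings for comparability); anastomosis uses the strict
$|\Delta t| < 1.3$ s rule, absolute value because retrograde delays
count. Censored delays enter only the categorical analyses and are
excluded from delta-t means and regressions.

## Sprout segmentation and morphometry

The green anatomy projection is smoothed (Gaussian, σ = 1 px),
thresholded at Otsu's value, cleaned by **opening-by-reconstruction**,
and components under 20 px are removed. Plain r = 1 morphological
opening — the textbook choice — erases 2-px-wide sprouts outright at
3.9 µm/px; eroding and then geodesically dilating inside the original
mask removes the same isolated noise specks while fully restoring thin
branches attached to surviving structures, which is exactly the feature
of interest here.

The mask is thinned (Zhang–Suen) and sprouts are the 8-connected in-band
skeleton components attached to a stump trunk; each yields one sprout
whose path runs from the attachment to the tip of the longest wound-ward
geodesic (ties resolved towards the leftmost tip, so detection is
deterministic). Because thinning retracts skeleton endpoints inside the
mask, the reported length — defined wall to tip — extends the path by the
root gap to the wall row and walks the tip forward through the mask; on
noise-free straight fixtures this lands within 2 px of truth. Adjacent
sprouts closer than the imaging resolution can merge into one branch
(as they would for a human rater); the exact-count contract is therefore
asserted on well-separated fixtures and recall statistically on random
scenes. Sessions with no sprouts report count 0 and a *missing* mean
length — never 0 — so the length model ignores them.

Perfused-sprout colocalization counts a sprout as perfused when at least
half its skeleton pixels exceed the red background median + 3 MAD in the
compressed z-projection. The first ~12 µm of each skeleton are trimmed
(the root sits on the perfused parent wall and always colocalizes), and
sprouts shorter than 15 µm are not counted at all — after the trim they
retain no assessable skeleton. Perfusion is assigned independently of
length, so this floor does not bias the perfused/total ratio.

## Calcium detection

ΔF/F uses a running 20th-percentile baseline over a 60 s window (floored
to avoid division blow-up), which tracks slow drift while ignoring sparse
transients. Events are maximal runs at or above 3 robust SDs (MAD) of the
series lasting at least 2 s, with sub-second gaps merged. This is a
minimal, parameterised stand-in for the original interactive toolbox; its
acceptance is recovery of generator ground truth, not equivalence with
that toolbox.

# Statistics

* **Sprout counts**: Poisson GLMM, `count ~ dpt + (1 | animal)`, Laplace
  approximation. The reported "sprouts per day" slope is on the count
  scale, while the model has a log link; the package converts via the
  average derivative over the observed range,
  $(\mu(t_{max}) - \mu(t_{min}))/(t_{max} - t_{min})$ with
  $\mu(t) = \exp(\beta_0 + \beta_1 t + \sigma^2/2)$, and a delta-method
  standard error. A log-link coefficient can never itself be a per-day
  count increment.
* **Lengths**: LMM `mean_length ~ dpt + (1 | animal)`, unbalanced data
  expected.
* **Treatment comparisons**: `value ~ group * dpt + (1 | animal)`
  ("MLMR"). Slope p-values are Wald z and the interaction omnibus is a
  Wald F with residual denominator df — no Satterthwaite machinery is
  available in this stack, and the denominator df choice is reported with
  the statistic. Post-hoc family: all pairwise group contrasts of
  predicted means at each observed session day, Holm-corrected; Holm is
  implemented directly (step-down with monotonicity) and cross-checked
  against an independent enumeration and `stats::p.adjust`.
* **Perfused fraction**: through-origin mixed regression
  `perfused ~ 0 + total + (1 | animal)`; with one observation per animal
  the random-intercept variance is unidentified and the fit falls back to
  through-origin least squares (same point estimate).
* **Nonparametrics**: paired Wilcoxon signed-rank (zero differences
  dropped; all-equal input is flagged, not tested), Fisher's exact on
  2×2 tables (empty margin ⇒ p = 1, flagged), Mann–Whitney U with exact
  small-sample p where feasible.
* Random effects are intercept-per-animal only, matching the original
  analyses; the resulting anti-conservatism of naive slope SEs under
  persistent-sprout correlation is documented above.

# What a green test establishes — and what it does not

The generator emulates the *design* (cohort sizes, session grids, effect
sizes, censoring structure, noise calibres) and makes every paper-printed
effect size a generator default: 1.5 sprouts/day, 10.4 µm/day, p = 2/3
perfused, 90%/80% anastomosis prevalence at 4 dpt, 4.74 ± 6.62 s wound
transit decaying to 0 ± 0 s, 5 transients/22 min at the 5 dpt peak, and
multiplicative treatment suppression (combo ≤ mono < control, with the
documented exception that anastomosis-probability factors follow the
observed non-monotone pattern at 4 dpt). Green tests establish that the
pipeline *recovers what generated the data* at the stated design size.
They do not establish anything about real tissue: the generator has
straight, non-interacting sprouts, perfectly aligned frames, no motion or
breathing artefacts, stationary noise, and sampled (not flow-derived)
arrival times. Known limitations worth naming:

* With n = 10 control animals, cohort-level sampling SDs are large
  relative to fitted SEs for the length slope and the perfused fraction
  (binomial); single-cohort recovery can land 2 SD from the generating
  value with honest machinery.
* The control time slopes of $\Delta t_{B-A}$ and of the integral flow
  measure are multi-modal across cohorts: their large magnitudes are
  carried by slow-backfill animals whose per-cohort count is
  Bernoulli(0.1) × 10, so ~35% of cohorts contain none at 4 dpt and show
  only the fast-delay slopes (~−0.1 and ~−1.8 s/day respectively).
* Degenerate inputs are handled explicitly: all-zero counts refuse to
  fit; blank images segment to an empty mask with a warning; stumps
  shorter than the ROI offsets raise a placement error naming the offset;
  TIFF/metadata mismatches are reported by key.

# Reproducibility

Every stochastic routine takes a seed; per-animal streams are derived by
hashing the master seed with the animal id, so enlarging a cohort never
perturbs existing animals, and re-running a study with the same seed
reproduces its CSV outputs byte-identically. `runConfig()` carries every
tunable with its default equal to the values fixed here and is serialised
into each output directory.

```{r example, eval = FALSE}
cfg <- runConfig(master_seed = 42, groups = list(control = 10))
res <- runAll(cfg, "study_run")
res$fits$sprout_count        # Poisson GLMM, count-scale slope
```
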