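---
title: "Modelling outdoor noise exposure by land use regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling outdoor noise exposure by land use regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noiseLUR)
```

## The problem

Assessing a population's exposure to environmental noise requires noise
levels at many locations, but continuous measurements are expensive and, in
dense informal settlements, logistically hard. Land use regression (LUR)
side-steps this by fitting an empirical linear model that predicts a noise
metric at a site from the geography around it — road lengths, distances to
noise sources, household density, land-use composition, greenness — and then
applying that model wherever the geographic layers are available.

noiseLUR implements the complete chain for a study of this design:

1. **Acoustic metrics** — from raw 1-second A-weighted logger series to
   cleaned period levels.
2. **GIS features** — from vector/raster layers to a dense site-by-predictor
   matrix.
3. **Supervised selection** — the stepwise, sign- and correlation-constrained
   procedure that builds the LUR model.
4. **Evaluation** — measured-versus-predicted diagnostics, overall and per
   study area.
5. **Synthetic data** — a generator with known ground truth, because the
   original field measurements and municipal GIS extracts are not public;
   every stage of the pipeline is validated against simulation and
   closed-form oracles instead.

## Acoustic metrics

Measurements nominally cover a week per site; analysis is restricted to a
fixed five-day window — Wednesday 06:00 to the following Monday 06:00,
432,000 one-second samples — so that all sites share the same measurement
days. Two cleaning rules apply, in this order:

* **Completeness.** A site missing more than 10% of the expected seconds
  (battery failures and similar) is excluded. The boundary is strict: a site
  missing exactly 10% is retained. Missingness is assessed *before* outlier
  removal; removed outliers never count against the completeness budget.
* **Outliers.** One-second values deviating from the five-day arithmetic
  mean of the dB values by more than three standard deviations (also in dB)
  are removed in a single pass. The mean and SD are not re-estimated after
  removal; a constant series (SD = 0) loses nothing. Both the single-pass
  rule and the dB scale are deliberate choices where the field convention
  admits either reading; iterating the rule would remove ever more of a
  heavy-tailed series and make the cleaned set depend on the iteration
  count.

From the cleaned series, levels are aggregated by the equal-energy rule
$L = 10\log_{10}\bigl(\tfrac1n\sum_i 10^{L_i/10}\bigr)$, pooling all seconds
of a period class across the five days: $L_{day}$ (06:00–18:00),
$L_{evening}$ (18:00–22:00), $L_{night}$ (22:00–06:00, wrapping midnight),
and $L_{Aeq24h}$ over everything (the window starts at 06:00, matching the
06:00–06:00 day convention). Pooling seconds, rather than averaging per-day
metrics, coincides with the per-day convention for complete data in this
window (each period class appears the same number of times) and is the
robust choice under gaps. The day–evening–night level adds the standard
annoyance penalties on the energy scale:

$$L_{den} = 10\log_{10}\!\Bigl(\frac{12\cdot 10^{L_{day}/10}
 + 4\cdot 10^{(L_{evening}+5)/10} + 8\cdot 10^{(L_{night}+10)/10}}{24}\Bigr).$$

Useful identities the tests lean on: a constant 60 dB series yields 60.00
for every period metric and $L_{den} = 66.40$; components (60, 55, 50) give
exactly 60.00 because the +5 and +10 penalties align all three terms; and
always $L_{Aeq24h} \le L_{den} \le L_{Aeq24h} + 10$.

Timestamps are local civil time handled in a fixed-offset zone; the field
campaign sits inside one offset regime, so daylight-saving transitions are
not modelled. Duplicate or sub-second timestamps are rejected at parse time
rather than silently merged.

## GIS features

All geometry is computed in a projected metric coordinate system; input that
looks geographic (lon/lat ranges) is refused at ingestion rather than
producing metre-buffers on degrees. The candidate grid follows the study's
variable inventory — 105 candidates:

| category | variables | buffers (m) |
|---|---|---|
| roads | clipped length of 10 class combinations | 25/50/100/200/500 |
| roads/air/rail/community | inverse distance to nearest road, airport, active railway, any railway, church, police, hospital | — |
| buildings | household density (count / buffer area) | 25/50/100/200/500/750/1000 |
| land use | area of residential, commercial, industrial, buildings, nature | 25/50/100/200/500/750/1000 |
| vegetation | mean NDVI | 30/100/150/200/500/750 |

Numerical choices: discs are closed (boundary included); segment clipping is
the exact quadratic segment–circle intersection; polygon–disc intersection
areas come from an exact per-edge decomposition into chord triangles and
circular sectors (Green's theorem), with bounding-box fast paths; raster
extraction uses the cell-centre rule, ignoring missing cells; composite road
lengths ("large and medium", "all roads") are sums of the class-specific
clipped lengths, identical to re-clipping a union for non-overlapping
classes. Inverse distances are floored at one metre so a site touching a
feature cannot produce an unbounded screening variable. Expected signs
encode the prior direction of effect: positive for all road lengths, inverse
distances, household density and commercial/industrial/buildings area;
negative for residential, nature and NDVI. Variables whose source layer is
absent (or, for inverse distances, empty) are dropped with a warning; an
empty household layer legitimately yields zero densities rather than a drop.

## The selection procedure

The model is built for $L_{den}$, the metric that best tracks long-term
annoyance. Stages, all deterministic:

1. **Univariate screen.** Each candidate is regressed on the response
   alone; slope, $R^2$ and sign agreement are recorded.
2. **Best buffer per type.** Within each variable type, only buffers whose
   slope has the expected sign survive; the highest univariate $R^2$ wins,
   exact ties going to the smaller buffer. Types with no correctly-signed
   buffer are dropped.
3. **Forward selection.** Candidates are tried in decreasing univariate
   $R^2$; one enters iff its absolute Pearson correlation with every
   included variable is below 0.7 *and* the adjusted $R^2$ strictly
   increases.
4. **Backward pruning.** While any variable has $p > 0.2$, the worst one is
   removed and the model refitted.
5. **Challenge.** Each remaining variable, in model order, is challenged by
   every candidate of any type and buffer not in the model; a swap is
   accepted iff it strictly improves the adjusted $R^2$, keeps the
   correlation gate, and carries the expected sign. One full pass — repeated
   passes would add a termination argument for no observed benefit.
6. **Final augmentation.** At most one supplementary variable may enter,
   requiring an adjusted-$R^2$ gain, the correlation gate, and $p \le 0.2$.

Open choices resolved here (each the conventional reading): correlation is
Pearson on raw columns, gated on $|r|$; backward removal is largest-$p$
first; sign constraints bind at screening and challenge, not at the
multivariable stages; candidates rejected in the forward pass are not
revisited there (the challenge step provides re-entry); response and
predictors are untransformed, so coefficients are per-unit dB effects. All
remaining ties break by higher adjusted $R^2$, then smaller buffer, then
variable name. Trial designs that are exactly collinear (composites of road
classes can be linear combinations of included variables without any
pairwise correlation reaching 0.7) are inadmissible rather than an error.

Every decision is logged in a trace (screened, buffer chosen, added,
rejected by correlation, rejected for no gain, removed by p-value,
challenged swap, augmented) with the adjusted $R^2$ before and after;
refitting the traced final set reproduces the reported model exactly.

## The synthetic study

`generateLayout()` emulates an informal-settlement study region: a 3 km
square with random road chords in four classes, households clustered around
the monitoring sites over a uniform background, a 250 m land-use tile
mosaic, community point features, and a smoothed Gaussian NDVI field — each
component drawn from its own seeded stream so one configuration change never
perturbs the others. Sites carry quadrant area labels to mimic a multi-area
design. The ground-truth response is linear,
$y = \beta_0 + \sum_k \beta_k x_k + \varepsilon$, with five generating
predictors mirroring the direction of effects observed in the field
(household density, medium- and large-road length, commercial and industrial
area, all positive). Default magnitudes are scaled to the layout so each
contributes about 2 dB of between-site SD; with $\sigma = 1$ dB residual
noise the total response SD lands near the ~4.7 dB observed for measured
$L_{den}$, and the intercept 61.3 dB sits at the observed mean. These
defaults were fixed once from a pilot layout's feature scales.

`generateSeries()` writes the acoustic side of the truth: per-second dB
levels drawn around the period targets (the Gaussian dB scatter inflates an
energetic mean by $\sigma^2\ln 10/20$, which the generator subtracts), one
contiguous seeded gap for missingness, and isolated single-second +25 dB
spikes. Spike times and the gap are recorded in the series metadata, so
tests can score the 3-SD rule's sensitivity (≥ 90% of injected spikes
caught; false removals at the ~0.27% Gaussian tail mass). Note the detection
margin is thinnest for night-period spikes, which sit closer to the pooled
five-day mean — a real property of a pooled-SD rule.

What the simulation does *not* emulate: spatially correlated residual noise,
non-linear source physics (propagation, shielding), measurement drift,
seasonal confounding, or GIS inaccuracy. Passing recovery tests therefore
demonstrates the correctness of the pipeline's computations and the
procedure's behaviour under its own assumptions — not that a field LUR with
these predictors would reach any particular $R^2$: on real data those
unmodelled influences are precisely what depresses the explained variance.

## Validation design

* **Closed-form oracles.** Energetic means, $L_{den}$ identities, chord
  lengths $2\sqrt{r^2-d^2}$, half-plane polygon areas, the class-partition
  additivity of road lengths, and dimensional scaling checks.
* **Exhaustive oracle.** With six or fewer screened candidates and a
  noiseless response, the stepwise procedure must select exactly the same
  set as an independent exhaustive best-subset search under the same
  correlation constraint (20 seeded instances). The noiseless setting makes
  the adjusted-$R^2$ landscape flat at the optimum, so both searches stop at
  the minimal exact-fit set.
* **Recovery experiment.** 50 seeded studies at 200 sites, $\sigma = 1$ dB:
  the five generating variable types must appear in the final model in at
  least 90% of seeds, and the 95% CIs of the exactly-recovered coefficients
  must cover their truth at a 90–98% empirical rate. "Recovery" is
  deliberately scored as sure-inclusion of the generating types: a
  procedure that retains variables at $p \le 0.2$ *by design* admits an
  occasional weak extra, so exact-set equality is not the property the
  procedure promises.
* **OLS identities.** On the training set the variance of the predictions
  equals $R^2$ times the variance of the measurements (to $10^{-6}$), which
  is the formal version of the narrower predicted-level histograms the
  evaluation reports.

Problem sizes in the default test runs (five-day windows at full 1-second
resolution, 200-site layouts, 50-seed recovery) were chosen so the whole
suite completes in a few minutes on a single core while keeping every rule
at its real operating scale — the completeness boundary, in particular, is
only meaningful against the full 432,000-second window.

## Limitations

* The model is purely correlative; no propagation physics, no traffic
  volumes, no temporal structure beyond the day/evening/night split.
* Predictions carry no extrapolation guard; applying the model outside the
  training feature ranges is the caller's responsibility.
* Per-area evaluation uses the squared Pearson correlation of the common
  model within each area (no per-area refits), and areas with fewer than
  three sites report no $R^2$.
* The GeoJSON reader handles the subset of the format the pipeline writes
  (single-ring polygons, per-feature properties); raster ingestion is
  ESRI ASCII grid.
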