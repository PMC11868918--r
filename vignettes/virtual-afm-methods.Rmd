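---
title: "Methods: a virtual AFM workbench for single-cell mechanics in co-culture"
author: "cellAFM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a virtual AFM workbench for single-cell mechanics in co-culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cellAFM` rebuilds, in software, the workflow of an image-guided AFM
experiment on high-density co-cultured cells: recognize the two cell types
and the spherical probe in a bright-field image, move the probe onto chosen
cells, record force curves, and extract the Young's modulus (indentation
assay) or the cell–cell adhesion force (SCFS assay) per cell, then compare
the two cell-type populations. Because every scene and every curve is
generated from known truth, the whole analysis chain is validated by
parameter recovery rather than by comparison with live-cell data. This
vignette records the models, the defaults and why they were chosen, the
numerical decisions, and what the validation does and does not establish.

## The scene generator

A scene is a field of view of 512 × 512 px at 0.65 µm/px (the pixel size is
a simulator convention — typical for a 20× objective — since no
magnification is prescribed by the workflow itself). Cells are ellipses
with equivalent radius drawn per type (type A: 12.5 ± 1.2 µm; type B: 16.25
± 1.6 µm, i.e. ~30% larger), mild eccentricity (axis ratio 0.78–1) and
uniform orientation. Each cell carries true mechanical parameters: a
log-normal Young's modulus (type A: log-mean log 3000 Pa; type B: log 6000
Pa; log-SD 0.35 — cell stiffness distributions are right-skewed, and the
factor-two separation mirrors the qualitative ordering reported between
co-cultured gastric cancer lines) and a truncated-normal adhesion force
(type A: 1.2 ± 0.25 nN; type B: 2.4 ± 0.4 nN, values in the usual nN range
of cell–cell adhesion).

Placement is dart-throwing: a candidate is accepted when its pairwise
overlap with every placed cell (computed analytically on equivalent
circles) stays below a cap, and rejected candidates trigger radius
resampling after 50 tries. Two caps implement the biology of "high-density
co-culture means different cell types in physical contact": cross-type
pairs may overlap up to 25% of the smaller cell's area, same-type pairs
only 10%. The second cap is what keeps the per-channel fluorescence
components separable (a same-type pair that overlapped deeply would merge
into one component in its channel, which no segmentation could undo); it is
also consistent with the checkerboard mixing of a well-mixed co-culture.
The larger type is placed first because packing is tightest for big cells.
The high preset places 80 cells per type (coverage settles at ~81–85%,
comfortably above the 60% definition of high density) — enough that 50
targets per type survive detection misses and border exclusions. The low
preset places 6 cells per type with a strict no-touch rule (center distance
above the radius sum plus 2 px), staying below the 10% definition. A
geometrically unreachable preset (too many cells for the field, or too few
to reach 60%) fails with an explicit density error rather than silently
degrading.

Coverage is computed by rasterizing every ellipse (a pixel is covered when
its center lies inside) and counting the union mask, so overlap handling is
exact by construction; the acceptance script reports the min/max coverage
over 20 seeded scenes per preset.

Rendering gives each cell a bright halo ring (width 2.5 px) and a darker
interior with type-specific texture: fine (smoothing scale 1 px, amplitude
0.04) for type A, coarse (3 px, 0.05) for type B, and a slightly brighter
ring for type B (0.84 vs 0.74 against a 0.55 background). These are
declared simulator conventions that make a classical detector viable — not
biological claims. Cells are drawn in placement order, so the ring of the
cell on top separates the two interiors where cells touch, exactly as
overlapping adherent cells present in bright-field. The probe is a bright
disc with a dark rim. A smooth illumination field (tilted plane plus one
low-frequency mode, amplitude 0.04) and Gaussian noise (SD 0.01 of full
scale) are added last. Fluorescence channels are noisy indicator masks
(interior 0.6, background 0.02) with strict channel–type correspondence.

What the generator does *not* emulate: phase-contrast optics, defocus,
motile or dividing cells, debris, more than two cell types, and realistic
fluorescence bleed-through. Detector performance numbers measured on these
scenes therefore characterize the pipeline's logic, not expected
performance on real micrographs.

## Detection and its evaluation

The default detector is deliberately classical and deterministic. The
bright-field image is flattened by subtracting a heavy Gaussian blur
(σ = 50 px, capped for small images), removing the illumination gradient
and local background. Cell interiors are segmented as dark regions
(threshold −0.02 after σ = 2.5 px smoothing); halo rings act as natural
separators between touching cells, holes from interior texture are filled,
and residual merges are split by watershed on the distance map (tolerance
3). Each component is classified by two features with fixed linear rules:
equivalent radius (threshold 14.4 µm, the midpoint of the two types' means)
and the log-ratio of coarse-band to fine-band texture energy (threshold
0.33, the midpoint of the two types' empirical distributions in the
rendered scenes — the detector is calibrated once against the simulator, as
any detector is calibrated against its training domain). The decision
margin maps through a logistic onto confidence in (0.5, 1]. The probe is
found as the bright compact component closest to the expected disc area.
Greedy non-maximum suppression at IoU 0.5 removes duplicates.

Detection quality is scored by greedy confidence-ordered one-to-one
matching against ground-truth boxes at IoU ≥ 0.5, label-sensitive, with
0/0 precision and recall defined as 1 so empty scenes are not pathological.
The matching convention is stated explicitly because published precision
figures for detector networks rarely state theirs; the harness makes the
threshold a parameter. Externally produced boxes (e.g. from a trained
network) can be evaluated and used for targeting through the YOLO-txt /
COCO-JSON readers — the pipeline's contract is "boxes in, moves out".

## Targeting

The "central area" of a cell is operationalized as its box center (the
cross inside a detection box); no mask-centroid refinement is attempted, so
targeting remains detector-agnostic. Stage calibration is a least-squares
affine map from pixels to stage microns (exact for truly affine pairs;
degenerate point sets are rejected), and all axis conventions live inside
that affine — no hidden flips. Moves are differences of affine-mapped box
centers; the virtual stage applies the inverse-linear-part displacement to
the scene's probe. Target selection orders boxes per label by descending
confidence (ties by appearance order), excludes boxes within 8 px of an
image edge and boxes whose center lies inside the probe box, and returns at
most the requested number per type. The confidence-ordered policy is a
declared convention; the source workflow does not state one.

## The virtual AFM

Indentation curves solve, per sample, the implicit cantilever–sample
balance `k d = (4/3) · E/(1−ν²) · √R · δ^{3/2}` with `δ = (z − z0) − d`
(spherical-indenter Hertz model in the paraboloid approximation, the
standard choice for microsphere probes on cells; ν defaults to 0.5 for an
incompressible cell). The left side is linear and the right side decreasing
in `d`, so the root is unique; a Newton iteration safeguarded by bisection
converges to relative tolerance 1e-10 with warm starts along the ramp.
Units are reconciled once (z µm, d nm, F nN, k N/m, R µm, E Pa) and
property-tested. The approach stops at the force setpoint (default 5 nN);
the retract retraces the elastic curve. Drift (0.5 nm/µm) and Gaussian
deflection noise are added after the physics, under the curve's seed.

SCFS retractions are phenomenological: past the contact point the force
ramps linearly to exactly −F_adh at one quarter of the detachment
separation (the apex is snapped to the nearest retract sample so the
noise-free minimum is exact), then returns to baseline through
`nRuptureSteps` equal upward jumps, reaching zero at the detachment
separation (default 1.5 µm). No receptor-bond kinetics are modeled: the
read-out of interest is the peak adhesion force, which this construction
reproduces by design. Defaults for the cantilever (k = 0.05 N/m, R = 5 µm)
are documented package conventions for soft-cell work, not asserted
instrument values.

## Force-curve analysis

Baseline correction fits a line to the first 30% of the approach and
subtracts it from both segments. The contact point is found by a grid
search over candidate contact samples scoring a piecewise model — flat
baseline before, Hertz `B δ^{3/2}` after, with `B` profiled out in closed
form — by total residual; a coarse-to-fine scan (every 4th sample, then a
±5 neighborhood) keeps it near-linear in curve length, and parabolic
interpolation of the residual valley gives sub-sample resolution. This
shares the Hertz model with the subsequent fit and is fully deterministic;
a ratio-of-variances pre-screen was considered and rejected as a second
method to maintain. A curve whose best piecewise model fails to improve on
the all-baseline model by 10%, or whose maximum force stays within 6
baseline SDs, raises a no-contact error — the path exercised when the
virtual probe misses a cell.

The Hertz fit minimizes squared force residuals over post-contact samples
with δ capped at 80% of the maximum indentation (shallow-indentation
practice; the cap is configurable), initialized by the closed-form profiled
estimate and refined by a joint BFGS optimization of `(B, z0)` at relative
tolerance 1e-14; the fitted subset is recomputed once at the refined
contact point. Convergence requires optimizer success and a finite positive
modulus; non-converged curves are excluded from per-cell aggregates, never
imputed, and counted.

Adhesion: the base definition is the magnitude of the most negative
baseline-corrected retract force. A raw per-sample minimum is biased upward
by noise (the minimum of several near-minimal samples plus noise is an
extreme-value statistic), so whenever a clear rupture edge (upward jump
above 6 baseline SDs) borders the minimum, the peak is re-read from a line
fitted to the loading ramp up to that edge, evaluated at the edge — the
usual way rupture forces are read off force-spectroscopy curves. Noise-free
curves are reproduced exactly by both paths. Work of adhesion integrates
the contiguous negative-force region containing the minimum by the
trapezoid rule (nN · µm = fJ); rupture steps are upward jumps above 5
baseline SDs inside the well.

Per-cell aggregation is the arithmetic mean of the (default 10) curves,
with the unbiased SD; the median is available. The aggregation rule for
repeated curves on one location is not dictated by the workflow, so the
mean is a declared default.

## Population statistics and the experiment driver

Per-type summaries fit the Gaussian by maximum likelihood on the raw
per-cell aggregates (µ = mean, σ = SD), so the fit is independent of the
histogram binning; the histogram overlay scales the density by n ×
binwidth. All-equal values are reported as a degenerate fit rather than an
error. The two-type comparison reports the difference of means, the
ordering, and a rank-based (Wilcoxon) p-value as a descriptive quantity —
no significance threshold is hard-coded because the claim of interest is an
ordering.

`runExperiment()` chains everything with full seed discipline: a master
seed derives the scene, render and per-curve seeds through a multiplicative
hash that keeps every derived seed a valid 32-bit integer, so two runs with
the same config are byte-identical in every CSV/JSON artifact. Defaults
mirror the reference experimental design — 50 cells measured per type, 10
curves recorded per cell. Every selected target either yields its full
complement of analyzed curves or is logged as an exclusion; a probe landing
off every cell mask produces a baseline-only curve that the no-contact path
rejects, and the miss is logged.

## Problem sizes and runtime

The validation suite runs on desk-scale sizes chosen so the whole suite
stays in the minutes range: 600-sample ramps, 200-curve Monte-Carlo
recovery for the modulus (E log-uniform 0.5–50 kPa at 2% force noise),
100-seed adhesion recovery at 0.05 nN noise, 50-seed contact-point recovery
at 1% noise, 10 rendered high-density scenes for the detector, 20 seeds per
density preset, 100 low-density scenes for targeting round-trips, and one
full default experiment (100 cells × 10 curves). These sizes are the
package's validation conventions; all are parameters.

## Known limitations

* The simulator's bright-field appearance model is stylized; the default
  detector's measured precision/recall characterizes pipeline logic on that
  model only and says nothing about trained-network performance on real
  micrographs, which the pluggable box readers exist to ingest.
* The Hertz model assumes an elastic half-space: no viscoelasticity,
  hydrodynamic drag, finite cell thickness (bottom-effect) correction, or
  cantilever dynamics. Fitted moduli inherit those assumptions.
* SCFS curves are phenomenological; rupture-step counts and work of
  adhesion are defined relative to that construction, and only the peak
  adhesion force should be compared across models.
* The affine stage calibration assumes a rigid, non-drifting mapping for
  the duration of a run; thermal drift beyond the linear deflection
  baseline is out of scope.
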