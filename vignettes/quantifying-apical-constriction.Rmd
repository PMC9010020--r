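---
title: "Quantifying apical constriction from cell and junction tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying apical constriction from cell and junction tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(constrictr)
```

## The measurement model

`constrictr` analyzes time-lapse records of an epithelium during neural
tube closure: per-frame tables of tracked apical cell surfaces and of
tracked cell–cell junctions, plus (optionally) the label images and
fluorescence channels they were measured from. The biological quantities
of interest are apical constriction (loss of apical area), the
accumulation of actin and N-cadherin in two subcellular domains — the
*junctional* belt and the *medial* free apical surface — and the
polarized shrinking/growth of junctions that drives convergent extension.
In mosaic CRISPR experiments a membrane-BFP tracer marks crispant
lineages, so control and mutant cells are observed side by side in the
same tissue under identical staging.

### Domain intensities on label images

A segmented frame assigns label *k* to cell *k* and 0 to the 1-px
boundary skeleton. The medial domain of a cell is its pixel region after
a one-pixel constriction; we implement this as erosion by the 3×3
(8-connected) structuring element, the convention of skeleton-based
tissue segmentation tools. The junctional domain is the set of skeleton
pixels 8-adjacent to the region. Domain intensity is the mean of the
channel over the domain's pixels (total fluorescence divided by area).
Cells so thin that erosion empties them are flagged degenerate and their
medial values reported missing rather than zero.

For a single junction between cells *a* and *b*, the junction pixel set
is the skeleton 8-adjacent to both regions, *excluding* vertex pixels
(skeleton pixels bordering three or more cells) so that pairwise
junctions do not double-count their shared endpoints; a cell's junctional
domain, by contrast, retains its vertices. When a z-stack is available,
each junction endpoint's depth is taken where the maximum-intensity
projection sampled the stack (argmax over z at the vertex pixel, ties
resolved deterministically to the smallest z), and the endpoint depth
difference yields `delta_z_micron`.

### Track preprocessing

Raw per-frame series are processed per track in a fixed order —
**mask → filter → smooth → convert → standardize** — recorded in each
run's manifest:

1. *Masking.* Frame ranges with imaging anomalies (e.g. a transient
   fluorescence drop) have their fluorescence values set to missing;
   geometry is retained and tracks are not split, since the cells remain
   tracked through the anomaly. Masked frames contribute nothing to any
   later window or statistic.
2. *Filtering.* Cell tracks shorter than 30 frames and junction tracks
   shorter than 15 frames are discarded (1 frame = 1 minute).
3. *Smoothing.* A centered 7-frame moving average (−3 to +3 frames). At
   track ends the window is truncated to the available frames rather than
   trimming three frames per end, so the smoothed series spans the whole
   track. Windows average only usable values.
4. *Unit conversion.* Pixel areas and lengths scale by the embryo's pixel
   size (`s²` and `s`). Junction lengths are corrected for
   z-displacement as `sqrt(length² + dz²)` — the unique choice that
   restores the 3D chord length a projection forecloses.
5. *Standardization.* Each track's smoothed series is mean-centered and
   divided by its own sample standard deviation (the `scale()`
   convention, *n*−1 denominator), so all dynamics are expressed in
   standard deviations of that track. This removes between-cell variation
   in initial size and expression level; statistics are computed over
   usable frames only, and constant tracks are flagged degenerate instead
   of dividing by zero.

The per-track **delta statistic** (final minus initial standardized
value) summarizes net constriction (negative for area) or net marker
accumulation. Paired delta scatters are summarized by quadrant
percentages, with zero deltas counted in the non-negative quadrants —
ties have measure zero in continuous data, so the convention is
documented rather than consequential.

### Genotype calling and the mosaic interface

Genotype is a lineage property, so each cell gets one label from the
track-mean of its medial membrane-BFP. The per-embryo threshold is the
config value when supplied; otherwise an automatic bimodal split
maximizes between-class variance (Otsu, 256 bins) on the log10 score
histogram. If the class means separate by less than twice the pooled
within-class spread the distribution is judged unimodal and all cells
fall back to control with a warning — the real analyses used manual
per-embryo thresholds, so the config override is authoritative, and
manual per-cell overrides (for ambiguous cells along the interface) are
applied last. Cells that ever border the opposite genotype, and
junctions between opposite genotypes, are flagged `at mosaic interface`
and excluded from every statistical comparison.

### Orientation conventions

Junction orientation is the acute angle to the embryo's mediolateral
axis, folded to [0°, 90°]: ML-aligned junctions read 0°, AP-aligned 90°.
The AP axis's image-frame angle is a per-embryo config value (how it was
originally annotated is a property of the experiment, not of this
package; the synthetic default is 90°, AP vertical). The result is
invariant to endpoint order and to jointly rotating segment and axis.
Junctions with mean orientation below 45° are classed AP (they join an
anterior neighbor to a posterior one), at or above 45° ML; the paper-side
definition uses strict inequalities on both sides, so the 45° boundary is
assigned to ML by documented choice.

### T1 neighbor exchanges

A T1 transition swaps one junction for its orthogonal partner: cells
(A, B) lose contact and the two cells (C, D) flanking the lost junction
gain one. `detect_t1()` scores an event when a loss of adjacency persists
at least `k_stable = 5` frames, a gain of (C, D) — common neighbors of A
and B at the loss — begins within ±3 frames and also persists ≥ 5
frames. The persistence criterion of the original tracking software is
unpublished, so 5 frames (≈ 5 min) is a documented, configurable default;
conclusions should be checked for sensitivity to `k_stable` rather than
assumed robust. The ±3-frame pairing window tolerates the transient
four-fold vertex. Each stable event increments the exchange count of all
four cells, so per-cell counts sum to 4× the event count.

## Statistical tests

Distribution shifts are compared with the two-sample Kolmogorov–Smirnov
test: `D` is the supremum ECDF distance computed by a scan over the
pooled values (right-continuous ECDFs handle ties), and the p-value uses
the asymptotic Kolmogorov distribution at effective size
`n_a n_b / (n_a + n_b)`. At the sample sizes used here the asymptotic
test is slightly conservative (its exact level at n = 50 per group is
≈ 0.039 at nominal 0.05, from the discreteness of D), which the null
calibration checks make visible.

Paired-delta distributions are compared in 2D with the Peacock test: the
statistic is the maximum over origins, and over the four quadrant
orientations at each origin, of the absolute difference in empirical
quadrant fractions. Two origin sets are provided: the full pooled
x × pooled y coordinate grid (Peacock's original proposal; the default)
and the pooled sample points only (the Fasano–Franceschini economy,
whose statistic can never exceed the full-grid one). The implementation
uses 2D prefix sums over the rank grid — algebraically identical to
direct quadrant counting but O(n²) per evaluation — and is verified
against a literal origin-loop counter in the test suite. Because the
test's asymptotic null is poorly behaved, p-values come from label
permutation of the pooled sample, `p = (count + 1)/(n_perm + 1)`, with an
explicit seed recorded in the manifest (default 999 permutations; the
calibration studies use 199, which preserves the exact 5% level since
10/200 = 0.05). Pearson correlations (with t-transform p and best-fit
line) quantify the coupling between area and marker dynamics on pooled
observations. No multiple-testing correction is applied, matching the
analysis style this package reproduces.

## The synthetic epithelium

The generator stands in for deposited tracking data: it produces tables
in the exact schema, with known ground truth, so every stage — reading,
preprocessing, genotyping, measurement, T1 detection, statistics — can be
validated end to end.

* **Mesh.** A jittered hexagonal tessellation with shared vertices. A
  honeycomb (rather than a jittered-lattice Voronoi diagram) provides the
  same guarantees that matter — every interior edge is bordered by
  exactly two cells, vertices are shared objects, Euler's formula holds —
  while keeping T1 topology well defined: the two cells at the ends of
  any edge are adjacent to both of its flanking cells, exactly the
  four-cell motif a neighbor exchange needs.
* **Kinematics.** Per-cell target areas follow regime trajectories and
  shared vertices relax toward them (bounded per-step rescaling about
  each cell centroid, averaged over the cells sharing each vertex, 4
  iterations/frame). This is deliberately *not* a force-balanced vertex
  model: the artifact needs kinematically consistent tracked geometry —
  areas, junction lengths and orientations that co-vary — not tissue
  mechanics.
* **Regimes.** Anterior-like control cells constrict gradually from the
  start (95% constricting to ~50% of initial area); anterior-like
  crispants are dilation-biased (70% dilating by 10–50%). Posterior-like
  tissue mixes late-onset rapid constriction (onset ~75% through the
  movie) with drift/dilation. These defaults mirror the qualitative
  regional behaviors of the system and are configuration, not asserted
  biology.
* **Intensities.** Each channel is a baseline modulated by
  `r · (−z_area) + sqrt(1 − r²)/g · ε`, where `z_area` is the cell's
  standardized area trajectory, `ε` is AR(1) noise (ρ = 0.8 by default,
  so that 7-frame smoothing is exercised meaningfully) and `r` the
  per-regime, per-genotype coupling (anterior control defaults:
  −0.7 for actin, −0.6 for N-cadherin; near zero for crispant and
  posterior N-cadherin). The factor `g` is the analytically known s.d.
  retention of a centered 7-frame mean over AR(1) noise
  (`g² = (w + 2·Σ(w−k)ρᵏ)/w²`): the coupling parameter is defined as the
  correlation of the *analyzed* series (smoothed, per-track
  standardized), so the generator pre-compensates its noise for the
  smoothing attenuation rather than targeting the raw-frame correlation.
* **Genotype and events.** Membrane-BFP is bimodal by genotype (modes
  100 vs 1000, s.d. 50) and the crispant half-plane is spatially
  contiguous, so a mosaic interface exists. Scripted T1 events collapse a
  chosen edge at a given frame and grow the orthogonal junction from its
  midpoint.
* **Rendering.** Frames rasterize the polygons with a 1-px skeleton
  (no two distinct labels 4-adjacent), paint medial domains uniformly
  with the tabulated per-cell values and skeleton pixels with the mean of
  their flanking cells' junctional values, and record the per-domain
  means actually painted by independent pixel enumeration — closing the
  loop with the measurement module.

What the generator does **not** emulate: segmentation error and track
breakage, pulsatile (sub-minute) contractility, cell division and
extrusion, mechanical force balance, and realistic point-spread/noise
structure in the rendered images. Tests passing on synthetic data
therefore validate the *pipeline definitions* — filters, windows,
standardization, exclusions, detection logic, statistics — not the
biological conclusions one would draw from real embryos.

## Numerical choices and problem sizes

Degenerate inputs never produce silent zeros: empty masks, constant
tracks and unimodal BFP distributions yield missing values or flagged
fallbacks. Missing values serialize as empty CSV cells and parse back as
missing. Doubles round-trip bit-faithfully through the table files
(shortest round-trip representation), which is what makes whole-pipeline
re-runs byte-identical and the manifest sufficient for reproduction.

The validation suite sizes its simulations to be decisive but small:
statistic oracles on 200 random instances of ≤ 40 points per sample,
null calibration on 500 simulations of n = 50 per group, parameter
recovery on a 300-cell × 60-frame cohort, and T1 recovery on 80-cell
meshes with 0, 1 or 3 scripted events. These were chosen as the smallest
sizes at which the checked properties are sharp (e.g. ±2 binomial
standard errors at 500 draws distinguishes calibrated from conservative
behavior).

## Known limitations

* The automatic BFP threshold is a stand-in for per-embryo manual
  thresholds; runs relying on it should report it (it is recorded in the
  genotype call attributes and the manifest).
* The Peacock variant and p-value method behind published analyses of
  this kind are often unspecified; both variants are provided and the
  manifest records which was used, but numeric p agreement with any
  particular external implementation is not a goal.
* `detect_t1()`'s stability constant is a convention; report sensitivity.
* The per-vertex z-lookup contract assumes the projection's argmax map is
  available or reconstructable; without a stack, `delta_z_micron` must
  already be present in the tables for length correction.
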