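# constrictr

Tissue-scale quantification of apical constriction from tracked-cell and
tracked-junction tables.

During neural tube closure, neuroepithelial cells shrink their apical
surfaces (apical constriction) while remodeling junctional and medial
(free apical surface) pools of actin and N-cadherin. Modern time-lapse
pipelines segment and track hundreds of cells and thousands of cell–cell
junctions per embryo, producing frame-by-frame tables of areas, junction
lengths, orientations and per-domain fluorescence. `constrictr` implements
the downstream analysis of such tables for mosaic CRISPR experiments,
where control and crispant lineages (marked by a membrane-BFP tracer)
share one epithelium:

* **Typed table I/O** — readers/writers and invariant validation for the
  four tracking tables (`cell_surfaces`, `junctions`, `cell_surface_stats`,
  `junction_stats`), with vertex outlines in `X:Y#X:Y` format and
  per-embryo calibration in a YAML config.
* **Image measurement** — per-cell medial/junctional domain splitting on
  label images (medial = region eroded by one pixel with the 3×3
  structuring element; junctional = boundary-skeleton pixels 8-adjacent to
  the region), domain mean intensities, per-junction pixel sets with
  vertex exclusion, and z-displacement from projection argmax.
* **Track preprocessing** — discard cell tracks < 30 frames and junction
  tracks < 15 frames; 7-frame centered moving-average smoothing (truncated
  at track ends); per-track standardization
  `z_t = (x_t - mean(x)) / sd(x)` so dynamics are measured in s.d. of each
  track; anomaly-frame masking of fluorescence (geometry retained);
  pixel→micron conversion.
* **Mosaic genotyping** — per-track BFP score, per-embryo threshold
  (manual or Otsu's between-class-variance split on the log-score
  histogram), manual overrides, per-frame neighbor genotype counts,
  mosaic-interface flags, and junction status
  (control / crispant / at mosaic interface). Interface cells and
  junctions are excluded from all comparisons.
* **Geometry** — shoelace polygon area; junction z-correction
  `L = sqrt(L_xy^2 + dz^2)`; orientation folded to [0°, 90°] with the
  mediolateral (ML) axis at 0° and the anteroposterior (AP) axis at 90°;
  AP/ML classification at the 45° boundary.
* **Dynamics** — delta statistics (final − initial standardized value),
  per-track summary tables, quadrant percentages of paired delta scatters,
  and stable T1 neighbor-exchange detection (loss and orthogonal gain each
  persisting ≥ 5 frames, paired within ±3 frames).
* **Statistics** — two-sample Kolmogorov–Smirnov
  (`D = sup |F_a - F_b|`, asymptotic p with effective
  `n = n_a n_b / (n_a + n_b)`); the Peacock two-dimensional KS test
  (max quadrant-probability difference over the pooled coordinate grid,
  or over sample origins à la Fasano–Franceschini) with label-permutation
  p-values; Pearson correlation with best-fit line; and a batch comparison
  runner.
* **Synthetic epithelium generator** — a jittered hexagonal tessellation
  with shared vertices evolved by per-cell area targeting, with
  region-specific constriction regimes, intensity channels coupled to
  standardized area with AR(1) noise, bimodal BFP by genotype, scripted T1
  events, and raster rendering with painted per-domain means; full ground
  truth is retained so every pipeline stage can be validated end to end.

## Worked example

Simulate a mosaic anterior-like sheet (150 cells, 60 minutes, 30%
crispant), run preprocessing, call genotypes, flag the interface and
compare the crispant and control constriction distributions:

```r
library(constrictr)

cfg  <- synthetic_config(n_cells = 150, n_frames = 60, seed = 1,
                         crispant_fraction = 0.3)
sim  <- simulate_epithelium(cfg)
ecfg <- embryo_config("sim_a", "anterior", microns_per_pixel = 0.5)

ds     <- preprocess_tables(sim$dataset, ecfg)
calls  <- call_genotype(ds$cell_surfaces, ecfg)
labels <- setNames(calls$CRISPR, calls$track_id_cells)
flags  <- flag_interface(neighbor_counts(sim$adjacency, labels), labels)
ds     <- summarize_tracks(ds, interface_flags = flags)

st   <- ds$cell_surface_stats
kept <- st[!st$at_mosaic_interface, ]
ks_2sample(kept$delta_apical_area[kept$CRISPR == "control"],
           kept$delta_apical_area[kept$CRISPR == "shroom3 crispant"])
#> Two-sample Kolmogorov-Smirnov test
#>   statistic = 0.967742, p = 3.101e-19 (asymptotic)
#>   n = 91, 31

round(quadrant_fractions(kept$delta_apical_area, kept$delta_medial_actin), 1)
#> x_neg_y_neg x_neg_y_pos x_pos_y_neg x_pos_y_pos
#>         4.9        70.5        13.1        11.5
```

The KS comparison separates the two cohorts almost completely
(D close to 1): in this configuration nearly all control cells constrict
while most crispant cells dilate. The quadrant table reads the paired
delta scatter: 70.5% of non-interface cells lost apical area
(`x_neg`, delta area < 0) while gaining medial actin (`y_pos`), the
signature of constriction-coupled actin accumulation; the `x_pos` columns
collect the dilating (mostly crispant) cells.

The same flow is available from a shell via
`inst/scripts/constrictr-run.R` (subcommands `simulate`, `preprocess`,
`analyze`, `stats`, `report`, `all`; every run writes a `manifest.json`
that reproduces it).

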