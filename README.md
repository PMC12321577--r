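# septastro

Cell-level quantification of astrocyte regional identity in the mouse
septum from multichannel fluorescence z-stacks — paired with a
synthetic-microscopy generator so that every measurement is testable by
parameter recovery against complete ground truth.

## The scientific problem

Septal astrocytes are regionally specialized: cells of the medial septum
(MS) differ from those of the dorsal, intermediate and ventral lateral
septum (dLS/iLS/vLS) in morphology, orientation, synaptic environment and
lineage. Establishing that from tissue imaging requires a handful of
quantifications, all implemented here:

- **Morphometry** of sparsely labelled astrocytes: nucleus-to-tip longest
  branch, length-to-width ratio of the arbor, orientation of its long axis
  relative to the septal midline (binned in 30° sectors), convex-hull
  territory area/volume, and Sholl profiles.
- **Synaptic puncta**: 3-D spot detection in pre- and postsynaptic
  channels, one-to-one colocalization within 0.5 µm, and colocalized-pair
  density per astrocyte territory (pairs per mm³).
- **Transcript puncta**: spots per nucleus and per-region densities
  normalized to the MS.
- **Lineage census**: per-region fractions of reference-marker-positive
  cells (e.g. Sox9) that carry a lineage reporter (e.g. GFP), and regional
  cell densities.
- **Statistics**: one-way ANOVA with Tukey's multiple-comparison test and
  mean ± s.e.m. summaries.

Because raw tissue stacks for such studies are rarely available, the
package includes a generator (`synth_config()`, `simulate_septum()`,
`render_cells()`, `sample_puncta()`, `sample_census()`) that produces
multichannel TIFF z-stacks, a region atlas, and full ground truth. The
model and every numerical choice are documented in the methods vignette
(`vignettes/astrocyte-regional-identity.Rmd`).

## Worked example

The numbered scripts under `analysis/` form the full workflow. They
simulate one septum field (160 × 160 µm, five labelled astrocytes per
region, seed `20250101`), measure it, and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # field + ground truth -> results/simulation/
Rscript analysis/02_morphometry.R   # per-cell morphometry -> morphometry.csv, angle_bins.csv
Rscript analysis/03_synapses.R      # puncta + territories -> synapse_density.csv, regional_density.csv
Rscript analysis/04_census.R        # lineage census       -> lineage_fractions.csv, cell_density.csv
Rscript analysis/05_stats.R         # group statistics     -> stats.csv, summary.csv
```

Output of that run (every number regenerates exactly from the seed):

```
01: simulated 19 astrocytes, 2588 pre / 3314 post puncta, 400 census cells
02: measured 19 cells (0 excluded as border-touching)
    longest branch: measured 49.2 um vs true 49.8 um (mean)
03: detected 2572 pre (true 2588), 3275 post (true 3314), 674 pairs (true 746)
    territory synapse density: mean 4.99e+06 per mm3 over 19 cells
04: MS   double-positive fraction 0.770 (n_ref 100), 15625 cells/mm2
    dLS  double-positive fraction 0.000 (n_ref 100), 15605 cells/mm2
    iLS  double-positive fraction 0.020 (n_ref 100), 15664 cells/mm2
    vLS  double-positive fraction 0.130 (n_ref 100), 15605 cells/mm2
05: longest_branch_um    F(3,15) = 3.02, p = 0.0626
    lw_ratio             F(3,15) = 0.80, p = 0.515
    territory_area_um2   F(3,15) = 11.30, p = 0.000392
```

The regional contrasts under study are visible even at this small n: MS
astrocytes point along the midline (orientation fractions in the
[0°, 30°) bin: 0.75 in MS vs 0.36 in pooled LS; `angle_bins.csv`), the
census recovers the generator's double-positive probabilities
(0.74/0.001/0.02/0.12), and transcript density relative to MS stays
within ~5% of 1 in a spatially uniform field (`regional_density.csv`).

A minimal interactive session:

```r
library(septastro)
cfg  <- synth_config(branch_length_sd_um = 0)   # 40 um branches exactly
pipe <- septastro_config()
set.seed(1)
cell <- sample_arbor(cfg, soma_yx_um = c(60, 60), cell_id = 1L)
st   <- render_cells(list(cell), cfg, shape_yx = c(600, 600))
arb  <- segment_arbor(st, "tdT", cell$soma_yx_um, pipe)
longest_branch(skeletonize_arbor(arb, pipe))
#> [1] 39.76129   (truth: 40; thinning erodes ~half a branch width at the tip)
```

## Layout

- `R/` — the package: io, geometry, filters, synthesize, segmentation,
  morphometry, puncta, census, stats.
- `tests/testthat/` — unit, property/oracle and end-to-end recovery tests.
- `analysis/` — the numbered workflow drivers shown above.
- `scripts/acceptance.R` — standalone reproduction script.
- `vignettes/astrocyte-regional-identity.Rmd` — methods: model,
  assumptions, tunables (with units and defaults), numerical choices and
  limitations.
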