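---
title: "Methods: quantifying astrocyte regional identity from synthetic multichannel z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying astrocyte regional identity from synthetic multichannel z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scientific problem

Astrocytes in the septum are not a uniform population: cells in the medial
septum (MS) differ from those in the lateral septum (LS, with dorsal,
intermediate and ventral subdivisions dLS/iLS/vLS) in developmental origin,
morphology and synaptic environment. Establishing such regional identity
from tissue imaging rests on a handful of cell-level quantifications:

* **Morphometry** of sparsely labelled astrocytes — the distance from the
  nucleus to the tip of the longest branch, the length-to-width ratio of
  the arbor, and the orientation of the arbor's long axis relative to the
  septal midline, summarized as fractions per angle bin.
* **Synaptic puncta colocalization** — pre- and postsynaptic marker spots
  paired one-to-one when closer than a colocalization radius, counted
  inside each astrocyte's territory (the convex hull of its arbor) and
  reported per unit volume.
* **Transcript puncta** — single-molecule in situ spots counted per
  nucleus, and per-region spot densities normalised to the MS.
* **Lineage census** — fractions of astrocytes (reference marker, e.g.
  Sox9) carrying a lineage reporter (e.g. GFP), per region, plus regional
  astrocyte densities.
* **Group statistics** — one-way ANOVA with Tukey's multiple-comparison
  test and mean ± s.e.m. summaries.

Raw tissue images for such studies are typically not deposited, so this
package pairs every measurement operator with a **synthetic-microscopy
generator** that produces multichannel z-stacks with complete ground truth.
Every pipeline stage is then testable by *parameter recovery*: simulate
with known parameters, render, measure, and compare.

# Coordinate and unit conventions

* Voxel indices are 0-based with axis order `(channel, z, y, x)`; physical
  positions in micrometres are `index * voxel_size_um`, with voxel centres
  at integer indices.
* The region atlas is 2-D (one coronal plane), labels
  `{0 background, 1 MS, 2 dLS, 3 iLS, 4 vLS}`, with a unit midline-axis
  vector in `(y, x)`; the default preset uses `(1, 0)`, the dorsoventral
  image y axis.
* Morphometry operates on 2-D maximum-intensity projections; puncta
  detection operates in 3-D. Territory volumes are `area × stack depth`
  (default 5 µm).

# The generator

`synth_config()` holds every generator knob. The defaults are the study
conditions used throughout the tests and analysis scripts.

* **Arbors** are stars of straight branches from the soma. Branch
  directions follow a von Mises distribution on the circle with mean
  `orientation_mu_deg` (default 0 = along the midline) and concentration
  `orientation_kappa` (default 8). `kappa = 0` is the isotropic, LS-like
  case; large kappa the midline-aligned, MS-like case. Branch lengths are
  Normal(`branch_length_mean_um` = 40, `branch_length_sd_um` = 8)
  truncated at > 1 µm; `n_branches` = 6. The recorded ground truth per
  cell includes the tip positions, the true longest branch (max
  tip-to-soma distance) and the true orientation (principal axis of the
  tip set against the midline, folded to [0, 90]°).
* **Rendering** (`render_cells()`) produces a DAPI channel of Gaussian
  nuclei (`nucleus_radius_um` = 3, Gaussian sigma = half the radius), a
  reporter channel of rasterized branches dilated to `branch_width_um`
  (1 µm) and blurred with a Gaussian PSF (`psf_sigma_um` = 0.5), and one
  nuclear channel per marker. All channels get `background_level` (10)
  plus Gaussian noise (`noise_sd` = 2) over peak `amplitude` (100); voxel
  size defaults to (1.0, 0.2, 0.2) µm over `n_z` = 5 planes.
* **Puncta** (`sample_puncta()`): presynaptic centroids are a homogeneous
  Poisson process (`lambda_pre_per_um3` = 0.02); a fraction
  `coloc_fraction` (0.3) receives a paired postsynaptic punctum displaced
  uniformly within a ball of `coloc_radius_um` (0.3); the remaining
  postsynaptic spots are an independent Poisson process. Rendered spots
  (`render_puncta()`) are 3-D Gaussians of `spot_sigma_um` = 0.15 —
  sub-resolution, as for synaptic markers.
* **Census** (`sample_census()`): per region, `n_cells_per_region` cells
  are placed uniformly, each independently double-positive with the
  region's `p_double_positive`; the default vector
  (MS 0.74, dLS 0.001, iLS 0.02, vLS 0.12) follows the strong
  medial-versus-dorsolateral contrast expected of a septal lineage mosaic.
* **Reproducibility**: `simulate_septum()` derives one deterministic
  substream per cell and per assay from the run seed with a counter-based
  mixing function, so adding a cell never perturbs the draws of the
  others, and every output is byte-identical given `(seed, config)`.

## What the generator does *not* emulate

Only a Gaussian PSF and additive Gaussian noise: no photobleaching, no
tissue autofluorescence, no depth-dependent aberrations, no secondary
branching of arbors (tips and mask extent drive all implemented metrics),
no anisotropic nuclei. Conclusions about detector robustness therefore
transfer to real data only qualitatively.

# Measurement pipeline and numerical choices

* **Nucleus detection**: multiscale scale-normalised Laplacian-of-Gaussian
  (LoG) on the max projection at sigma = `nucleus_radius_um / 2` ± 25%,
  response floor `median + 10·MAD` of the response image (nuclei pool many
  voxels, so their responses sit far above background), peaks closer than
  one radius merged keeping the stronger, centroid refined by
  intensity-weighted centre of mass, nuclear mask by Otsu within twice the
  radius.
* **Arbor segmentation**: Otsu threshold inside a `arbor_window_um` (60)
  window around the nucleus, or a fixed `arbor_threshold` (needed on
  noise-free two-valued images where Otsu is degenerate); connected
  component containing the nucleus; holes filled; border-touching flagged
  and excluded from morphometry by default.
* **Skeletonization**: Zhang–Suen thinning; the skeleton graph uses
  8-adjacency with *corner suppression* (a diagonal link only counts when
  neither shared cardinal neighbour is a skeleton pixel), which removes
  the staircase corner artifacts thinning leaves on diagonal branches;
  spurs shorter than `min_spur_um` (2) are pruned iteratively. Thinning
  erodes up to half the branch width at branch tips, so measured branch
  lengths are biased short by ≲ 0.5 µm at default settings — visible and
  accounted for in the recovery tolerances.
* **Shape metrics**: length = exact maximum Feret diameter (farthest pair
  of convex-hull vertices); width = hull extent perpendicular to the
  max-Feret axis; orientation = angle between that axis and the midline,
  folded to [0, 90]°, undefined below `orientation_min_elongation` (1.1).
  A 0.5°-grid rotation search is kept as a test oracle only. Angle bins
  default to [0, 30, 60, 90]° — three equal bins, so the isotropic case
  expects exactly 1/3 per bin.
* **Spot detection**: 3-D LoG at `spot_sigma_um` ± 50%, robust floor
  `median + 5·MAD`, sub-voxel refinement by per-axis quadratic fit,
  duplicates within `min_spot_separation_um` (0.3) merged keeping the
  stronger. With 1 µm z sampling of 0.15 µm spots, the renderer integrates
  the axial Gaussian over each optical section (otherwise spots falling
  between slice centres would vanish); detection relies on the same
  physics.
* **Colocalization**: greedy globally-nearest one-to-one matching with
  distance cap `coloc_max_dist_um` (0.5, about one optical PSF), ties
  broken lexicographically. One-to-one matching prevents one postsynaptic
  punctum from being counted against several presynaptic ones; tests bound
  the cost of greediness against an exhaustive optimal matcher and against
  the closed-form chance rate `1 − exp(−λ·(4/3)πr³)`.
* **Census calls**: positivity = mean nuclear intensity above background
  mean + `marker_threshold_k` (3) background s.d., background estimated
  outside all dilated nuclear masks — robust when a region is ~0% or
  ~100% positive, where bimodality-based thresholds fail.
* **Statistics**: ANOVA via the standard linear-model fit; Tukey–Kramer
  `q = |mi − mj| / sqrt(MSw/2 (1/ni + 1/nj))` with p values from the
  studentized-range distribution; quartiles by linear interpolation
  (type 7); s.e.m. uses the n−1 sample s.d. All conventions are fixed for
  reproducibility even where field practice varies.

# File formats

Images are plain multi-page TIFF (32-bit float, channel-major pages) with
a JSON sidecar `<path>.json` carrying voxel size, channel names and the
intensity scale, because baseline TIFF tags cannot store them; OME-TIFF
`PhysicalSize*` metadata is honoured on read as an alternative. Tables are
UTF-8 CSV; ground truth and run manifests are JSON. Configuration files
are YAML with two sections (`pipeline`, `synth`); unknown keys anywhere
are a hard error.

# Problem sizes

The analysis scripts and tests run at desk scale by design: fields of
320 × 320 pixels (64 × 64 µm) with 5 z-planes, 5 astrocytes per region,
puncta fields of ~400 spots per channel, censuses of 10²–10⁴ cells per
region, and statistical calibrations of 10⁴ null simulations. One full
simulation takes a few seconds; the complete test suite a few minutes on
one CPU. These sizes are the package's own choice — large enough for the
binomial/Poisson tolerances used in the recovery tests, small enough to
iterate quickly.

# Open questions and limitations

* Real pixel sizes, colocalization criteria and angle-bin boundaries of
  published septal analyses are rarely stated; the defaults here (0.2 µm
  lateral pixels, 0.5 µm pairing radius, 30° bins) are declared
  operationalizations, all configurable.
* Territory outlines are operationalized as convex hulls; manual outlining
  practices differ.
* The skeleton is 2-D (projection-based), matching common practice for
  5 µm stacks, and its Sholl profile is a stand-in for proprietary
  filament-tracing "branch complexity" outputs, not a claimed equivalence.
* The statistics module analyzes pooled cells; it does not model per-mouse
  nesting.
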