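---
title: "Methods: simulating and analysing a lipid-droplet repurposing screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a lipid-droplet repurposing screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldscreen)
library(dplyr)
```

## The assay this package models

Fibroblasts from patients with neutral-lipid storage disease accumulate
cytoplasmic lipid droplets (LDs) because the ABHD5 co-activator of the
triglyceride lipase ATGL is lost; healthy fibroblasts carry few LDs. A
high-content repurposing screen exploits that contrast: patient cells are
seeded in 384-well plates, treated with one library compound per well at a
single dose, stained with a neutral-lipid dye (LDs), a whole-cell stain and a
nuclear stain, and imaged at 12 fields per well. Patient cells plus vehicle
serve as negative controls (12 wells/plate); healthy control lines plus
vehicle serve as positive controls. Each well is reduced to four LD
parameters, compounds are scored by their distance from the sample median in
SD units per parameter, and a hit must clear the threshold in **all four
parameters individually**.

`ldscreen` implements the full computational chain — synthetic data
generation with exact ground truth, segmentation, morphometry, plate QC,
scoring, hit calling, and the two-group organelle statistics used around the
screen — so every stage can be validated without access to the original
images.

## The four well parameters

For each segmented LD with area $A$ (µm²) and perimeter $P$ (µm):

* **compactness** $= P^2 / (4\pi A)$ — 1 for a circle, larger for irregular
  boundaries;
* **form factor** $= 4\pi A / P^2$ — its exact reciprocal. The identity
  $\text{compactness} \times \text{form factor} = 1$ is enforced by
  construction (the form factor is stored as the reciprocal), so the
  directionality of either readout is always recoverable from the other.

A well is summarised by `ld_area` (mean per-object area), `ld_total_area`
(summed LD area divided by the well's cell count, µm²/cell),
`ld_compactness` and `ld_form_factor` (unweighted per-object means).
Normalising total area per cell keeps wells with different cell numbers
comparable — a raw sum would confound toxicity with lipolysis; the raw
per-well sum is available via `aggregate_well(per_cell = FALSE)`. Pooled
object means (rather than means of per-cell means) are used because they
remain defined when many cells carry zero LDs; the per-object mean is also
what `ld_area` denotes. Perimeters use the four-direction Crofton chord
estimator, the least-biased standard choice for small digitised objects
(a digitised disk of radius 30 px gives a form factor of 0.98).

## Scoring and hit calling

For parameter $k$ and compound $c$, the score is

$$z_{c,k} = \frac{x_{c,k} - \mathrm{median}_k}{\mathrm{sd}_k},$$

with the median and SD taken over the **reference set** — by default all
test-compound wells on the plate. With a mostly inert library the sample
median sits at the null centre and is robust to the few active wells; this
follows the screen's convention of measuring distance from "the median of
the samples". Referencing the negative controls instead
(`reference_source = "negative_controls"`) is the right choice for small
custom plates, where a handful of compound wells cannot define a stable
reference (with $n$ reference wells the largest attainable |z| is about
$\sqrt{n}$). The SD is the plain sample SD by default; `robust_sd = TRUE`
substitutes $1.4826 \times \mathrm{MAD}$, which resists inflation by the
active wells themselves. The screen community often labels this quantity
"SSMD"; the canonical strictly-standardised mean difference needs
per-compound replicate variance that a one-well-per-compound layout cannot
estimate, so that formula is provided separately as `ssmd_canonical()` for
replicated layouts.

Hit calling uses per-parameter thresholds of 2 SD for area, compactness and
total area and 4 SD for form factor. Total LD area must *decrease*
($z \le -2$): the screen looks for compounds that clear droplets. The other
three parameters are two-sided by default because a therapeutic effect may
move size and shape in either direction (the fewer-but-larger and
fewer-and-smaller archetypes both occurred among real hits); one-sided
policies are configurable and the sign of every total-area change is
recorded. A compound with any undefined score is excluded and flagged, never
silently passed. No multiple-testing correction is applied beyond the SD
thresholds — faithful to the screen's design, where the 4-SD form-factor bar
dominates the family-wise false-positive rate (about $6\times10^{-5}$ per
compound under the null).

Plate quality is summarised by the Z′ factor per positive-control line,
$Z' = 1 - 3(\sigma_{pos}+\sigma_{neg})/|\mu_{pos}-\mu_{neg}|$; the two
control lines are never pooled. Under the generator's default phenotypes the
simulated plates sit near $Z' \approx 0.85$ on total LD area — an excellent
assay window.

## What the generator emulates — and what it does not

The generator has two modes sharing one parameterisation.

**Feature mode** draws the four well parameters around closed-form
expectations. LD count per cell is Poisson($\lambda$), LD radius is
log-normal (median $m$ px, log-SD $\sigma$); then the expected per-object
area is $\pi (m s)^2 e^{2\sigma^2}$ µm² (pixel size $s$) and expected total
area per cell is $\lambda$ times that — linear in a count multiplier,
quadratic in a radius multiplier, which the tests exploit as oracles.
Phenotypes act multiplicatively on $\lambda$ and $m$: patient baseline
(1, 1), healthy controls (0.25, 0.9), and compound archetypes for clearance
(0.35, 0.7), fusion (0.3, 1.5) and accumulation (1.6, 1.15). Gaussian
well-to-well noise (default SD 1 unit per parameter) is added on top.

Planted screen effects use a different contract: a `shift_sd` profile sets a
well's parameters to *expectation + shift × noise SD* exactly, with no
additional noise draw. Planting "a 5-SD shift" therefore means the well
truly sits 5 SD from the null centre — the displacement is the ground truth
that recovery tests compare against. If shifts instead perturbed the
pre-noise mean, a 5-SD planted effect would clear the 4-SD form-factor bar
only ~84% of the time and "planted hits are always recovered" would be
unattainable by any implementation; the deterministic contract is what makes
exact-recovery guarantees well-defined. With zero noise, shifts are read as
absolute parameter units.

**Image mode** renders fields: non-overlapping elliptical cells (rejection
packing with whole-field restarts; loud `placement` error when the field
genuinely cannot hold the cells), interior nuclei, LDs as digitised disks
placed in the cytoplasm with a minimum separation when space allows, then a
Gaussian PSF (σ = 1 px) and additive Gaussian pixel noise. Compactness and
form-factor changes are *not* simulated directly in image mode — they emerge
from rendering and segmentation, which is exactly what makes the mode a
useful end-to-end test. Each stage (cell placement, LD counts, LD geometry,
noise) draws under its own sub-seed derived from the master seed, so the
per-cell Poisson counts can be replayed independently and identical
spec + seed reproduces a field pixel-for-pixel.

Default scene: 256×256 px at 0.65 µm/px, 20 cells/field, patient
$\lambda = 8$, $m = 2$ px, $\sigma = 0.25$ — chosen once as a plausible 20×
fibroblast field with the LD-laden disease phenotype. The paper reports no
per-well cell-count variability or field-to-field variance, so those are not
modelled: cell count per field is fixed and noise enters per pixel (image
mode) or per well (feature mode). Not modelled, deliberately: illumination
and vignetting artifacts, confluent or motile cultures, cell-cycle effects,
photorealistic textures, 3-D stacks. Passing tests therefore demonstrate
correctness of the *analysis chain* on data with known truth, not robustness
to every artifact of real microscopes.

## Segmentation choices

The original analysis names its software but not its algorithms; the
defaults here are the closest standard counterparts, all config-exposed:

* **Nuclei** — Gaussian smoothing (σ = 2 px), Otsu threshold, hole filling,
  removal of objects under 60 px², distance-transform watershed to split
  touching nuclei.
* **Cells** — Otsu foreground mask on the whole-cell stain, partitioned
  among nucleus seeds by Voronoi-based propagation (one cell per nucleus).
  Border-touching cells are removed by default to avoid truncated-cell bias.
* **Puncta** — white top-hat (disc radius 6 px) to suppress background,
  Otsu threshold estimated *within the union of the cell masks*, area filter
  (min 3 px²), 8-connected component labelling, optional distance-map
  watershed to split touching puncta (on by default), parent-cell assignment
  by centroid (majority-overlap assignment available). Puncta whose centroid
  lies in no cell are dropped and tallied as a QC count.

Fixed conventions: 8-connectivity for puncta, 4-connectivity for holes;
row-major pixel grid; areas reported in px² and µm². A blank channel yields
an empty label map with a warning rather than an error, so a dead well does
not abort a plate. LD statistics are computed per cell by default (the
pooled per-object table carries the parent of every punctum); whole-field
analysis is available by passing a single all-field "cell" mask.

Numerical notes: the in-package Otsu operates on an arbitrary pixel subset
(256-bin histogram, maximal between-class variance) and matches an
exhaustive between-class-variance search; thresholds may also be given as
numbers. Watershed splitting uses a basin tolerance of 1 px, which splits
blurred droplet pairs with distinct distance peaks but does not shatter
single puncta; truly coalesced droplets (centres closer than the PSF) are
unresolvable in principle and account for the residual ~3% undercount at
default settings.

## The two-group organelle comparison

`compare_groups()` reproduces the gated testing convention used for
organelle quantifications (e.g. peroxisome counts and sizes per cell):
Shapiro–Wilk normality per group at α = 0.05; if both groups pass, a
two-tailed Welch t-test, otherwise a two-tailed Mann–Whitney U. The
Mann–Whitney branch uses the normal approximation without continuity
correction so that identical samples give p = 1 exactly; all-tied data, for
which normality is undefined, fall back to Mann–Whitney with a flag. The
gate's empirical type-I error at n = 30 per group stays within
[0.04, 0.06] (measured over 10,000 null simulations by the acceptance
script), and log-normal data route to the rank test essentially always.
`simulate_organelle_groups()` generates per-cell Poisson counts and
log-normal mean sizes to study such contrasts; the planted
"1.3× count, 0.8× size" disease contrast at 150 cells/group is detected with
power ≈ 1.

## Problem sizes used in validation

The test-suite and acceptance-script runs use: 384-well feature-mode plates
(360 compounds, 12 negative controls, 6 positive wells per line) over 10
(planted) and 20 (null) seeds; 100 random plates for the scoring oracle;
10,000 null simulations for the type-I error; 400 for gate routing; 200 for
organelle power; and, in image mode, single fields at the default scene plus
an 8-well × 4-field mini-plate at 256×256 px. These sizes give Monte-Carlo
standard errors comfortably below the tolerances they are checked against.

## Known limitations

* Image mode is tuned for sub-confluent fields of well-separated cells;
  dense monolayers need a different cell-segmentation strategy.
* The per-punctum area of the very smallest droplets (r ≲ 1.5 px) is
  quantisation-limited: one boundary pixel is >10% of the object, so
  individual small puncta can exceed 20% area error even though the typical
  (median) error is ~8%.
* Feature mode draws the four parameters independently; real wells show
  correlated parameter noise. Scores are location/scale invariant, so this
  affects only the joint null distribution of the four pass flags (the
  independent case is the conservative one for the intersection rule).
* Single-dose screening only: no dose–response modelling, compound
  annotation or toxicity counter-screens.
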