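---
title: "Methods: whole-slide mIHC analysis of the aortic wall"
author: "wallplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-slide mIHC analysis of the aortic wall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallplex)
```

## The analysis problem

Multiplex immunohistochemistry (mIHC) of full-thickness aortic wall
sections yields, after cell segmentation, a table of single cells with
positions and per-marker intensities for every slide of a cohort. The
questions asked of such data are compositional and spatial: which immune
populations live in which wall layer (intima, media, adventitia), how
their abundance differs between patient groups (here: non-dilated,
dilated and dissected ascending aortas of patients with a bicuspid
aortic valve), whether organized tertiary lymphoid structures (TLS) are
present in the adventitia, and how far particular phenotypes sit from
vascular targets such as the vasa vasorum.

`wallplex` implements that analysis chain — gating, layer-stratified
quantification, TLS detection, nearest-neighbor statistics, cohort
statistics — together with a synthetic whole-slide generator that
replaces the imaging front end. The generator produces tables with known
ground truth (true phenotype, true layer, planted TLS), so every stage
of the pipeline can be validated quantitatively at desk scale.

## Phenotype gating

Each of the two 8-color panels carries an ordered list of boolean rules
(`panel_adaptive()`, `panel_innate()`); the most specific matching rule
wins, e.g. CD3+CD8−FoxP3+ is a regulatory T cell, not a helper T cell.
Cells positive for mutually exclusive lineage markers (CD3 & CD20,
CD68 & CD15) are segmentation doublets, labeled *ambiguous*, counted in
totals but in no phenotype — a conservative choice for composition
estimates. Cells matching no rule are *other*.

Bimodal lineage markers are thresholded with a fixed configured gate
(default 15 intensity units, between the two log-normal modes of the
default intensity model). CD45RO and MMP9 are expressed gradually, with
no separated positive mode; they are thresholded adaptively per slide:
the cells negative for every lineage marker form a negative-control
population, and the threshold is that population's 0.995 nearest-rank
quantile. The quantile default bounds the false-positive rate at 0.5%
by construction; intensity equal to a threshold is negative
(deterministic tie-break). If fewer than 50 negative-control cells are
available the gate errors and instructs a fixed fallback threshold.

Masked markers (FoxP3 in the post-mortem non-dilated group, where its
expression is not representative) disable every rule that needs them,
and the affected phenotypes are reported missing, never zero.

## Layer quantification

Geometry v1 is a rectangular strip with horizontal layer bands — intima
at the bottom, media, adventitia on top — in µm with a continuous
coordinate system; curvature would not change any of the statistics
computed here. Excluded polygons (blood, background) are removed from
both the cell sets and the analyzed areas (polygon clipping against the
bands), so densities stay unbiased. A cell exactly on a band boundary
belongs to the inner (more luminal) layer.

Per slide and layer the package reports counts, fractions of all cells
and densities for every leaf phenotype, plus derived populations
computed from marker positivity (all CD3+CD8− helper T cells,
lymphocytes = CD3+ or CD20+, all CD68+ macrophages, any immune
lineage). Group contrasts are ratios of group *medians* of per-slide
fractions-of-all-cells — median-based, because these variables are
non-Gaussian, and fraction-based to match percent-of-all-cells
reporting; densities are also emitted. Whether a fold change should be
a ratio of medians or a median of ratios was genuinely open; the ratio
of group medians is used and documented here. The adventitia of
dissected aortas is too disrupted for quantitative composition
analysis; those slides carry `adventitia_quantifiable = FALSE` and are
excluded from adventitial group summaries (TLS detection still runs on
them, but they are not counted in TLS group statistics).

## TLS detection

Lymphoid infiltrates are defined spatially: T and B lymphocytes of the
adventitia form a contact graph with an edge whenever two cell centers
are at most 12 µm apart (about one lymphocyte diameter — "physically
touching"), and an infiltrate is a connected component with at least 20
members containing both lineages. An infiltrate is classified as a TLS
if it has segregated B/T zones or a germinal center:

* **Zones** — for each lineage, the mean over its members of the
  fraction of their 5 nearest within-component neighbors sharing the
  lineage; zones are present when both scores reach 0.7.
* **Germinal center** — some 15 µm disk centered on a member whose
  cell density is at least 2× the component's median local density
  (same disk radius) with at most 20% T cells.

The probe radius matters: a germinal center is a compact proliferating
B-cell focus, and a probe much larger than the focus averages it away
against the surrounding B mantle — with a 30 µm probe no compact
two-zone structure that passes the zone criterion can reach a 2× density
fold. The 15 µm default was chosen by simulating planted structures
during design; with it, planted TLS classify as zones-positive 98% and
germinal-center-positive 97% of the time. Venules, an alternative
criterion for TLS in histopathology, are not modeled: the adaptive
panel carries no endothelial marker.

The distance of a TLS to the media is the Euclidean distance from the
component centroid to the media/adventitia boundary. Group statistics
report prevalence (fraction of slides with ≥1 TLS), the mean count per
TLS-positive slide (the mean over all slides is also emitted, since
"TLS per slide" is ambiguous), and the mean distance.

## Nearest-neighbor analysis

`median_min_distance()` computes, per slide, the median over source
cells (default M1-like macrophages, CD68+CD206−) of the distance to the
nearest target cell (default endothelium, CD31+CD68−) in the media and
adventitia. All tiles of a slide are merged before the computation so
neighbors are found across tile borders, and excluded-region cells are
dropped for consistency with the composition analysis. Slides with
fewer than 150 cells of either phenotype are excluded (flagged with
counts, not silently dropped) because of the high sampling error; the
150-cell rule is read as applying to either phenotype. The direction is
source→target only; the reverse is available by swapping the rules.
Distances come from a grid-bucket index with expanding-ring search and
are exact (verified against the O(n²) brute force). Group comparison is
a Kruskal–Wallis test on the per-slide medians.

## Statistical battery

Median (IQR) summaries use linear-interpolation quartiles (type 7).
Two-group comparisons use the two-sided Kolmogorov–Smirnov test (exact
p for small tie-free samples via `stats::ks.test`, asymptotic
otherwise); three-group comparisons use the tie-corrected
Kruskal–Wallis test with all pairwise tests Bonferroni-adjusted by the
number of pairs and capped at 1. Binary contrasts use the two-sided
Fisher exact test. Correlations use tie-corrected Kendall τ-b,
appropriate for the small group sizes, with a seeded percentile
bootstrap CI (2,000 resamples by default — the CI method had to be
chosen here, and the bootstrap makes no distributional assumption) and
the standard τ null p-value. Inter-observer agreement uses the
two-way random-effects absolute-agreement single-measures ICC(2,1),
computed from ANOVA mean squares; the consistency form ICC(3,1) is
available via a flag since the original software's choice is not
knowable. Identical ratings give ICC 1 by convention. Significance is
α = 0.05 throughout.

## The synthetic cohort and its calibration

The default configuration (`default_cohort_config()`) emulates a cohort
of 8 non-dilated, 15 dilated and 4 dissection slides. Each slide is a
4 × 2.15 mm strip (150 µm intima, 1.2 mm media, 0.8 mm adventitia) with
one excluded luminal blood region, carrying ≈2×10⁴ cells — a deliberate
desk-scale stand-in for multi-centimeter sections with up to 400
20×-views, small enough that a 27-slide cohort runs in seconds while
every spatial statistic still operates far from small-sample artifacts.

Cells are placed as homogeneous Poisson processes per layer and
phenotype; endothelium is instead placed as small vasa-vasorum-like
clusters (8 cells within 20 µm) so the nearest-neighbor analysis has
realistic targets. Intensities are log-normal per marker and
population; the gradual markers get overlapping positive/negative
populations, reproducing the behavior the adaptive threshold exists
for. MMP9 positivity is an independent 5% Bernoulli on top of lineage,
equal across groups. Blood regions contain nuisance cells that must be
excluded by geometry, not by gating.

Planted TLS are three concentric shells: a dense germinal-center focus
(12 µm, 20 B cells), a B mantle (to 30 µm, 45 B total) and a T ring
(to 58 µm, 60 T cells, 72% helper). Member spacing is far below the
contact radius, so each structure forms one component. TLS centroids
sit at a truncated-normal offset (mean 242 µm, sd 40 µm) from the
media/adventitia boundary. Prevalence is realized as an exact fraction
of each group's slides (`round(prevalence × n_slides)` randomly chosen
slides), because the emulated quantity is a realized cohort property,
not a superpopulation rate; positive slides carry 1 + Poisson(1.6)
structures (mean 2.6).

Default densities are calibrated once, by construction, so the full
pipeline recovers the cohort statistics the package targets: 4× more
adventitial lymphocytes and 25× more B cells in dilated than
non-dilated aortas, helper T cells at 12.42% of adventitial cells,
CD4/CD8 ratios of 2.52 (dilated) and 1.82 (non-dilated), 1.6× more
CD68+ macrophages, TLS in 50% of dilated slides with 2.6 per positive
slide at 242 µm from the media, and a quiet intima (8.1% immune cells,
4.6% M1-like macrophages, identical across groups). Because planted TLS
members add to both the numerator and the denominator of adventitial
fractions on TLS-positive slides, and because the group median is an
order statistic that typically lands on the smallest TLS-positive
slide, the background densities were solved with a count-level Monte
Carlo of the generative model (bisection on the background density so
the across-seed median of group medians equals the target). The solver
uses only the count model — never the pipeline's output — and the
resulting defaults are frozen in `default_cohort_config()`.

Determinism: per-slide child seeds are derived from the master seed, so
an identical configuration reproduces a bit-identical cohort; every
stochastic routine with its own randomness (bootstrap CIs) takes an
explicit seed.

## What passing tests do and do not show

The generator emulates post-segmentation tables, not images. Real data
bring segmentation errors beyond simple doublets, spatially varying
staining intensity and autofluorescence, curved and locally thinned
layers, tissue folds, and TLS of irregular shape — none of which are
modeled (the intensity floor of the negative populations is the only
autofluorescence-like nuisance). Recovery of the calibrated statistics
therefore validates the *analysis chain* — gating logic, geometry
handling, graph detection, estimators — under known ground truth; it
does not certify performance on inForm exports, where thresholds and
the contact radius may need adjustment. Per-tile statistics are out of
scope (slides are analyzed whole), as are spectral unmixing,
pixel-level segmentation and permutation-based spatial interaction
nulls.

## Numerical choices and degenerate inputs

* Strict `>` at every gate; equality is negative.
* Boundary cells belong to the inner layer; points on an excluded
  polygon's edge count as excluded.
* Components smaller than k+1 compute zone scores with the neighbors
  they have; a 1 T + 1 B pair is never a TLS.
* An empty target set in the nearest-neighbor analysis excludes the
  slide; it never crashes.
* A zero denominator median in a fold change reports `Inf` with a
  warning; a zero cytotoxic count makes the CD4/CD8 ratio missing with
  a warning; constant vectors make τ missing.
* All reported problem sizes (20 master seeds, 27 slides, ≈2×10⁴
  cells/slide; 500 null simulations at n = 8/15/4; 50 brute-force
  oracle instances up to 1,000 cells) are the package's validation
  conditions and are restated in the test suite.
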