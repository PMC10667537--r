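---
title: "Scoring and prognostic analysis of tumour-infiltrating lymphocytes from nuclei maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and prognostic analysis of tumour-infiltrating lymphocytes from nuclei maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilscape)
```

## The problem

Tumour-infiltrating lymphocytes (TILs) carry prognostic information in
breast cancer, but the recommended visual score — a pathologist's
estimate of the percentage of tumour-associated stroma occupied by
lymphocytes — is a single coarse number with modest inter-observer
agreement, and it ignores the intratumoural compartment and all spatial
structure. When a nuclei-detection model and a region-segmentation model
have already been run over a whole-slide image, their outputs (a table
of nucleus centroids with types, and tumour/stroma region masks on the
same downsampled grid) contain far richer information. `tilscape` turns
those two inputs into quantitative TILs features and carries them
through the full outcome-analysis protocol used in luminal
breast-cancer cohort studies.

The package deliberately starts *after* the deep-learning steps: it
never touches raw slide images beyond simple tissue-mask thresholding,
and segmentation models are out of scope. Everything downstream of the
nuclei map — region algebra, feature definitions, cohort statistics —
is implemented and testable here.

## Coordinate and mask conventions

All spatial computation happens at one shared resolution: the grid on
which nucleus centroids were mapped (typically a five-times downsampled
slide). Coordinates are 0-based with `x` the column and `y` the row,
`y` increasing downward. A nucleus at `(x, y)` lies inside a mask iff
the mask is set at the pixel containing its rounded centroid; halves
round up, a pinned tie-break so that boundary nuclei are assigned
deterministically. No micron conversion is attempted anywhere — the
`scale_note` field of a mask set carries provenance only.

On load, mask sets are repaired to satisfy two invariants: tumour and
stroma are forced inside tissue, and tumour-stroma overlap is removed
from stroma (with a warning stating the pixel count). Repair is
idempotent.

## Tumour-associated stroma (TAS)

Not all stroma is relevant: the visual protocol scores the stroma *of
the tumour*, not distant or uninvolved stroma. `capture_tas()`
reproduces that with a morphological recipe: dilate the (artefact- and
DCIS-free) tumour mask with a Euclidean disc of radius 8 px, fill holes
with a disc of radius 32 px, and call any stroma inside the resulting
envelope TAS.

Two readings of "fill holes with a disc" are defensible, and both are
implemented:

* `close_then_fill` (default): morphological closing with the
  32 px disc followed by binary hole filling. This bridges stromal
  channels narrower than roughly twice the fill radius *and* captures
  fully enclosed stroma.
* `fill_only`: fill only fully enclosed holes whose inscribed-disc
  radius is at most the fill radius.

The default was chosen because the recipe's purpose is to capture the
tumour-associated stroma, and narrow fjords between adjacent tumour
nests are exactly that. The choice is a config key
(`tas_fill_mode`), never hard-coded.

Three numerical contracts are pinned so that the operation is exactly
testable:

* discs are *closed* Euclidean balls on pixel centres (a pixel is in
  the disc iff its centre distance is `<= r`);
* masks are padded with background by the total structuring radius
  before morphology and cropped after, so image edges never generate
  artificial TAS;
* holes are 4-connected background components not touching the border.

Distance computations use the exact Euclidean distance transform of
`EBImage::distmap()`; connected components and hole filling use a
run-based union-find written here because the pinned 4-connectivity
semantics must not depend on another package's undocumented convention.
The test suite holds the whole recipe to *exact* equality with a
brute-force oracle (union-of-discs stamping, duality erosion, frontier
flood fill) on random masks, and checks monotonicity of TAS in the
dilation radius. Whether the published radii refer to the downsampled
or the full-resolution grid is not stated anywhere we could find; we
take them on the nuclei-map grid, where they are of the same order as
typical nest spacing.

## Per-slide features

With regions fixed, every nucleus gets exactly one label:
`tumour_region`, `tas`, `other` (tissue outside both), or `excluded`
(DCIS/artefact pixels, unlabelled pixels, out-of-grid coordinates).
Excluded nuclei take part in nothing downstream.

* **sTILs count** — immune nuclei in TAS.
* **tTILs count** — immune nuclei in the tumour region. "In direct
  contact with tumour cells" is not decidable from centroids alone, so
  membership of the effective tumour mask is the operational
  definition.
* **total TILs** — immune nuclei anywhere non-excluded; the three
  region tallies add up exactly (conservation is a tested invariant).
* **AI-based sTILs percentage** — `100 * (immune nucleus area in TAS) /
  (TAS area)`, clamped to `[0, 100]`. Nuclei without polygon areas
  contribute `default_nucleus_area` px each (default 28 px, a typical
  lymphocyte footprint at this grid scale; the value is configurable
  and echoed in outputs because percentage-based conclusions should
  not silently depend on it). An empty TAS yields `NA` — undefined is
  not zero.
* **Co-occurrence matrix (CM)** — over the ordered types (tumour,
  stromal, immune): for each unordered pair of nuclei within
  `cooc_radius_px` (default 32 px) of each other, cross-type pairs
  increment both symmetric cells and same-type pairs the diagonal once.
  The implementation uses a uniform-grid spatial index whose contract
  is exact equality with the all-pairs computation — tested on random
  slides up to 2000 nuclei.
* **CM scalars** — `stroma_immune_cooc = cm[stromal, immune]`,
  `tumour_immune_cooc = cm[tumour, immune]`; *heterogeneity* is the
  Shannon entropy (bits) of the CM normalised over its upper triangle,
  and *contrast* is the immune-involving off-diagonal mass fraction.

The co-occurrence radius, and the heterogeneity and contrast formulas,
are declared interpretations: the source protocol names these features
but does not define the distance or the formulas. Both definitions are
dimensionless, simple, and pinned by oracle tests; treat cross-study
comparisons of their absolute values with care.

## Cohort statistics

Association testing mirrors the tables such studies print: for each
feature and each clinicopathological grouping, per-group `n` and mean
rank (mid-ranks over the pooled sample) with a Mann-Whitney (2 groups)
or Kruskal-Wallis (3+) p-value. Rank-sum conservation
(`sum(n_g * mean_rank_g) = N(N+1)/2`) holds exactly for every result.
P-values are two-sided; following the protocol we emulate, no
multiple-testing correction is applied across the battery, and reports
say so. The Mann-Whitney p uses the tie-corrected normal approximation
with continuity correction (the behaviour of the standard packages
these studies rely on); for pooled samples of 10 or fewer the exact
mid-rank permutation distribution is enumerated instead. The continuity
correction is a documented switch, since sources rarely state it.

Agreement between the visual and automated sTILs percentage is an
intraclass correlation. No model is ever named in such papers; we use
the two-way, absolute-agreement, single-measures form — the standard
choice for method agreement — computed from the mean-squares
decomposition, and the result always carries its model tag.

## Survival protocol

The cohort is split once into discovery and test sets by stratified
random sampling on the event indicator. Each feature is dichotomised
by an outcome-based cut-point *derived on the discovery set only*: the
log-rank chi-square of high-vs-low (`high` strictly above the cut) is
maximised over a percentile grid (5th-95th, step 1) subject to a
minimum group fraction (default 0.1) on both sides, with ties broken
toward the median. This emulates the X-tile procedure, which is a
closed GUI tool; the grid policy is explicit and logged rather than
guessed. Because the statistic is maximally selected, its p-value is
optimistic: it is reported as `p_uncorrected` with an attached caveat,
and no Miller-Siegmund-type correction is applied — the held-out test
set is the protocol's guard. The audit trail in the pipeline manifest
records exactly which rows the cut saw.

Kaplan-Meier curves, log-rank tests and Cox models come from the
`survival` package behind tidy wrappers; Efron tie handling is the
default, with Breslow available (under which the Cox score test at
zero equals the log-rank chi-square — a cross-module identity the
suite checks to 1e-8). Count effects are also reported per 1000 units
(`exp(1000 * beta)`, CI endpoints transformed identically), the
convention used for tTILs counts. Subjects with zero follow-up time
are rejected at load rather than shifted: ambiguous data should fail
loudly.

## What the synthetic data emulates — and what it does not

The cohorts these methods were developed on are not public, so the
package ships generators whose *defaults are the study conditions*
rather than free dials.

`generate_slide()` plants tumour nests as random discs in a tissue
field, homogeneous Poisson tumour/stromal nuclei inside their regions,
and immune nuclei split 80/20 between stroma and tumour (stromal TILs
dominate intratumoural TILs, as consistently reported), with stromal
immune placement decaying exponentially with distance to the tumour
border (`border_attraction`). Every planted nucleus is labelled against
the same analysis regions the pipeline will compute, so the generator
carries exact ground-truth counts; `compute_slide_features()` must
reproduce them exactly, including after a round trip through CSV and
PNG files.

`generate_cohort()` uses a shared per-patient log-normal latent
intensity: sTILs and tTILs counts are conditionally Poisson given their
latents, which share a common component (SD 0.8) plus idiosyncratic
noise (SD 0.45). On the count scale this yields a population Pearson
correlation of about 0.68, with n = 1000 samples ranging roughly
0.58-0.79 — emulating the reported 0.6 (discovery/test) to 0.8
(external validation) band. Mean counts default to 800 sTILs vs 150
tTILs. Survival is exponential with hazard
`8e-4/month * exp(log(1.7) * z)`, where `z` is the standardized
log(1 + total TILs) — proportional hazards holds by construction, the
per-SD hazard ratio is the 1.7 magnitude reported for tTILs, and the
8e-4 baseline with a 240-month administrative censoring horizon gives
the ~15-20% breast-cancer-specific event fraction typical of luminal
cohorts. Ordinal covariates (grade, size, nodal status, Ki67, LVI) are
thresholded latents correlated 0.5 with the immune latent, so
high-TILs patients skew toward high grade, large size and young age —
directions, not magnitudes, are the calibration targets, because
published mean ranks are cohort-specific. The visual score is the AI
percentage plus Gaussian noise sized (on one rater, hence the factor
of 2 in the variance) for an agreement ICC of about 0.7.

What passing tests on this generator do **not** show: anything about
segmentation accuracy on real slides; realistic spatial textures
(nuclei are Poisson within regions, not clustered glands); non-PH
survival structure or competing risks; informative censoring; real
inter-observer behaviour beyond additive noise. The generator exists
to verify the *pipeline's* algebra and the statistical machinery's
calibration, not to impersonate a cohort.

## Problem sizes and numerical choices

The test suite runs the geometry oracles on 128x128 masks (50 random
masks for the TAS oracle, with dilation radii 4-8 and fill radii 8-32),
the co-occurrence oracle on 100 slides of 50-2000 nuclei, planted-count
recovery on 100 random slide configurations, type-I calibration on
1000 null replicates (n = 50 per group), Cox coverage on 200 cohorts of
n = 1000, and cut-point recovery on 100 seeds — sizes at which every
check is sharp while the whole suite stays fast on one CPU. The
acceptance script scales a few of the replicate counts down (100
coverage fits, 50 cut-point seeds, 500 calibration replicates) and uses
a 2231-patient cohort split 70/30, matching the discovery/test sizes of
the motivating study design.

Degenerate inputs are contracts, not accidents: constant-intensity
images yield an empty tissue mask with a warning; an empty TAS makes
the sTILs percentage `NA`, never 0; a percentage above 100 (possible
only in pathological synthetic input) clamps with a warning; a cohort
with zero events skips the survival stages with explicit records while
associations still run; unknown nucleus type labels map to `other`
with a warning rather than failing a whole slide.

## Limitations

Immune nuclei are one class: no CD8/CD4/FOXP3 subtyping is possible
from H&E-scale nuclei maps. tTILs-by-centroid-membership is a proxy for
"in contact with tumour cells". The co-occurrence distance and the
heterogeneity/contrast formulas are this package's pinned
interpretations of named-but-undefined features. The discovery-set
cut-point p-values are maximally selected and must only ever be read
next to their test-set validation.
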