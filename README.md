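# tilscape

Quantification and prognostic analysis of tumour-infiltrating
lymphocytes (TILs) in breast cancer, starting from the outputs of
nuclei-detection and region-segmentation models: a per-slide table of
nucleus centroids with types, and co-registered tumour/stroma region
masks on the same downsampled grid.

TILs studies in luminal breast cancer need more than the pathologist's
single visual estimate of stromal TILs. Given a nuclei map, `tilscape`
computes:

* **Tumour-associated stroma (TAS)** by the morphological recipe
  `envelope = fill_holes(close(dilate(tumour, disc(8)), disc(32)))`,
  `TAS = envelope ∩ stroma` — exact closed-Euclidean-disc semantics,
  verified against a brute-force per-pixel oracle;
* **sTILs / tTILs / total TILs counts** — immune nuclei in TAS, in the
  tumour region, and anywhere non-excluded (DCIS and artefact regions
  are removed first);
* the **AI-based sTILs percentage**
  `100 · area(immune ∩ TAS) / area(TAS)`, the automated counterpart of
  the visual score;
* a **cell-type co-occurrence matrix** over (tumour, stromal, immune)
  nuclei — unordered pairs within a fixed centroid distance (default
  32 px), counted by a spatial index that is exactly equal to the
  all-pairs computation — plus derived scalars (stroma–immune and
  tumour–immune co-occurrence, Shannon heterogeneity, immune contrast);

and runs the full cohort protocol: stratified discovery/test split,
rank-based association tests with mean-rank reporting, visual-vs-AI
agreement (ICC, two-way absolute-agreement single-measures),
X-tile-style outcome-based cut-points (maximally selected log-rank over
a percentile grid, derived on discovery only), Kaplan–Meier/log-rank,
and Cox models with hazard ratios reported both per dichotomised group
and per 1000 count units (`exp(1000·β)`).

Because the motivating cohorts are proprietary, the package includes a
first-class synthetic module: virtual slides with exact planted ground
truth, and virtual cohorts with the reported statistical structure
(sTILs–tTILs correlation ≈ 0.6–0.8, TILs-linked exponential
proportional-hazards survival with HR 1.7 per SD of log TILs burden,
covariates correlated with TILs, visual scores agreeing at ICC ≈ 0.7).

## Worked example

```r
library(tilscape)

# a synthetic slide with known ground truth
slide <- generate_slide(slide_sim_config(seed = 7))
features <- compute_slide_features(slide$nuclei, slide$masks)
features
#> <slide_features>
#>   sTILs 38 | tTILs 21 | total 100 | sTILs% 14.40
#>   co-occurrence: stroma-immune 863, tumour-immune 514
#>   heterogeneity 2.3580 bits | contrast 0.4074
```

38 immune nuclei sit in tumour-associated stroma (sTILs) and 21 inside
tumour nests (tTILs); immune nuclei occupy 14.4% of the TAS area; the
co-occurrence cells count nucleus pairs within 32 px of each other.
These counts equal the generator's planted truth exactly.

```r
# a synthetic cohort through the full protocol
cohort <- generate_cohort(cohort_sim_config(n_patients = 2231, seed = 7))
res <- run_tils_pipeline(cohort, "results/", seed = 7, test_fraction = 0.3)

dplyr::filter(res$survival_results,
              feature == "ttils_count", model == "cox_uni_high_vs_low")
#>   feature     set       model                  hr ci_low ci_high  p_value    n n_events
#> 1 ttils_count discovery cox_uni_high_vs_low  2.12   1.64    2.74  1.14e-8 1562      296
#> 2 ttils_count test      cox_uni_high_vs_low  2.10   1.40    3.13  2.96e-4  669      127

res$correlations[1, ]
#>   x           y                r   p_value method     n
#> 1 stils_count ttils_count  0.669 1.25e-289 pearson 2231

res$icc
#>     icc model                   n_subjects n_raters
#> 1 0.758 two_way_absolute_single       2231        2
```

High tTILs (above the cut-point derived on the discovery set and
applied unchanged to the test set) roughly doubles the
breast-cancer-death hazard in both sets; sTILs and tTILs counts
correlate at r ≈ 0.67; the simulated visual scorer agrees with the
automated percentage at ICC ≈ 0.76. `results/` receives
`manifest.json` (with an audit of the discovery rows used for
cut-points), `cutpoints.csv`, `survival_results.csv`,
`associations.csv`, `correlations.csv`, `icc.csv` and per-feature
Kaplan–Meier tables; a rerun with the same seed is byte-identical.

A thin command-line front end is installed at
`inst/scripts/tilscape.R` (verbs `simulate`, `features`, `analyze`,
`run`, each taking `--config cfg.yaml --seed N --out dir`).

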