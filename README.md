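# richnet

Graph-theoretical group comparison of weighted structural brain
networks, for researchers analyzing diffusion-MRI connectomes: given
per-subject symmetric FA-weighted connectivity matrices (e.g. 90 AAL
regions), a node table, and a subject table (group, age, sex, optional
behavioral score), `richnet` computes

- **small-world metrics** over a proportional-density sweep: weighted
  clustering Cp (Onnela), characteristic path length Lp (distances
  1/w), and their null-normalized forms γ = Cp/Cp_rand, λ = Lp/Lp_rand,
  σ = γ/λ, summarized by the trapezoidal AUC over the density grid;
- **rich-club organization**: Φ(k) = 2E_{>k}/(N_{>k}(N_{>k}−1)),
  normalized as Φ_norm = Φ/Φ_rand against Maslov–Sneppen
  degree-preserving rewired ensembles; rich-club regions as the top 15%
  of nodes by pooled average degree; edge classes (rich-club / feeder /
  local) and per-class connectivity strengths;
- **group statistics** adjusted for age and sex (residualization +
  equal-variance t-test), edge-wise tests at p < 0.001, Pearson
  chi-square demographics, and Pearson behavior correlations in
  patients;
- **MVPA**: per edge class, F-score feature ranking and a linear SVM
  under leave-one-out cross-validation (ranking, scaling and cost
  search strictly inside each training fold), accuracy / sensitivity /
  specificity / ROC-AUC, a full-pipeline permutation test, consensus
  features (selected in every fold) and weighted regions (≥ mean + 1 SD
  of aggregated |SVM weight|);
- a **synthetic cohort generator** with planted ground truth (rich-club
  core, feeder/local group effects, behavior-coupled edges, age/sex
  covariates) so the whole pipeline is testable without any data
  download.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
simulated cohort. Step 1 simulates 28 patients + 28 controls with 90
regions and writes `results/cohort/`:

```
$ Rscript analysis/01_simulate.R
Cohort written to results/cohort:
cohort: 56 subjects ( 28 patients / 28 controls ), 90 nodes
planted rich core: 5 11 18 36 41 55 65 70 72 76 80 84 89
planted effect edges: 21 ( 10 feeder / 11 local )
patient CLCDS-like scores: mean 91.1 sd 3.2 (floor 86)
sex distribution chi-square: 0.000 (p = 1.000)
```

The chi-square of 0 (p = 1) reflects the identical 21/7 male/female
split in both groups. Step 4 tests every common connection at 16%
density, adjusted for age and sex:

```
$ Rscript analysis/04_group_differences.R
testable edges: 218  significant at p < 0.001: 20
        direction
class    -1  1
  feeder  0 10
  local   1  9

recovery vs planted truth: rich-set Jaccard 1.00, edge sensitivity 0.95, FDR 0.00
lower-in-patients connections: (15,71)
```

All 13 planted core regions are recovered (Jaccard 1.00); 19 of the 21
planted effect edges reach p < 0.001 with no false positives, and the
single planted lower-in-patients connection is detected with negative
direction. Steps 2–3 produce the small-world AUC comparison and the
per-degree Φ_norm profiles, step 5 the per-class SVM results with
consensus features, and step 6 the behavior correlations of the
consensus features.

Equivalent programmatic use:

```r
library(richnet)
res    <- generate_cohort(synthetic_config(seed = 1))   # or read_cohort(dir)
report <- run_full_analysis(res$cohort, analysis_config(seed = 1))
report_summary(report)
```

Desk-scale defaults (ensembles of 100, B = 100 permutations) keep a run
in minutes; `analysis_config(full_scale = TRUE)` restores
literature-scale 5,000/1,000/1,000 ensembles.

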