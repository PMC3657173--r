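# col6screen

Quantitative flow-cytometry screening for collagen VI deficiency in primary
skin fibroblasts.

Collagen VI myopathies — Ullrich congenital muscular dystrophy (UCMD) at the
severe end, Bethlem myopathy (BM) at the mild end — are caused by mutations in
*COL6A1/2/3*. Before committing to sequencing 107 coding exons, clinical labs
want quantitative evidence of abnormal collagen VI protein expression.
Immunolabelling a patient's cultured fibroblasts with an anti-collagen VI
antibody and counting antigen-positive cells by flow cytometry provides that
evidence: UCMD fibroblasts retain mutant collagen VI intracellularly and show a
marked loss of surface staining, BM fibroblasts a milder, variable reduction.

`col6screen` implements the complete analysis pipeline for this assay, plus an
event-level simulator so every stage is testable without instrument data:

- **Gating** (`derive_positive_gate`, `apply_gate`, `gate_batch`): the
  positivity threshold is the empirical quantile *q* (default 0.99, type-1 /
  inverted-CDF) of the fluorescence of a no-primary-antibody **negative
  control**; the same gate is applied to every sample of the batch, and a
  sample's readout is its percent of events strictly above the threshold.
- **Screening statistics** (`retention`, `group_summary`, `group_comparison`,
  `deficiency_ratio`, `classify_sample`): per subject, the intracellular
  **retention** statistic is `pct_perm − pct_nonperm` (permeabilised staining
  reaches intracellular antigen, so the difference estimates retained
  collagen VI). Groups are compared by ordinary least squares on group
  indicators with controls as reference (equivalently one-way ANOVA with
  treatment contrasts), so each coefficient is that group's mean difference
  from controls in percentage points with a two-sided *t* test. Surface
  values below 37% classify as `UCMD_range`, above 44% as
  `BM_or_control_range`, with an explicit `indeterminate` gap between.
- **Synthetic cytometry** (`fluorescence_model`, `generate_sample`,
  `generate_cohort`): each event is antigen-positive with the sample's true
  fraction; fluorescence is log-normal per population (negative at
  10^1, positive at 10^3, SD 0.35 decades), side scatter normal. Per-subject
  true fractions follow mean-calibrated truncated normals parameterised by the
  published group statistics (controls 65.4 ± 10.7% surface-positive, BM
  54.1 ± 8.0%, UCMD 19.6 ± 10.0%, permeabilised > 90% in all groups).
- **FCS / CSV I/O** (`write_fcs`, `read_fcs`, `read_manifest`, …): a minimal
  FCS 3.1 list-mode writer (float32) and reader (float + integer dialects),
  a CSV fallback, and batch manifests.
- **Pipeline** (`run_screen`, `simulate_screen`, `screen_batch`,
  `write_report`) and a CLI (`inst/exec/col6screen`) tying it together.

## Worked example

```r
library(col6screen)

report <- simulate_screen(cohort_config(base_seed = 42))
subset(report$group_summaries, measure != "pct_perm")
#>      measure condition n mean_pct sd_pct min_pct max_pct
#>  pct_nonperm   control 5    70.79  5.736   61.59   75.24
#>  pct_nonperm        BM 5    55.57  5.005   50.34   63.29
#>  pct_nonperm      UCMD 8    23.76  9.377   11.97   36.10
#>    retention   control 5    24.75  4.606   20.39   31.33
#>    retention        BM 5    41.45  6.299   30.50   45.65
#>    retention      UCMD 8    66.85  9.348   54.30   78.33

report$comparisons$pct_nonperm
#> Group comparison vs 'control' (OLS on group indicators, 15 residual df)
#>   group estimate std_error t_value   p_value
#> 1    BM   -15.23     4.753  -3.204 5.919e-03
#> 2  UCMD   -47.03     4.285 -10.977 1.446e-08
```

One simulated 18-subject cohort (5 controls, 5 BM, 8 UCMD; 15,000 events per
sample, paired non-permeabilised/permeabilised staining): mean surface
expression is markedly reduced in the UCMD group (−47.0 points vs controls,
p ≈ 1.4 × 10⁻⁸), mildly in BM, while intracellular retention rises from ~25
points in controls to ~67 in UCMD. Every UCMD subject classifies into
`UCMD_range` (surface < 37%) and every BM/control subject above 44%.
The same screen runs from the shell:

```sh
inst/exec/col6screen simulate --seed 42 --out results/demo
inst/exec/col6screen screen --manifest batch.csv --negative-control NC01 --out results/run1
```

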