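# ctrepro

Reproducibility analysis for plasma microRNA RT-qPCR assays.

Circulating miRNAs are attractive disease biomarkers, but plasma miRNA
studies are notoriously hard to compare: results depend on how quickly
plasma is separated from whole blood, which RNA extraction chemistry is
used, where the cycle-threshold (Ct) bar is set, and who runs the plates.
ctrepro is for biostatisticians and assay developers who want to quantify
those effects. It provides:

* a **mechanistic amplification-curve simulator** with known ground truth
  (group effects, operator shifts, method-dependent dropout, storage
  degradation), generating study-shaped experiments — e.g. 16 cases + 16
  controls, an 11-miRNA panel with RNU6 as endogenous reference, two
  operators, duplicate wells, two extraction workflows, extraction delays
  of 0–72 h;
* a **Ct-calling engine** with fixed thresholds (0.01 / 0.03 / 0.05 / 0.5)
  or instrument-style automatic per-target-per-plate thresholds;
* **relative quantification**: with target Ct `Ct` at threshold intensity
  `Tt` and reference Ct `CR` at `TR`,

  ```
  ∇Ct = Ct − CR                      (fixed threshold)
  ∇Ct = Ct − CR − log2(Tt/TR)        (variable threshold, normalized)
  ∇Ct = Ct − CR, log2(Tt/TR) kept    (variable threshold, covariate)
  ```

  plus ΔΔCt contrasts, |ΔΔCT| summaries and fold changes `2^(−ΔΔCt)`;
* the **six-variant ANOVA family**
  `∇Ct = α + β1·Group + β2·Operator + β3·Group×Operator +
  β4·log2(Tt/TR) + ε` (operator term in/out, interaction in/out, single
  operators, operator average);
* the **reproducibility pipeline**: time-to-extraction contrasts, repeated
  sample acquisition, intra-operator (duplicate) variability,
  inter-operator variability, extraction-method comparison with a
  chi-squared dropout test;
* a **screening statistics kernel**: pooled/Welch t-tests computable from
  printed (mean, SD, n) cells, paired t, chi-squared 2×2,
  Benjamini–Hochberg FDR, the FDR-adjusted per-test alpha
  `α* = f·power·m1 / ((1−f)·m0)` for an m-feature screen, detectable-effect
  solving from the noncentral t, and logistic biomarker-panel ROC/AUC.

## Worked example

Simulate the study-shaped design at extraction time 0, call Ct at the
fixed 0.03 bar, and compare operators within each extraction method:

```r
library(ctrepro)

cfg <- study_preset("paper_design", seed = 2026)
cfg$timepoints_h <- 0
sim <- simulate_experiment(cfg)              # 3072 wells x 40 cycles
ct  <- call_ct_table(sim$curves, threshold = 0.03)
io  <- lapply(split(ct, ct$method), inter_operator_analysis)

head(io$mirneasy_like$per_target[, c("target", "mean_dct_op1",
  "sd_dct_op1", "mean_dct_op2", "p", "mean_abs_ddct")], 4)
#>       target mean_dct_op1 sd_dct_op1 mean_dct_op2     p mean_abs_ddct
#> 1    miR-122       0.5600       2.67       0.8589 0.655          1.18
#> 2 miR-142-3p      -3.0446       1.90      -3.1143 0.884          1.10
#> 3     miR-21      -3.6980       1.95      -3.3483 0.505          1.04
#> 4    miR-218       0.0555       2.47       0.0339 0.972          1.01
```

Each row compares the two operators' ∇Ct for one target over the 32
subjects (unpaired pooled t), with the per-sample |ΔΔCT| summary
alongside. The method comparison shows the simulated trizol-like workflow
is both noisier and more dropout-prone, as injected:

```r
io$trizol_like$total$mean_abs_ddct    # 1.69 vs miRNeasy 1.07
io$trizol_like$not_expressed_total    # 116 of 704; miRNeasy 0 of 704
method_comparison(io$trizol_like, io$mirneasy_like)$chisq
#> chi-squared (Pearson): estimate = 126.4, statistic = 126.4, df = 1,
#> p = 0.0000
```

Published table cells can be re-tested directly from their printed
summaries — here an inter-operator miR-21 contrast, mean ∇Ct −1.83
(SD 2.60) vs 0.05 (SD 2.01), n = 32 per arm:

```r
two_sample_t(summary_stats(-1.83, 2.60, 32), summary_stats(0.05, 2.01, 32))
#> two-sample t (pooled): estimate = -1.88, statistic = -3.236, df = 62,
#> p = 0.0019
```

meaning operator 1's delta-Ct ran 1.88 cycles lower (≈ 3.7-fold apparent
expression difference) — a significant operator effect for this target
under the low-yield workflow.

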