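# epichron

Leukocyte transcriptome correlates of epilepsy duration and age at seizure
onset.

`epichron` is an R package for clinicians and bioinformaticians asking
whether bulk blood-leukocyte RNA-seq expression tracks the clinical course
of epilepsy. Starting from a normalized gene × sample CPM matrix (e.g. a
GREIN export of a GEO series) and a per-patient clinical table, it
provides the full analysis path:

* **Preprocessing** — retain genes with CPM > 1 in at least 50% of samples,
  add a dataset-derived pseudocount (smallest non-zero value / 1000), and
  log2-transform.
* **Cohort stratification & clinical statistics** — split patients at
  duration ≤ 20 vs > 20 years (short vs long duration) or onset age ≤ 12
  vs > 12 years (childhood vs adolescent onset), with descriptive
  statistics and two-sided Mann–Whitney rank-sum comparisons (midranks,
  tie-corrected variance `n₁n₂/12 · [(N+1) − Σ(t³−t)/(N(N−1))]`, 0.5
  continuity correction).
* **Differential expression** — per-gene Welch t (or rank-sum) on log2
  values with log2FC = mean(high) − mean(low) and strict volcano
  classification (p < 0.05 and |log2FC| > 0.5).
* **Trait correlation** — per-gene Spearman r against duration or onset
  age with the t-approximation p (`t = r√((n−2)/(1−r²))`, df = n − 2) and
  the joint |r| > 0.5 ∧ p < 0.05 rule; exclusion flagging for published
  age-associated gene lists.
* **Partial Spearman correlation** — expression and trait each
  residualized by OLS against age, gender and etiology; Spearman on the
  residual pair gives the covariate-adjusted association.
* **Directional overlaps** of gene lists, and **cytogenetic-band
  over-representation** (upper-tail hypergeometric + Benjamini–Hochberg),
  computed locally so no web service is needed.
* **Synthetic data** — a cohort and expression generator with ground-truth
  spike bookkeeping (duration-, onset- and age-driven genes) for recovery
  and calibration testing.

The 16-patient reference clinical table is packaged both as
`fixture_clinical_table()` and as
`inst/extdata/clinical_table1.csv`.

## Worked example

```r
library(epichron)

clin <- fixture_clinical_table()
cohort <- stratify(clin, "duration", 20)
clinical_comparison_table(clin, cohort)
```

```
Clinical comparison stratified by duration at 20 years

duration (n = 8 / 8)
  mean 10.75 / 40.12 | sd 5.18 / 10.58 | min 4 / 25 | max 19 / 61

seizure_frequency (n = 8 / 8)
  mean 9.29 / 1.69 | sd 20.54 / 1.22 | min 0.33 / 0.25 | max 60 / 4
  rank-sum p = 0.45

age (n = 8 / 8)
  mean 29.62 / 49.25 | sd 9.75 / 11.04 | min 16 / 32 | max 45 / 62
  rank-sum p = 0.0073

onset_age (n = 8 / 8)
  mean 18.88 / 9.12 | sd 10.23 / 7.51 | min 6 / 1 | max 37 / 21
  rank-sum p = 0.052

gender (F/M): low: 3/5, high: 3/5
high seizure group (%): low: 50, high: 12.5
```

The short-duration group (`low`) has mean duration 10.75 years against
40.12 in the long-duration group; the groups differ significantly in age
(p = 0.0073), show a strong trend in onset age (p = 0.052) and are
comparable in seizure frequency (p = 0.45) — the ages are older in the
long-duration group simply because duration accumulates with age, which is
exactly the confounding the partial-correlation step addresses.

On synthetic data with known ground truth:

```r
gen  <- generate_expression(clin, spike_spec())   # 2000 genes, 20 per spiked class
expr <- as_expression_matrix(gen$expression) |>
  filter_low_expressed() |>      # CPM > 1 in >= 8 of 16 samples
  log_transform()                # log2(CPM + min-positive/1000)

de  <- group_de(expr, cohort)                      # Welch t on log2 values
scr <- screen_genes(expr, clin, trait = "duration")
adj <- partial_spearman(expr, clin, trait = "duration")
```

```
sensitivity (duration-spiked): 1.00
null flag rate: 0.047
age-confounded flag rate: plain 0.90 -> adjusted 0.10
```

Every spiked duration gene is recovered; independent null genes are
flagged at the ≈ 5% rate the joint threshold implies at n = 16; and genes
driven purely by age — flagged 90% of the time by the plain screen —
drop to a near-null 10% after adjusting for age, gender and etiology.
`plot_volcano(de)` and `plot_partial_residuals()` draw the standard
figures; `run_epilepsy_pipeline()` executes all stages on files and writes
TSV tables plus a JSON manifest.

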