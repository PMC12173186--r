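# regcap

Composite-indicator evaluation of provincial drug-regulatory capacity.

Drug regulation in China is carried out by 31 provincial-level agencies
whose resources and effectiveness differ widely across the eastern,
central and western economic belts. `regcap` implements a quantitative
evaluation pipeline for this setting, aimed at regulatory-science and
health-policy analysts: it turns a region × year × indicator panel into a
two-level composite capacity index, tests regional differences, and
diagnoses which indicators most restrict each region.

## The model

Fourteen indicators `I_1 … I_14` are grouped into five capacity
dimensions (resource acquisition, functional performance, performance
level, learning and development, Internet application). The pipeline is:

1. **Normalization.** Each indicator is min-max scaled to `[0, 1]`:
   `y = (x − x_min) / (x_max − x_min)` for positive indicators and
   `y = (x_max − x) / (x_max − x_min)` for negative ones, with bounds taken
   over the pooled 2018–2022 panel so scores are comparable across years.
2. **Subjective weights.** Each expert scores indicator importance on a
   1–5 scale; an indicator's weight for one expert is its score share
   `w_j = d_j / Σ_j d_j`, and `B_j` is the mean over experts.
3. **Entropy weights.** With `n` region-years as objects,
   `P_ij = y_ij / Σ_i y_ij`, `E_j = −(1/ln n) Σ_i P_ij ln P_ij`, and
   `A_j = (1 − E_j) / (m − Σ E)`: more dispersed indicators carry more
   objective information and hence more weight.
4. **Combined weights.** `W_j = A_j B_j / Σ_j A_j B_j`. Summing `W_j`
   within a dimension gives the dimension weight `W_d`; dividing by it
   gives within-dimension weights.
5. **Scores.** Dimension score `s_d = Σ_{j∈d} within_j · y_j`; composite
   `C = Σ_d W_d · s_d`; regions are ranked per year by competition
   ranking ("1, 2, 2, 4") at the 3-decimal precision of published tables.
6. **Inference and diagnosis.** One-way ANOVA compares score columns
   across the three economic belts; the obstacle degree
   `P_j = (1 − y_j) W_j / Σ_k (1 − y_k) W_k × 100%` apportions each
   region's shortfall to indicators; national pharmacovigilance series
   (ADR report counts, clinical-trial pass rates) are summarized
   descriptively.

A synthetic-data generator (`simulate_panel()`, `simulate_expert_scores()`,
`simulate_vigilance()`) produces panels with the same structure (31
regions in 12/9/10 belts, 2018–2022, 7 experts) and a known latent
capacity per region, so recovery and calibration of the whole pipeline
can be tested without access to the original raw data.

## Worked example

The package bundles the published weight system and the published 2022
score table as fixtures. Reconstructing the composite index from the five
printed dimension scores and the printed dimension weights
(0.153, 0.218, 0.289, 0.210, 0.130):

```r
library(regcap)
schema  <- read_schema(regcap_example("schema.yaml"))
weights <- printed_weight_set(schema)
scores  <- printed_scores_2022()

recon <- composite_scores(scores, weights)
head(recon[order(recon$rank), c("region", "category", "rank", "composite_3dp")], 5)
#>    region category rank composite_3dp
#>   Jiangsu  eastern    1         0.204
#>   Beijing  eastern    2         0.172
#>  Zhejiang  eastern    2         0.172
#>  Shanghai  eastern    4         0.162
#>     Jilin  central    5         0.147

round_half_up(mean(recon$composite_3dp), 3)       # 0.113  national average
count_above_mean(scores$composite, digits = 3)    # 13 regions above it
```

Jiangsu leads; Beijing and Zhejiang tie at rank 2 so rank 3 is skipped.
Thirteen regions sit above the national average of 0.113 (the comparison
is made at the table's 3-decimal precision).

Regional differences, tested across the three belts:

```r
anova_by_column(scores)[, c("column", "F", "p", "stars")]
#>       column    F       p stars
#>    composite 3.63 0.03959     *
#>     resource 7.90 0.00191    **
#>   functional 2.89 0.07222
#>  performance 2.45 0.10415
#>     learning 1.34 0.27818
#>     internet 2.75 0.08121
```

Resource acquisition differs strongly across belts (p < 0.01) and the
composite significantly (p < 0.05); the remaining dimensions do not reach
the 5% level. Clinical-trial pass rates follow from the published counts:

```r
pass_rate(c(879, 1483, 1579), c(1099, 1830, 1829))
#> 79.98 81.04 86.33
```

For a full run on data files (normalization → weighting → scoring →
ANOVA → obstacle diagnosis → report bundle) see `?run_pipeline`, or the
thin command-line wrapper `exec/regcap`. The methods vignette
(`vignettes/regulatory-capacity.Rmd`) documents the model, the generator
and all numerical conventions.

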