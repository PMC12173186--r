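---
title: "Methods: a two-level composite index of drug-regulatory capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-level composite index of drug-regulatory capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regcap)
```

## The evaluation problem

`regcap` evaluates the drug-regulatory capacity of the 31 Chinese
provincial-level regions from a yearly panel of 14 indicators grouped
into five capacity dimensions. The product is a composite index per
region and year, regional-difference tests across the eastern, central
and western economic belts, and an obstacle-factor diagnosis that says
*which* indicator most restricts each region. The same machinery applies
to any two-level indicator system described by a schema file; nothing in
the code is tied to the bundled 14-indicator layout.

The pipeline makes the assumptions standard in entropy-weight composite
indicators:

* indicators are monotonically related to capacity, with their direction
  declared in the schema (`positive` / `negative`);
* the linear min-max transform makes values comparable after removing
  units; no distributional form is assumed;
* the weighted arithmetic mean is an acceptable aggregator, i.e. deficits
  in one indicator can be compensated by others (fully compensatory
  aggregation — if that is not wanted, a geometric aggregator would be a
  structural change, not a parameter);
* for the ANOVA stage, composite scores within each belt are roughly
  normal with similar variances. With groups of 12/9/10 the F test is
  robust to moderate violations, but the p-values should be read as
  approximate.

## Stages and their conventions

### Missing data

`interpolate_missing()` fills interior gaps of each (region, indicator)
series linearly in year and boundary gaps with the nearest observed
value; a series with a single observation is filled with that constant.
A fully missing series is an error rather than an imputation, since the
pipeline would otherwise fabricate an entire indicator. Every imputed
cell is logged in the `"imputed"` attribute. Imputation never happens at
read time: `read_panel()` keeps `NA`s so that `validate_panel()` can
report them.

### Normalization

Bounds are taken over the **pooled** panel (all region-years) by
default. Pooling is what makes year-to-year trend panels meaningful: a
per-year scope (`scope = "per_year"`) re-bases every year to its own
min-max and is provided for cross-sectional use only. Two degenerate
cases are handled explicitly:

* a **constant indicator** within its scope group has no ordering
  information; its cells are set to 0.5 with a warning. The value 0.5 is
  arbitrary by design — the entropy stage assigns such an indicator zero
  weight, so the choice cannot affect any score;
* when **frozen bounds** are applied to new data (scoring a new year on
  an old scale) out-of-range values are clipped to `[0, 1]` with a
  warning, keeping the score space closed.

### Weighting

Subjective weights average the per-expert score-share vectors rather
than taking the share of summed scores: each expert's judgement is first
normalized to a weight vector, then experts are pooled with equal
weight, so a generous scorer does not dominate. Entropy weights are
computed **once** on the pooled panel and held fixed across years — the
published weight system is a single table used for all years, and fixed
weights are what makes scores comparable over time. In the entropy
formula `0·ln 0` is taken as its limit 0 (normalized minima are exactly
zero, so zeros always occur); an `eps` argument adds a uniform shift to
the proportions purely for cross-checking against implementations that
regularize instead. An all-zero normalized column gets entropy 1 (zero
weight) with a warning instead of `0/0`.

The combined weight is the normalized product `A_j B_j / Σ A_j B_j`.
Two consequences worth knowing: the operation is symmetric in its
arguments, and a constant indicator ends with combined weight exactly 0
no matter how important experts rate it. Dimension weights are the sums
of their members' combined weights and within-dimension weights their
shares — the aggregation convention; the package equally accepts a
frozen two-level table via `printed_weight_set()`. The bundled printed
weight table rounds to 3 decimals, which leaves three within-dimension
vectors summing to 1.001; the loader renormalizes within dimensions (a
≤0.1% correction) and keeps the printed dimension weights verbatim,
since table comparisons weight printed dimension scores by printed
dimension weights.

### Scoring, ranking and printed-precision comparisons

Scores are weighted means of values in `[0, 1]`, so dimension scores and
the composite stay in `[0, 1]`, the composite is monotone in every
normalized value, and permuting indicators changes nothing (these are
tested properties, not hopes). Published score tables print 3 decimals
and exhibit competition ranking — tied printed composites share a rank
and the next rank is skipped — so `rank_regions()` ranks at 3-decimal
precision by default (`digits = NULL` for full precision), and
score tables carry both the full-precision composite and a
`composite_3dp` column rounded **half-up** (`round_half_up()`), because
printed tables round half away from zero while R's `round()` rounds
half-even.

One counting convention deserves a flag. `count_above_mean()` counts
values strictly above the exact arithmetic mean by default. When the
comparison target is a printed table, the published count of
above-average regions corresponds to comparing the printed 3-decimal
scores against the 3-decimal rounded mean (`digits = 3`): a region whose
printed composite equals the printed average is not "above average".
The two conventions can differ by one region when a composite sits
within half a rounding unit of the mean, which is exactly the situation
in the bundled 2022 table.

### ANOVA

`one_way_anova()` computes the classic fixed-effects decomposition from
sums of squares and the upper-tail F probability. It refuses groups of
fewer than two members and zero within-group variance ("degenerate
ANOVA") rather than returning infinities. Stars follow the usual
two-level convention (`*` p < 0.05, `**` p < 0.01). No Welch correction
and no post-hoc tests are applied — the published analysis reports a
single F and p per column, and that is what is reproduced. Note that
recomputing F from a *printed* (3-decimal) score table cannot reproduce
F values computed on pre-rounding data; the significance pattern is the
stable quantity, and that is what the test suite asserts.

### Obstacle diagnosis

Obstacle degrees use the **global** combined weights `W_j`, not
within-dimension weights, so degrees are comparable across dimensions
and sum to 100% per region-year. If a region is at the ideal on every
indicator, degrees are reported as 0 with a `no_obstacles` flag instead
of `0/0`. Ties in `top_obstacles()` break by schema order,
deterministically. For regional summaries two conventions exist and the
published tables do not say which was used; `regional_obstacle_summary()`
defaults to the mean of member regions' degree vectors renormalized to
100% (`"mean_of_members"`, the convention that treats every region
equally) and offers `"profile"` (degrees of the category-mean profile)
behind a flag.

### Vigilance descriptives

Pass rates and serious-report proportions are plain ratios ×100 rounded
half-up to 2 decimals; year-over-year changes are relative to the
previous year. These are deliberately descriptive — no
disproportionality statistics are computed, because the national series
contain yearly totals only.

## The synthetic-data generator

`simulate_panel()` emulates the structure of the study panel: 31 regions
in belts of 12/9/10, years 2018–2022, the 14-indicator schema, and 7
experts scoring 1–5. Its statistical model is deliberately simple: a
latent capacity per region (belt mean + Gaussian region effect), a
linear year trend, Gaussian cell noise on the latent scale, and
per-indicator monotone links that map the latent signal to plausible
units (qualified rates squeezed into 85–100%, counts made integer and
nonnegative, monetary values log-linked). Defaults are fixed once at
values a policy analyst would call realistic on a unit latent scale —
belt gap 0.1, region effect SD 0.05, cell noise SD 0.05, trend 0.02 per
year, 2% missing cells — and all randomness flows from the mandatory
seed through a local RNG that leaves global state untouched. The spec of
the config also exposes a `region_sd` separately from `noise_sd`:
without a persistent region effect there would be no latent ordering for
recovery tests to recover.

What the generator does **not** emulate: cross-indicator correlation
beyond the shared latent, heavy-tailed provincial size effects, serial
correlation of the noise, or policy shocks (such as a pandemic year).
Passing recovery tests therefore shows the pipeline is consistent under
its own assumptions — it does not validate those assumptions against
real provincial data.

Two calibration properties are checked at simulation scale (problem
sizes chosen as a compromise the test suite can afford): with the belt
gap at twice the cell-noise SD, the composite ANOVA should reject at
α = 0.05 in at least 90% of 200 seeds; with no gap, the rejection rate
over 200 seeds should sit near the nominal 5% (the accepted band is
2–9%). The observed null rate runs slightly conservative, which is
expected: pooled normalization and data-driven entropy weights couple
the regions weakly, shrinking the effective between-group variation
under the null. Latent rank recovery (Spearman between latent capacity
and composite) is checked over 30 seeds at low noise.

## Known limitations

* Min-max normalization is sensitive to outliers at the bounds; a single
  extreme province compresses everyone else. The pipeline reports the
  bounds it used so this is at least visible.
* Entropy weights depend on the object slice; adding a year changes
  them. The package freezes them on the pooled panel by design, but that
  means published weights cannot be re-derived without the original raw
  panel — they are consumed as a fixture instead.
* Reconstructions from printed tables inherit printed rounding;
  quantities computed on pre-rounding data (F statistics, pre-rounding
  averages) can only be matched in pattern, not digit-for-digit.
* The ANOVA treats regions as independent sampling units within belts;
  spatial spillovers between neighbouring provinces are ignored.
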