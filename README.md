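# tailbias

Differential-expression analysis for 3′-biased bulk RNA-seq, with a
conservative three-way consensus correction, age-trend statistics,
lifespan tests and ΔΔCT qPCR concordance.

## The problem

RNA extracted with guanidinium/phenol reagents and sequenced with
3′-weighted protocols shows coverage that decays with distance from the
transcript 3′ end. When the decay scale differs between the groups being
compared, long transcripts lose proportionally more reads in one group
than the other, and the artifact looks exactly like differential
expression correlated with transcript length: a scatter of log2 fold
change against log10(length) shows a strong trend and an uncorrected
pipeline calls hundreds of false positives under a true null.

`tailbias` is for people analysing such data — aging studies in model
organisms are a typical case, where RNA quality drifts with age and
treatment — and for people who want to *test* such pipelines: a
synthetic-data generator with known ground truth drives every stage.

## The method

Coverage decay is modelled as exponential with per-sample scale τ (nt); a
transcript of length *L* captures the fraction

> B(L, τ) = (τ/L) (1 − e^(−L/τ)).

On top of a self-contained count pipeline (CPM > 1 filter on the smallest
group, TMM normalization factors, common NB dispersion φ by conditional
maximum likelihood, conditional exact test, Benjamini–Hochberg FDR), three
corrections are computed per two-group contrast:

1. **3′-window counting** — rerun the pipeline on counts restricted to the
   3′-terminal min(L, W) nt; the length-dependent group difference cancels.
2. **Length-binned TMM** — renormalise within 10 equal-count bins on
   log10(length), then align the residual LogFC-vs-length slope.
3. **Slope alignment** — remove the OLS trend of LogFC on log10(length),
   preserving the mean exactly.

The per-gene **consensus** takes the minimum-magnitude LogFC of the three
when they share a sign and sets LogFC = 0 (p = 1) on any sign conflict, so
differential expression is declared only when all three methods agree.

Also included: the age-associated fold change 2^(2b) from the OLS slope
*b* of log2 expression over ages coded 0/1/2 (a gene going 1, 2, 4 across
ages scores exactly 4), group-exclusive Venn partitions of age-associated
genes, hypergeometric overrepresentation over GMT gene sets, a lifespan
battery (log-rank, Fisher exact on the pooled-median split, Wang–Allison
at the pooled 90th percentile, Bonferroni), and ΔΔCT qPCR concordance
with RNA-seq fold changes.

## Worked example

A null experiment (no true effects) with strong differential 3′-bias
between diets (τ = 1000 nt vs 4000 nt), males at 2 weeks, 3 replicates
per group:

```r
library(tailbias)
sim <- simulate_counts(sim_config(
  n_genes = 2000, seed = 1,
  design = dplyr::filter(default_design(), sex == "male", age_weeks == 2),
  de_fraction = 0, age_slope_fraction = 0,
  bias_tau = c(torin = 1000, control = 4000)))
fit <- consensus_de(sim$counts, sim$windowed_counts, sim$annotation,
                    sim$samples)
fit
#> Consensus 3'-bias-corrected DE: torin vs control
#>   genes in consensus: 1994
#>   zeroed (sign conflict): 425
#>   FDR < 0.05: consensus 131 | uncorrected 642
fit$diagnostics
#> # A tibble: 5 × 6
#>   route           n pearson_r    slope intercept degenerate
#>   <chr>       <int>     <dbl>    <dbl>     <dbl> <lgl>
#> 1 uncorrected  1994   -0.873  -1.29       4.52   FALSE
#> 2 threeprime   1994   -0.0304 -0.0249     0.107  FALSE
#> 3 binned_tmm   1994    0.0132  0.00950   -0.0453 FALSE
#> 4 slope_only   1994    0.0113  0.00821   -0.0327 FALSE
#> 5 consensus    1994   -0.0164 -0.00889    0.0324 FALSE
```

Every gene here is a true null. The uncorrected pipeline shows the
length–LogFC correlation of −0.87 characteristic of differential 3′-bias
and calls 642 genes at FDR < 0.05; each correction flattens the trend
(|r| ≤ 0.03), and the consensus cuts the false calls by ~80% (to 131),
zeroing 425 genes whose three estimates disagreed in sign. `tidy(fit)`
returns the per-gene consensus table, `autoplot(fit)` draws the
length-vs-LogFC panels per route.

The lifespan battery on a simulated protective treatment (hazard ratio
0.5, n = 150/group):

```r
compare_survival(simulate_lifespans(150, effect = 0.5, seed = 1),
                 control = "control")
#> # A tibble: 1 × 12
#>   group       n median median_control max_quantile logrank_chisq logrank_p …
#> 1 treated   150     64             55           73          57.2  4.01e-14 …
```

The treated median rises from 55 to 64 days and all three tests agree the
cohorts differ.

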