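---
title: "Consensus correction of 3'-coverage bias in RNA-seq differential expression"
author: "tailbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus correction of 3'-coverage bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message = FALSE}
library(tailbias)
library(dplyr)
```

## The problem

RNA extracted with guanidinium/phenol chemistry (Trizol, QIAzol) and
sequenced with oligo-dT-primed 3' protocols shows *3'-coverage bias*: read
coverage decays with distance from the transcript 3' end. When the degree
of decay differs between the sample groups being compared — different
extraction batches, different RIN, different storage — the decay difference
masquerades as differential expression that is *correlated with transcript
length*. Long transcripts lose proportionally more reads in the more
degraded group, so a scatter of log2 fold change (LogFC) against
log10(length) shows a strong trend, and an uncorrected count pipeline
reports hundreds of false positives under a true null.

`tailbias` implements a conservative defence: three independent correction
strategies whose artifacts differ, fused per gene by a rule that only
declares differential expression when all three agree.

## The model

We model per-gene coverage as exponential decay from the 3' end with a
per-sample scale $\tau_s$ (nt). A transcript of length $L$ then captures
the fraction

$$B(L, \tau) = \frac{\tau}{L}\left(1 - e^{-L/\tau}\right),$$

which is 1 when $\tau \gg L$ (no bias) and decreases with $L$. The
fraction of a transcript's reads falling in its 3'-terminal window of
width $W$ is

$$w(L, \tau, W) = \frac{1 - e^{-\min(W, L)/\tau}}{1 - e^{-L/\tau}}.$$

Both are closed forms, so the synthetic-data generator built on them is
testable against Monte-Carlo and limiting cases. Counts are negative
binomial, $y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi)$ with
$\mathrm{Var} = \mu + \phi\mu^2$, and

$$\mu_{gs} \propto e_g \, B(L_g, \tau_s)\, 2^{x_s \delta_g + a_s b_g},$$

where $e_g$ is a log-normal baseline abundance, $x_s$ the treatment
indicator, $\delta_g$ the true treatment effect (log2), $a_s \in \{0,1,2\}$
the age index for 2/4/6 weeks, and $b_g$ the true per-timepoint age slope
(log2). Each sample is scaled so its expected library size is constant:
3'-bias is purely compositional, exactly as it appears after CPM
normalisation of real data. Windowed counts are binomial thinnings of the
full counts with probability $w(L_g, \tau_s, W)$, so they can never exceed
them.

## The count pipeline

The differential-expression engine is self-contained so the correction
layer can drive it with arbitrary count inputs:

1. **Filter**: keep genes with CPM strictly above 1.0 in at least 50% of
   the smallest group (rounded up).
2. **Normalise**: trimmed mean of M-values against a reference sample
   (upper-quartile rule), M-values doubly trimmed (30% on M, 5% on
   abundance) and weighted by delta-method variances. The factors are
   size-factor style — they absorb depth and composition, have geometric
   mean 1, and `counts / factor` puts samples on a common scale. With
   equal library sizes they coincide with the classic TMM factors, which
   is how the test suite cross-checks them.
3. **Dispersion**: one common NB dispersion by conditional maximum
   likelihood on counts rescaled to the common scale (proportional
   rescaling plus rounding stands in for exact quantile adjustment; the
   approximation error is far below the recovery tolerances we verify).
4. **Test**: conditional exact test. For each gene the split of its total
   between the two groups is compared with its conditional distribution
   under equal means; the two-sided p-value sums the probabilities of all
   splits no more likely than the observed one. At $\phi = 0$ this is
   exactly the binomial test (verified to machine precision). LogFC uses a
   prior count of 0.125 so zeros never produce infinities.
5. **FDR**: Benjamini–Hochberg.

## The three corrections and the consensus

- **3'-window counting** (`method1_threeprime()`): rerun the full pipeline
  on counts restricted to the 3'-terminal $\min(L, W)$ nt. Under the decay
  model the windowed mean is $\propto \tau(1 - e^{-W/\tau}) / L$: the
  group difference collapses to a per-sample constant that normalisation
  absorbs, so this route removes the length-correlated artifact at the
  cost of discarding reads. $W$ defaults to 1000 nt (configurable; chosen
  as a round value comfortably below typical fly transcript lengths).
- **Length-binned renormalisation** (`method2_binned_tmm()`): split genes
  into 10 equal-count bins on log10(length) (ties broken by gene id) and
  renormalise within each bin, so each bin's factors absorb the local
  bias; then remove any residual trend with the slope alignment below.
  Bins with fewer than 5 genes merge into a neighbour with a warning.
- **Slope alignment** (`method3_slope_align()`): fit
  $\mathrm{LogFC} \sim \log_{10}(L)$ by OLS across genes and subtract the
  trend. The mean LogFC is preserved exactly, the residual slope is zero
  by construction, and the transform is idempotent. The log base of the
  length axis only rescales the reported slope, never the corrected
  values.
- **Consensus** (`consensus()`): per gene, if the three LogFC estimates do
  not share one sign, the gene is zeroed (LogFC 0, p 1); otherwise the
  minimum-magnitude estimate wins and carries its method's p-value, and
  BH FDR is recomputed across genes. Two properties hold by construction
  and are asserted as invariants: $|\mathrm{LogFC}_{cons}| \le
  \min_m |\mathrm{LogFC}_m|$, and the consensus never opposes any
  contributing method's sign.

Three decisions here were genuinely open and are worth stating. The
consensus is defined in the literature for fold changes only; we carry the
chosen method's p-value (1 for zeroed genes) and re-run BH, which
preserves the "confirmed by all three methods" intent but means the
slope-only route contributes p-values computed from unaligned counts —
the price is a residual false-positive rate visible in the rescue numbers
below. "Differently directed" is read as a strict sign conflict
(min·max < 0), so zeros agree with either sign. Ties in the
minimum-magnitude rule go to the first method in argument order
(deterministic and vanishingly rare with continuous estimates).

`consensus_de()` runs everything for one two-group contrast and returns
the per-route tables, the consensus, and length-trend diagnostics;
`tidy()`, `glance()` and `autoplot()` work on the result. Contrasts are
run per design cell (e.g. males, 2 weeks, torin vs control) rather than
through a factorial model: the engine is a two-group exact test by design,
and per-cell contrasts are what the downstream age-trend logic consumes.

```{r pipeline, eval = FALSE}
sim <- simulate_counts(sim_config(
  n_genes = 2000, seed = 1,
  design = dplyr::filter(default_design(), sex == "male", age_weeks == 2),
  de_fraction = 0, bias_tau = c(torin = 1000, control = 4000)))
fit <- consensus_de(sim$counts, sim$windowed_counts, sim$annotation,
                    sim$samples)
glance(fit)
autoplot(fit)
```

## Age trends, exclusive sets, overrepresentation

Expression trajectories are mean $\log_2(\mathrm{CPM} + 0.5)$ per age
(the pseudo-count choice keeps zeros finite; any common summary works
since the statistic is scale-equivariant). The **age-associated fold
change** is $2^{2b}$, where $b$ is the OLS slope of log2 expression on
ages coded 0, 1, 2 — with three equally spaced points this reduces to
$b = (y_3 - y_1)/2$, so the statistic is the fitted old-vs-young ratio: a
gene going 1, 2, 4 across ages scores exactly 4. A gene is called
age-associated when its young-vs-old consensus p-value is below 0.05 and
$|\log_2|$ of the age fold change strictly exceeds 0.3; the young-vs-old
consensus contrast supplies the p-value because it is the widest lever on
the trajectory and keeps the call consistent with the bias correction.
`exclusive_sets()` partitions the called genes into every region of the
group-inclusion lattice (up and down separately), and `ora()` performs
one-sided hypergeometric overrepresentation against user-supplied GMT
collections (KEGG/GO/Reactome exports or the bundled synthetic fixture) —
static files only, so results are version-stable.

## Lifespan battery

Cohorts are uncensored integer days (every fly dies under daily
collection), so the Kaplan–Meier estimator reduces to the empirical
survival function. Survival curves are compared with the log-rank test
(hypergeometric variance at each death day handles the heavy ties; the
`survival` package provides the statistic). Median lifespan is compared by
dichotomising every individual at the *pooled* median and applying the
two-sided Fisher exact test — the construction used by the standard online
lifespan-analysis services; maximum lifespan uses the same construction at
the pooled 90th percentile (Wang–Allison), ties falling in the lower cell.
Bonferroni adjustment is applied across comparisons. The lifespan
simulator draws from a Gompertz hazard $h(t) = a\,e^{bt}$ with defaults
$a = 3\times10^{-4}$/day, $b = 0.1$/day — median ≈ 55 days, the scale of
wild-type Canton-S males at 25 °C — and a treated cohort multiplies $a$
by a hazard ratio.

## qPCR concordance

$\Delta C_T = C_T(\mathrm{reference}) - C_T(\mathrm{target})$ per
biological sample, technical replicates averaged first, multiple reference
genes combined by the arithmetic mean of their $\Delta C_T$; then
$-\Delta\Delta C_T$ = mean $\Delta C_T$(treated) − mean
$\Delta C_T$(control), directly comparable to the RNA-seq log2 fold
change under the classic assumption of amplification efficiency 2 (no
Pfaffl-style efficiency correction, and no reference-gene stability
statistic — excluding an unstable reference is the user's call). Plate
offsets common to a sample cancel exactly, which the tests assert.

## What the generator does and does not emulate

The generator reproduces the statistical structure the analysis assumes:
a 2 sexes × 3 ages × 2 diets × 3 replicates design, NB counts with
library-size normalisation, length-dependent capture under per-sample
decay scales, known treatment and age effects with random signs (signed
effects keep the compositional shift of injected genes roughly balanced),
binomially thinned 3'-window counts, Gompertz lifespans, and Ct tables
with sample offsets and well noise. It does **not** emulate isoform
structure, positional GC/fragment effects, correlated gene modules,
batch-by-covariate confounding, or overdispersion heterogeneity (a single
common $\phi$). Passing tests therefore demonstrate correctness of the
machinery under the stated model, not robustness to everything real data
can do.

Default problem sizes are the package's working scale: 2000 genes, library
size $10^6$, dispersion 0.05, lengths $10^{\mathrm{U}(2.7, 4.3)}$ nt,
$\tau = 2000$ nt unless set per group. These keep the exact test's
conditional enumeration (cost proportional to per-gene totals) fast enough
that the full simulation battery runs in about a minute, while leaving
per-gene counts in the realistic tens-to-thousands range.

## Numerical choices and known limitations

- **Discreteness of the exact test.** The conditional exact test is
  discrete: a gene observed at its conditional mode has p exactly 1, and
  low-count genes passing the CPM filter hit that atom with appreciable
  probability (≈4% of genes at the default depth). The null p-value
  distribution is therefore sub-uniform near 1 — a whole-distribution
  uniformity test (e.g. Kolmogorov–Smirnov over thousands of genes)
  detects this for *any* test of this construction, including the
  classic reference implementation on identical data — while the
  rejection-region calibration that matters for error control is nominal
  (empirical type-I error 0.04–0.05 at the 0.05 level in our null
  simulations).
- **Residual consensus false calls.** Because the slope-only route adjusts
  fold changes but not p-values, a gene can be zeroed-out in magnitude yet
  carry a small p from the biased test when another route is chosen. Under
  a strong differential-bias null (τ 1000 vs 4000 nt) the consensus still
  removes ≈80% of the uncorrected pipeline's false discoveries; it does
  not remove all of them.
- **Boundary conventions.** CPM filtering and the age-association
  thresholds use strict inequalities; dispersion estimates are clipped at
  0; the minimum-magnitude tie goes to the first method; Fisher tables
  with a zero margin report p = 1 with a `degenerate` flag.
- **Scope.** No censoring support in the lifespan battery (all deaths
  observed); no GLM/factorial DE models or tagwise dispersion shrinkage;
  no isoform-aware or model-based positional bias correction; no live
  pathway-database queries.
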