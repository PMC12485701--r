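---
title: "Inferring functional sex chromosome complement from bulk expression"
author: "scckit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring functional sex chromosome complement from bulk expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tumors (and, more rarely, normal tissues) can lose the transcriptional output
of a sex chromosome: loss of chromosome Y (LOY) in male patients, loss of an
X chromosome (LOX) or loss of X inactivation (XaXa) in female patients. The
DNA-level karyotype is often unavailable, but bulk RNA-seq is ubiquitous, and
the *functional* sex chromosome complement (SCC) leaves a clear transcriptional
signature: XIST is expressed almost exclusively when an inactive X is present,
and a small panel of broadly expressed, non-pseudoautosomal Y-linked genes
(DDX3Y, EIF1AY, KDM5D, RPS4Y1, USP9Y, ZFY, UTY) is expressed only when an
active Y is present. scckit turns this signature into an explicit classifier
and carries the resulting calls through the downstream analyses they enable.

## The classifier

Expression in TPM is binned into three tiers: **expressed** (>= 10 TPM),
**low** (1-10 TPM), **not expressed** (<= 1 TPM). Both cutpoints are
configurable (`ExpressionThresholds`); the >= comparator at 10 TPM is the
default. An active Y is called when at least 2 of the 7 panel genes are in
the expressed tier (`MarkerPanel`, both the panel and the count are
configurable) — requiring two genes suppresses false positives from a single
aberrant transcript while tolerating organ-to-organ variability in individual
Y genes.

Calls follow a fixed decision table over (XIST tier, Y presence, reported
sex, X DNA ploidy). For female samples, absent XIST is ambiguous on its own:
with single-X ploidy it means LOX (`X0_LOX`), with double-X ploidy it means
two active X chromosomes (`XaXa`), and with unknown ploidy the package
refuses to guess and returns `X0_ambiguous`. XIST in the low tier counts as
not-expressed for calls (the binary X+ criterion is >= 10 TPM); the tier is
still reported for descriptive tables. Male calls use expression only —
ploidy is ignored. Discordant evidence yields explicit states
(`XXY_like`, `XX_unexpected`, `XY_unexpected`) or a `ploidy_inconsistent`
flag (XIST expressed with single-X ploidy) rather than a silent coercion.

Some tissues are poor substrates for fixed thresholds: whole blood and most
brain regions sit below 10 TPM for these markers even in typical samples.
The package formalizes this as a computed rule (`flagLowSignalTissues`): a
tissue is flagged when the median XIST TPM among reported-female samples, or
the median mean-Y-panel TPM among reported-male samples, falls below the
expressed threshold. A computed rule was chosen over a fixed tissue list
because the phenomenon is a property of the data, not of tissue names.

## Differential expression

DE operates on `log2(TPM + c)` (`c = 0.5` by default). TPM is what the
relevant public cohorts distribute; a counts mode is deliberately out of
scope. The model per gene is weighted least squares on a two-level group
indicator plus age (age is a covariate because atypical SCC is
age-associated), with two layers borrowed from the moderated-linear-model
tradition and implemented explicitly in the package:

1. **Precision weights.** Per-gene residual standard deviations from an OLS
   pre-fit are smoothed against mean log-expression with lowess (span 0.5),
   the trend is evaluated at each observation's fitted value, and the weight
   is the predicted sd to the power -4.
2. **Variance moderation.** Residual variances are shrunk toward a pooled
   prior, `s~²ᵍ = (d₀s₀² + dᵍs²ᵍ)/(d₀ + dᵍ)`, with `(d₀, s₀²)` estimated by
   moment-matching the log residual variances against the scaled-F model
   (trigamma inversion by Newton's method). `d₀` is capped at 10x the median
   residual df so that a near-flat variance distribution cannot collapse
   into infinite shrinkage; the cap is a config field. The moderated t has
   `d₀ + dᵍ` degrees of freedom.

Genes are tested only when TPM > 1 in at least 20% of the tissue's samples
(the filter is configurable and recorded); tissues enter a contrast only when
both groups have at least 3 samples. P-values are BH-adjusted within each
tissue.

**Cross-tissue consistency.** A gene belongs to a contrast's consistent
profile when its fold change has the same (nonzero) sign in *all* eligible
tissues and p < 0.05 in at least 60% of them. A fold change of exactly zero
matches no direction and disqualifies the gene. Profile overlaps are tested
with the upper-tail hypergeometric `P(X >= k)`; the default universe is the
intersection of genes tested in both analyses, since no other universe is
canonically defined for two profiles built on different tissue sets.

## Group structure and X0 convergence

Per-gene one-way ANOVA across the four groups `female_XaXi`, `female_X0`,
`male_XY`, `male_X0` (ambiguous and unexpected calls are excluded first) is
computed by vectorized sums of squares; the top `n_top` genes by p-value
(ties: descending F, then gene id — fully deterministic) feed a two-component
PLS-DA (NIPALS PLS2 against one-hot group membership, X-loading deflation).
Genes are centered and unit-scaled by default; scaling is a flag because
either convention is defensible and the choice is recorded in the run
manifest. Component signs are fixed so the largest-magnitude loading is
positive, making projections bit-reproducible.

Convergence of the two X0 groups is summarized as
`r = d(centroid(female_X0), centroid(male_X0)) /
d(centroid(female_XaXi), centroid(male_XY))` in score space; `r < 1` means
sex-chromosome-loss tumors are closer to each other than the typical groups
are. Note that a cohort with *no planted effects at all* still shows `r < 1`
when sex-chromosome genes are included, because the marker genes themselves
carry real group structure (both X0 groups lack XIST and Y expression); the
neutral reference analysis therefore excludes chrX/chrY genes, which the
`exclude_sex_chromosomes` flag provides.

## Survival

Kaplan-Meier curves, medians and log-rank tests are computed through the
survival package (survfit/survdiff) behind a fixed set of conventions: ties
aggregate exactly (censoring at an event time is processed after events), the
median is the smallest event time with `S(t) <= 0.5` (a strict-inequality
variant is a flag), pairwise log-rank tests over all group pairs are
BH-adjusted by default (Bonferroni available). Groups are the five labels
`female_XaXi`, `female_XaXa`, `female_X0`, `male_XY`, `male_X0`; ambiguous
and unexpected calls are excluded.

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the pipeline is built
for, with planted truth for every sample and gene:

- **Markers**: XIST ~ LogNormal(ln 60, 0.4) in XaXi samples, LogNormal(ln 0.2,
  0.5) otherwise; each Y gene ~ LogNormal(ln 30, 0.5) with Y present,
  LogNormal(ln 0.1, 0.5) otherwise. At these defaults the tier boundaries at
  1 and 10 TPM carry essentially no probability mass, so classifier recovery
  is exact by construction.
- **Baseline**: gene-level meanlog ~ N(2, 1), per-tissue per-gene offsets
  ~ N(0, 0.3), within-group log-normal noise sdlog 0.5.
- **Planted effects** are a log-scale effect matrix over (gene, group):
  2-fold sets for LOX (50 genes), XaXa (50), LOY (50); a 200-gene baseline
  sex-difference set attached to the Xi-retaining female groups (so it is
  lost with LOX — the mechanism behind X0 convergence); and a 100-gene shift
  shared by both X0 groups. Per-contrast truth is *derived* from this matrix
  (genes whose effects differ between the contrast's groups), so overlapping
  sets stay honest in recovery metrics.
- **Ages**: N(60, 10) plus offsets +3.7 y (female X0) and +4.6 y (male X0).
- **Survival**: exponential with medians 4445 d (XaXi and XaXa), 3200 d (XY)
  and a common 1900 d for both X0 groups (between the two reported X0
  medians, reflecting their statistically indistinguishable survival), with
  independent Uniform(0, c_max) censoring where c_max is solved per group so
  the expected censored fraction is 0.3. An earlier design that censored at
  a random fraction of the death time was rejected as informative censoring —
  it biases the product-limit estimate upward.
- **Simulated TPM are not renormalized to sum to 1e6 per sample**, and the
  pipeline never relies on that property.
- Non-marker chrY genes follow the autosomal baseline model; their labels
  exercise chromosome bookkeeping only. Tumor purity mixtures, single-cell
  heterogeneity, library-level artifacts and batch effects are *not*
  simulated, so green tests certify the statistical machinery, not
  robustness to those real-data features.

`corruptCohort()` stress-tests the classifier: label swaps flip reported sex,
and boundary noise pushes expressed markers into the low tier and blanks the
X ploidy, which must surface as `X0_ambiguous`/unexpected calls only on the
corrupted samples.

## Problem sizes and numerical choices

The validation suite runs the default cohort (6 tissues x 20 samples per
group x 2000 genes), null-calibration batches of 2000 genes x 20 samples
over 20 seeds, 100 seeded convergence replicates at a reduced size (2
tissues x 10 per group x 300 genes, 100 top genes), survival at 200-500 per
group, and KM median recovery averaged over a few replicates of n = 2000 so
the Monte Carlo error of the check stays well inside its tolerance band.
These sizes are the package's chosen desk-scale study conditions; effect
sizes, thresholds and rates are never reduced.

Degenerate inputs are resolved explicitly: genes numerically constant within
a fit report a null result (fold change 0, p = 1) instead of 0/0 artifacts;
ANOVA on all-equal observations returns missing; constant genes are dropped
(with a warning) before scaled PLS-DA; correlations on zero-variance vectors
are missing; survival pairs without events are reported missing. Welch's
t-test is the default for age contrasts (a pooled-variance option exists for
exact replication of classical Student results); Spearman is the default
correlation for age vs marker expression since no distributional form is
assumed.

## Known limitations

- Bulk TPM only; no single-cell mode, no counts mode.
- Ploidy is consumed as an annotation, never called from DNA.
- The generator's log-normal world has no heavy-tailed outliers, no
  mosaicism (partial loss within a sample), and no tissue-specific marker
  escape; threshold behavior near 1/10 TPM in real data should be assessed
  with the low-signal-tissue flags and the three-tier evidence fields.
- Consistent-profile overlap p-values depend strongly on the chosen universe;
  values computed under different universes are not comparable.
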