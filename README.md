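# scckit

Inference of the **functional sex chromosome complement (SCC)** of bulk
RNA-seq samples, and the analyses such calls enable.

Tumors can lose the transcriptional output of a sex chromosome — loss of
chromosome Y (LOY) in male patients, loss of an X (LOX) or loss of X
inactivation (XaXa) in female patients — with consequences for gene
expression and patient outcome. scckit classifies each sample's functional
complement from expression alone:

- **X side**: XIST marks an inactive X. Tiers: expressed (TPM ≥ 10),
  low (1–10), not expressed (≤ 1). X⁺ ⇔ XIST ≥ 10 TPM.
- **Y side**: an active Y requires ≥ 2 of the panel
  *DDX3Y, EIF1AY, KDM5D, RPS4Y1, USP9Y, ZFY, UTY* in the expressed tier.
- A fixed decision table over (X⁺, Y⁺, reported sex, X DNA ploidy) yields
  XaXi, XaXa, X0 (LOX/LOY), XY, plus explicit ambiguous/unexpected states
  (X0_ambiguous, XXY_like, XX_unexpected, XY_unexpected) rather than silent
  guesses.

Downstream, the package provides per-tissue differential expression on
log₂(TPM + c) with voom-style precision weights and empirical-Bayes moderated
t-statistics (t = b₁/(se·s̃), s̃² = (d₀s₀² + d·s²)/(d₀ + d)); cross-tissue
**consistent gene profiles** (same direction in all tissues, p < 0.05 in
≥ 60%); hypergeometric profile-overlap tests; per-gene ANOVA → top-gene
PLS-DA maps with an **X0 convergence ratio**
r = d(f-X0, m-X0)/d(f-XaXi, m-XY); and SCC-stratified Kaplan–Meier /
log-rank survival analysis. A fully seeded synthetic multi-tissue cohort
generator with planted truth makes every stage testable without downloads.

Intended users: computational biologists analysing bulk expression cohorts
(tumor atlases, tissue consortia, cell-line panels) who want SCC as a
first-class sample annotation.

## Worked example

```r
library(scckit); library(SummarizedExperiment)

sim   <- simulateCohort(simConfig(seed = 1))   # 6 tissues x 5 groups x 20
batch <- inferSCCBatch(sim$se)
head(as.data.frame(batch$calls)[, c("sample_id", "call", "xist_tpm",
                                    "n_y_expressed", "x_ploidy_used")], 4)
#>        sample_id call  xist_tpm n_y_expressed x_ploidy_used
#> S00001    S00001 XaXi  39.55284             0             2
#> S00002    S00002 XaXi 105.99239             0             2
#> S00003    S00003 XaXi  88.42221             0             2
#> S00004    S00004 XaXi  66.24593             0             2

mean(batch$calls$call ==
       sim$truth$scc$call[match(batch$calls$sample_id,
                                sim$truth$scc$sample_id)])
#> [1] 1          # every planted complement recovered

de   <- fitDEPerTissue(sim$se, batch$calls, "XaXi", "X0_LOX",
                       "female", "female")
prof <- buildConsistentProfile(de, contrast = "lox")
prof
#> ConsistentProfile 'lox': 172 up, 171 down across 6 tissue(s)
#> (same direction in all; p < 0.05 in >= 60% of tissues)
```

The call table gives, per sample, the call plus its full evidence (XIST TPM
and tier, number of expressed/low Y genes, ploidy used, flags); the profile
holds the genes moving consistently with loss of X across all six simulated
tissues. Survival stratification on a 200-per-group cohort:

```r
sv_sim <- simulateCohort(simConfig(seed = 201, n_tissues = 1,
                                   n_per_group = rep(200, 5), n_genes = 10,
                                   n_de = c(lox = 0, xaxa = 0, loy = 0,
                                            sex = 0), n_convergence = 0))
sv <- survivalBySCC(inferSCCBatch(sv_sim$se)$calls, colData(sv_sim$se))
sv$medians
#>         group   n events median_days
#>     female_X0 200    140    1832.131
#>   female_XaXa 200    145    4276.743
#>   female_XaXi 200    142    4202.728
#>       male_X0 200    137    1923.737
#>       male_XY 200    148    3063.206
```

Both X0 groups sit far below their typical counterparts (planted medians
1900 vs 4445/3200 days) and are statistically indistinguishable from each
other — the "equally poor" X0 state.

`runPipeline(config, out_dir)` chains simulate/load → infer-scc → DE →
consistency → group-structure → survival with a JSON manifest, parameter
echo, and digest-based resume. A thin CLI lives at
`inst/scripts/scckit.R`.

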