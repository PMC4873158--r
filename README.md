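# pathconcord

Cross-study concordance and co-expression network analysis for curated
signaling pathways in blood transcriptomes.

## The problem

Atherosclerosis, ischemic stroke and myocardial infarction share a
long-standing inflammatory substrate, so their peripheral-blood expression
profiles should show common immune dysregulation. `pathconcord` is for
analysts who have several independent expression cohorts (case/control, or
paired two-timepoint) plus curated gene sets — Toll-like, T-cell and B-cell
receptor signaling in the motivating application — and want to answer, with
self-contained permutation statistics:

1. Is each pathway **enriched** for differentially expressed genes within
   each cohort?
2. Are the per-gene changes **concordant** across cohorts?
3. Do the pathway genes form **co-expression sub-networks** whose hubs are
   also the most strongly changed genes?
4. Is a candidate **regulator** (e.g. DNMT1, a transcript-level proxy for
   DNA-methylation control) correlated with the pathways and itself
   dysregulated?

## The statistics

- Per-gene differential expression: Welch t (case − control, Satterthwaite
  df) or paired t on within-subject late − early differences.
- Pathway enrichment: observed count k of set genes with p < α versus a
  label-permutation null (sign flips of subject differences for paired
  designs); `perm_p = (1 + #{k_null ≥ k_obs}) / (B + 1)`.
- Concordance: Pearson r of per-gene t statistics between two studies over
  the set genes on both platforms, p from `t = r·√((n−2)/(1−r²))`.
- Networks: unsigned soft-threshold adjacency `a_ij = |cor(x_i, x_j)|^β`
  (β chosen by scale-free topology fit), topological overlap
  `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(K_i, K_j) + 1 − a_ij)`,
  connectivity `k_i = Σ_{j≠i} TOM_ij`; edges called as the top quantile of
  TOM values intersected with a permutation FDR (Benjamini–Hochberg on
  pooled-null empirical p-values); hub relevance as Pearson r between k_i
  and −log10 p_i.
- Regulator: Pearson r (shared kernel with the concordance module) between
  the regulator and every pathway gene, per-set sign summaries, and the
  regulator's own DE row.

A parameterized simulator (`new_synthetic_design()`) generates multi-cohort
data with planted directional effects, hub-structured within-set
correlation and a factor-coupled regulator, plus ground-truth tables, so
the whole pipeline is testable offline.

## Worked example

```r
library(pathconcord)

design <- new_synthetic_design(seed = 42)   # three cohorts, three pathways
sim <- simulate_cohorts(design)
sim$studies$atherosclerosis
#> ExpressionStudy 'atherosclerosis': 2000 features x 96 samples (unpaired design)
#>   case: 48, control: 48

de <- lapply(sim$studies, de_test)

enrichment_test(sim$studies$atherosclerosis, sim$sets, B = 1000, seed = 42)
#>   set   m  k        label      perm_p
#> 1 TLR 106 64 64/106 (60%) 0.000999001
#> 2 TCR 104 60 60/104 (58%) 0.000999001
#> 3 BCR  72 36  36/72 (50%) 0.000999001

concordance(de$atherosclerosis, de$stroke, sim$sets)
#>           study_a study_b set n_common         r            p
#> 1 atherosclerosis  stroke TLR      106 0.7664154 1.030406e-21
#> 2 atherosclerosis  stroke TCR      104 0.5570138 8.216467e-10
#> 3 atherosclerosis  stroke BCR       72 0.5877627 5.695228e-08

pg  <- unique(unlist(sim$sets$sets))
net <- tom_matrix(sim$studies$atherosclerosis, beta = 4, genes = pg)
cs  <- connectivity_significance(net, de$atherosclerosis)
sprintf("connectivity vs -log10(p): r = %.2f (p = %.2g)", cs$r, cs$p)
#> [1] "connectivity vs -log10(p): r = 0.78 (p = 2.6e-54)"

rd <- regulator_de(sim$studies$atherosclerosis, "DNMT1", de$atherosclerosis)
sprintf("DNMT1: t = %.2f, p = %.2g, %s", rd$t, rd$p, rd$direction)
#> [1] "DNMT1: t = -3.28, p = 0.0015, decreased"
regulator_correlations(sim$studies$atherosclerosis, sim$sets, "DNMT1")$set_summary
#>   set   n     mean_r fraction_positive
#> 1 BCR  72  0.3194576         1.0000000
#> 2 TCR 104  0.3019458         0.9903846
#> 3 TLR 106 -0.2904202         0.0000000
```

Reading the output: 50–60% of each pathway's mapped genes reach p < 0.05
with the enrichment permutation p at its floor (< 1/(B+1)); per-gene t
statistics correlate 0.56–0.77 between the two unpaired cohorts within each
pathway; network connectivity tracks significance (r = 0.78); and the
regulator is down-regulated while correlating negatively with the up-set
(TLR) and positively with the down-sets (TCR/BCR) — the planted structure,
recovered.

`run_all(config)` drives everything (DE, enrichment, networks, concordance,
regulator) for a list of studies and writes per-stage TSVs plus a combined
`report.json`; see `?run_all` and the vignette in `vignettes/`.

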