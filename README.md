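# ubiScreen

Pan-cancer proteomic analysis of E3 ubiquitin ligase and deubiquitinase
(DUB) regulation, and multi-omics screening for substrates under
**degradative ubiquitination** — the pattern in which an up-regulated E3
hyper-ubiquitinates a substrate and routes it to proteasomal degradation, so
the substrate's protein level falls while its mRNA does not.

The package is aimed at proteogenomics analysts working with paired
tumor/normal-adjacent-tissue (NAT) cohorts: log-ratio protein abundance
matrices, RNA count matrices, protein-corrected ubiquitination-site (diGly)
matrices, curated E3/DUB catalogs and E3–substrate interaction (ESI)
networks. A synthetic multi-omics cohort generator with planted ground truth
backs every stage, so the full pipeline is testable end to end without any
external downloads.

## What it computes

**Differential expression** (per cohort). After dropping proteins missing in
over 50% of samples and completing the rest with a three-method ensemble
imputation (feature-space kNN, row mean, iterative low-rank SVD), tumor vs
normal significance comes from the Wilcoxon signed-rank test on pair
differences (paired designs) or the rank-sum test (unpaired), with
Benjamini–Hochberg adjustment. RNA counts are median-of-ratios normalized
and tested with the same rank tests.

**Degradative-ubiquitination screen.** Every ESI edge (E, S) is evaluated
against three criteria:

- (a) S has an up-regulated ubiquitination site: log2FC > 0, q < 0.05;
- (b) E's protein is up-regulated: log2FC ≥ 0.5, q < 0.01;
- (c) S's protein drops (log2FC < 0, q < 0.01) without a significant mRNA
  drop, **or** S's protein is flat (q ≥ 0.01) while its mRNA rises
  (log2FC > 0, q < 0.01).

(a) ∧ (b) calls the pair *over-ubiquitinated*; adding (c) calls it
*degradative*, with the full evidence serialized per call.

**Regulatory atlas and sample clustering.** Signed per-column scaling of the
enzymes × cohorts log2FC matrix into [−1, 1], Ward (ward.D2) clustering,
hypergeometric over-representation of gene sets per cluster; per-cohort
Z-scoring, retention of enzymes expressed in all cohorts, PCA with JackStraw
component selection, and Louvain clustering on a shared-nearest-neighbor
graph.

**ESI correlation analysis.** Spearman correlations of E3–substrate pairs in
tumor vs normal samples against enzyme-matched random non-substrate
backgrounds, compared by the two-sample Kolmogorov–Smirnov test.

**Pathway impact analysis.** For each signed pathway topology, observed
per-gene changes ΔE propagate as PF = ΔE + B·PF (B the out-degree-normalized
signed influence matrix), giving net accumulations Acc = PF − ΔE and the
total accumulation tA = Σ Acc. The over-representation tail pNDE
(hypergeometric) and the bootstrap perturbation tail pPERT (two-tailed around
the null median of tA) combine by Fisher's product method,
pG = c − c·ln c with c = pNDE·pPERT; tA > 0 labels a pathway Activated,
otherwise Inhibited.

**Prognosis.** Univariate Cox proportional-hazards models (Efron ties),
maximally selected rank statistics for marker cutpoints (standardized
log-rank statistic maximized over candidate cutpoints, permutation p-value),
Kaplan–Meier/log-rank group comparison, biweight midcorrelation for robust
substrate co-expression, and between-group differential expression feeding
the pathway engine.

## Worked example

```r
library(ubiScreen)

spec <- cohortSpec(n_pairs = 40, n_proteins = 500, seed = 42)
sim  <- simulateCohort(spec)
sim$proteome
#> AbundanceExperiment: 500 features x 80 samples
#>   cohorts: SYN
#>   tumor: 40  normal: 40  paired: 40
#>   missing: 9.7%

proteome <- imputeAbundance(filterMissing(sim$proteome))
sites    <- imputeAbundance(filterMissing(sim$sites))
prot_de  <- testDifferential(proteome, paired = TRUE)
screen   <- runScreen(sim$esi, testSites(sites), prot_de, testRNA(sim$rna))
screen$summary
#>                 call n_pairs n_e3 n_substrates
#> 1 over_ubiquitinated      30   16           30
#> 2        degradative      30   16           30

subset(screen$calls, call == "degradative",
       c(e3, substrate, branch, e3_log2FC, prot_log2FC, rna_log2FC))[1:3, ]
#>        e3 substrate                     branch e3_log2FC prot_log2FC  rna_log2FC
#> 7  E3_002     P0122 protein_down_mrna_not_down  2.095195   -1.758853 -0.03348755
#> 10 E3_002     P0303 protein_down_mrna_not_down  2.095195   -2.087029 -0.15222298
#> 11 E3_003     P0024 protein_down_mrna_not_down  1.850489   -2.016092 -0.13484275
```

The generator planted 30 degradative pairs among 300 interactions; the
screen recovers all 30 (and only those), each showing the expected
signature: E3 protein up about 2 log2 units, substrate protein down, mRNA
flat. `selectSignificantE3(prot_de, sim$catalog)` returns the 18 planted
up-regulated E3s.

The whole synthetic pipeline — simulation, imputation, differential
expression, atlas, sample clustering, ESI correlations, screen, pathway
impact, survival — runs from one configuration:

```r
cfg <- pipelineConfig(out_dir = "run", seed = 1)
runPipeline(cfg)   # writes TSV tables plus manifest.json
```

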