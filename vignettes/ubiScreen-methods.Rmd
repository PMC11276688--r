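---
title: "Methods and design of the ubiScreen pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the ubiScreen pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubiScreen)
```

# Scope and data model

ubiScreen analyzes paired tumor/NAT multi-omics cohorts for the regulatory
footprint of the ubiquitin–proteasome system. Three molecular layers enter
the analysis, all features × samples:

- a **proteome** of log-ratio abundances (missing values allowed),
- an **RNA count** matrix,
- a **ubiquitination-site** matrix (`GENE_K123`-style ids), assumed already
  corrected for the parent protein's abundance, so a site's signal reflects
  ubiquitination stoichiometry rather than protein amount.

All three live in an `AbundanceExperiment`, a `SummarizedExperiment`
subclass whose column data carry cohort, tumor/normal condition and an
optional pair id linking a tumor sample to its NAT from the same subject.
Feature identity is symbol-keyed throughout; no identifier-mapping layer is
provided, so inputs must share a namespace before entering the pipeline.

# Missing data

Mass-spectrometry proteomics leaves a substantial fraction of cells
unobserved, preferentially at low abundance. Two stages handle this:

- `filterMissing()` removes features missing in *strictly more than* half
  of the samples (the threshold is a parameter; "over 50%" is the default
  and read literally, so a feature missing in exactly half survives);
- `imputeAbundance()` completes the rest with the elementwise mean of three
  imputations: kNN over feature profiles (Euclidean distance on shared
  observed samples, k = 10), the feature mean, and an iterative rank-5 SVD
  fit (50 iterations, convergence tolerance 1e-4 on the RMS change of
  imputed cells). The ensemble idea follows crowd-style imputation for
  proteomics; the three members are deliberately simple, dependency-free
  and individually testable. Observed cells are never altered — this is
  asserted elementwise in the tests — and a complete matrix passes through
  unchanged for every method.

Tumor and normal samples are imputed jointly per cohort. Whether to split
by condition is a genuinely open choice; joint imputation borrows strength
across the design and avoids two half-sized problems, at the cost of a mild
shrinkage of tumor–normal differences when missingness is severe.

# Differential expression

Per feature, paired designs use the Wilcoxon signed-rank test on
tumor-minus-normal differences over complete pairs (at least 3 required);
unpaired designs use the rank-sum test. p-values are two-sided and
BH-adjusted. The nonparametric choice matches heterogeneous, ratio-scale
proteomic cohorts where normality per feature is indefensible.

The log2 fold change is the difference of group means of the (already
log2-scale) abundances. An estimator had to be fixed and means were chosen
over medians: with the generator's Gaussian noise both are unbiased, and
means keep additivity with the planted effects.

Degenerate inputs follow explicit conventions: a feature with zero variance
in both groups (or identical values in all pairs) gets p = 1; a paired
feature with fewer than 3 complete pairs gets NA, which BH propagates.

RNA counts are normalized by median-of-ratios size factors (the median over
all-positive features of the count over the feature's geometric mean)
before the same rank tests; the RNA log2FC uses pseudo-counted normalized
group means, log2((mean_t + 0.5)/(mean_n + 0.5)). A negative-binomial GLM
would be the usual alternative; the rank-test route keeps the inferential
philosophy uniform across layers and is validated by power and type-I
oracles in the test suite. One property of median-of-ratios worth knowing:
when a large, one-sided fraction of features is truly changed, the
size-factor reference shifts and null features acquire a small
opposite-sign bias — the classic composition effect, shared with
count-based normalizers generally.

# The degradative-ubiquitination screen

The screen's thresholds (`screenThresholds()`) default to: site log2FC > 0
at q < 0.05; E3 log2FC ≥ 0.5 at q < 0.01; substrate protein and mRNA at
q < 0.01. Two deliberate subtleties:

- *Enzyme significance vs criterion (b).* The significance call for E3s
  (`selectSignificantE3`) uses |log2FC| strictly greater than 0.5, while
  screening criterion (b) admits log2FC exactly 0.5. Both rules are applied
  as stated for their respective steps rather than harmonized; a boundary
  E3 can therefore satisfy (b) without appearing in the significant list.
- *"Not significantly down" / "no significant change".* For the substrate's
  mRNA, "not significantly down-regulated" is the logical negation
  ¬(log2FC < 0 ∧ q < 0.01); for its protein, "no significant change" is
  q ≥ 0.01, with no fold-change condition.

Criterion (a) is satisfied by any single qualifying site, since a substrate
"has up-regulated ubiquitination sites" as soon as one exists; a minimum
site count can be imposed via the call table's evidence columns. Calls nest
by construction (degradative ⊆ over-ubiquitinated) and tighten
monotonically as any q threshold tightens; both properties are tested.
Pairs missing a layer are skipped with a per-layer reason code rather than
silently dropped.

# Atlas and sample clustering

The pan-cancer atlas scales each cohort's enzyme log2FC column into
[−1, 1] by dividing positives by the column's maximum positive and
negatives by the magnitude of the column's minimum. This preserves sign
structure and within-column ordering while making cohorts comparable; it is
invariant to positive rescaling of a column. Cells missing because an
enzyme was not quantified in a cohort are excluded from scaling and enter
the Ward (ward.D2, Euclidean) row clustering as 0 — the neutral point of
the scaled scale — because the clustering needs complete vectors while the
scaling must not be distorted by absent enzymes. The default of 3 row
clusters is a starting point, not an inference; the dendrogram heights are
returned for cut-height decisions.

Cross-cancer sample clustering first Z-scores each feature within each
cohort and condition (removing cohort batch offsets; a zero-SD feature is
set to 0 and logged), keeps catalog enzymes observed in every cohort, and
runs PCA. JackStraw selects components: each replicate permutes a small
fraction (default 1%) of features across samples, PCA is re-run, and the
permuted features' loadings pool into a per-component null; each observed
loading gets an empirical p against that null, and the component p-value is
a one-sided KS test of those feature p-values against uniform. Significant
components (p < 0.05) feed a shared-nearest-neighbor graph (k = 20
neighbors including self, Jaccard weights, pruned below 1/15) partitioned
by Louvain modularity at the chosen resolution (defaults 0.5 for normal and
0.6 for tumor samples, 0.8 when only DUBs are features). Louvain with
Jaccard-SNN mirrors the conventions of the popular single-cell toolchain;
no bit-compatibility with any external tool is claimed. Singleton
communities are merged into the nearest cluster by centroid distance and
logged.

# ESI correlations

Spearman correlations (average ranks on ties) are computed per E3–substrate
pair over one condition's samples, with pairwise-complete observations and
a minimum of 10 complete observations for a reported value — below that, or
against a constant profile, the pair is reported with a missing
correlation. The background draws, for each pair, one protein uniformly at
random excluding the E3 itself and all of its known substrates, preserving
the E3 multiset so the background is enzyme- and size-matched. One draw per
pair is the default; repeated draws only smooth the background and do not
change its location. Distributions are compared by the two-sample KS test
(asymptotic p); when several cohorts are tested, BH is applied across
cohorts by the caller.

# Pathway impact engine

The engine combines evidence that a pathway contains many changed proteins
with evidence that the changes propagate coherently through its topology:

- `buildInfluence()` encodes edges as beta[i, j] = ±1 for j → i and
  normalizes each column by the source's out-degree, splitting influence
  among targets.
- `netPerturbation()` solves PF = ΔE + B·PF directly as
  PF = (I − B)⁻¹ ΔE. If I − B has reciprocal condition number below 1e-12
  (tight feedback cycles), B is dampened to 0.99·B and the solve retried —
  a logged convention, equivalent to a slight leak in the propagation.
  Accumulation is Acc = PF − ΔE and tA = Σ Acc; negating all inputs negates
  tA exactly, and the solution matches fixed-point iteration to 1e-10 on
  acyclic graphs (tested).
- `pPert()` exploits the linearity tA = w·ΔE (w from column sums of
  (I − B)⁻¹) to bootstrap node assignments cheaply: the observed ΔE values
  are reassigned to random pathway nodes (default 2000 replicates), and
  pPERT is the two-tailed probability, centered at the null median, of a tA
  at least as extreme, with add-one smoothing so pPERT > 0 always.
- `combineFisher()` gives pG = c − c·ln c, c = pNDE·pPERT — the exact tail
  of the product of two independent uniforms, identical to the χ²₄ tail of
  −2 ln c (verified to 1e-9). A zero product is clamped to the machine
  minimum and logged.

Pathways with no DE member report pNDE = pPERT = 1, tA = 0. Edge semantics
are collapsed to activation/inhibition (±1); graded per-relation weights
are out of scope. The ΔE score is deliberately generic: fold changes for
group comparisons, signed biweight midcorrelations for substrate-mediated
association — any signed per-gene quantity propagates identically.

# Prognosis

Cox models are univariate on a continuous marker with Efron tie handling;
no clinical covariate adjustment is attempted. The maxstat cutpoint
computes log-rank (Savage) scores — event indicator minus the Nelson–Aalen
cumulative hazard at the subject's own time — and, for every candidate
cutpoint (observed marker values within the 10%–90% quantile window leaving
at least 5 samples per side), the standardized linear statistic of the
low-marker group under the permutation distribution. The cutpoint maximizes
the absolute standardized statistic, taking the smallest candidate on ties.
Because maximization inflates significance, the p-value permutes the marker
against the survival data and recomputes the maximum each time (default
1000 permutations, add-one smoothing) — exact-by-simulation rather than the
improved-Bonferroni approximation, which could be added behind the same
interface. Being rank-based, the selected *split* is invariant under
strictly monotone transformations of the marker.

Biweight midcorrelation uses Tukey weights around the median with the 9·MAD
cutoff (unscaled MAD); a zero MAD triggers a Pearson fallback with a
warning. Substrate association ranks all other proteins by |bicor| (ties
broken lexicographically) and truncates to the top 500 by default — large
enough to cover a pathway's neighborhood, small enough to keep the
over-representation tail meaningful.

# The synthetic cohort generator

`simulateCohort()` is the package's ground-truth instrument and its
defaults define the reference study conditions used by the tests: 80
tumor/NAT pairs, 800 proteins (60 E3s, 20 DUBs), 5 substrates per E3 (300
interactions, each substrate unique to its E3 so planted calls are
unambiguous), 30% of E3s planted up and 30% of DUBs down by 2 log2 units
against residual noise of 0.5, a tenth of interactions degradative, a
shared subject effect of 0.3 giving paired tests their power, and 10%
missingness. These sizes mirror a single mid-sized proteogenomic cohort
while keeping a full pipeline run in seconds.

Layer construction: the proteome is Gaussian on the log scale (baseline +
subject effect + planted shift + noise); RNA counts are negative binomial
(dispersion 0.1) with means tied to the protein baselines and following the
protein shifts, *except* degradative substrates, whose mRNA stays flat
while their protein drops — the defining decoupling. Sites (1–3 per
substrate, shifts applied to all of a substrate's sites) are generated
directly on the protein-corrected scale. Missingness is MCAR by default; an
intensity-dependent mechanism (logistic in abundance, calibrated by root
finding to the requested overall rate) is available.

Scenario generators cover the three structural findings the pipeline should
reproduce: `simulateTissueCohorts()` (cohort-specific normal baselines,
tumor profiles converging across cohorts — tumor samples then form no more
clusters than normal ones), `simulateRewiredESI()` (substrates track their
E3 in normal samples but decouple in tumor — tumor correlation
distributions concentrate near zero), and `simulateProtectiveCohort()` (a
protective marker suppressing one pathway's nodes with survival improving
in the marker — the Cox/maxstat/group-DE/pathway-impact chain should
rediscover that pathway as Inhibited).

What the generator does **not** emulate: mass-spectrometer peak-level
noise, TMT batch structure, correlated missingness across features,
identifier ambiguity, or biological pathway crosstalk. Passing tests
therefore demonstrate the statistical machinery's correctness and
calibration under its stated model, not robustness to every artifact of
real acquisitions.

# Reproducibility and problem sizes

Every stochastic routine takes an explicit seed and restores the caller's
RNG state; the pipeline derives all stage seeds from one master seed and
writes them to its manifest, and reruns are byte-identical. The test suite
runs at the reference conditions above, with replicated studies scaled to
keep the full suite in minutes on one CPU: 20 null cohorts for the
false-call study, 200 replicates for permutation-uniformity checks, 100
random instances per brute-force kernel comparison, 20 seeds for the
protective-marker workflow. These sizes were chosen as the smallest that
leave the acceptance margins comfortable rather than as statements about
asymptotics.

# Known limitations

- Symbol keying: no isoform or site-level protein inference; site ids must
  embed their parent symbol.
- The screen is a proxy: K48- vs K63-chain topology is not observable here,
  so "degradative" is an inference from the multi-omics pattern, not a
  measured linkage.
- The rank-test route for RNA forgoes the shrinkage and dispersion
  modeling of NB-GLM tools; at very small n it is conservative.
- Louvain modularity has a resolution limit; very small sample groups may
  merge at default resolutions.
- The JackStraw component p-value is a pragmatic KS-against-uniform
  summary; it is calibrated under the null (tested) but other summaries
  (e.g. proportion tests) are equally defensible.
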