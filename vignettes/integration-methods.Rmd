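---
title: "Methods: cross-layer integration, moderation, and subnetwork discovery"
author: "crossomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-layer integration, moderation, and subnetwork discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossomics)
```

This vignette is the package's own account of its statistical
machinery: the models, the defaults and why they were chosen, the
numerical conventions, and what the synthetic validation does and does
not demonstrate.

# Data model and preprocessing

A layer is an `OmicsDataset`, a `SummarizedExperiment` whose assay is a
feature-by-sample matrix of abundances (raw or log2; the object tracks
which), with feature metadata (`feature_id`, `gene_symbol`,
contaminant/decoy flags) and sample metadata (`group`, `replicate`,
`batch`, `plex`, free covariates). Zeros in imported matrices become
missing values by default — reporter-ion exports encode "not
quantified" as 0 — and this is switchable off for data where zero is a
real measurement.

Preprocessing follows the order flag-filter, missingness filter
(default: drop features missing in more than 30% of samples — a common
operating point for two-replicate multiplexed designs; fully
user-settable), log2 transform, normalization, optional imputation.

## The normalization menu and how a method is recommended

Six methods operate on the log2 matrix, all preserving missing cells in
place: `quantile` (columns receive row-rank means, so all columns share
one value multiset), `median` (columns shifted to the grand mean of
column medians), `medianMAD` (affine map to common median and common
raw MAD), cyclic `loess` (pairwise MA loess, span 0.7, 3 cycles — fixed
because the menu names the method, not its knobs, and these are the
conventional settings), `ztransform` (column-wise mean 0, sd 1), and
`irs` (internal reference scaling: per TMT plex, features rescaled by
the cross-plex mean of reference-sample intensities; geometric means on
the raw scale are arithmetic means on the log scale, which is how it is
computed).

`evaluateNormalizations()` scores each candidate with three pooled
within-group variation metrics and one separation metric:

* **PMAD** — per group with ≥ 2 replicates, mean over completely
  observed features of the raw median absolute deviation (no 1.4826
  consistency constant: the metric's name describes the raw MAD, and
  the constant would cancel in comparisons anyway);
* **PCV** — mean of sd/|mean| (sample sd, ddof 1 throughout the
  package);
* **PEV** — mean of the within-group variance;
* **average silhouette width** of the known groups, Euclidean, computed
  by default on the top-2 principal component scores of the
  complete-feature submatrix (group separation is judged after
  dimension reduction; a `space = "features"` flag uses the raw feature
  space instead). Samples in singleton groups score 0.

The recommended method minimizes the rank sum (ascending ranks on
PMAD/PCV/PEV, descending on silhouette); ties resolve to the first
method in the user's list. Missing values are excluded pairwise inside
every metric, never implicitly imputed.

## Local least squares imputation

`imputeLLS()` fills each missing cell by ordinary least squares (with
intercept) of the target feature on its k = 10 most correlated
neighbour features (absolute Pearson over complete pairs) that are
fully observed in the columns required for fitting and prediction.
Features with no eligible neighbour — including the degenerate case of
only constant neighbours, where correlation is undefined — fall back to
the row mean. Observed cells are never modified. On exactly rank-1 data
a single neighbour reconstructs masked cells to machine precision,
which the suite uses as the correctness oracle. Imputation is off by
default in the pipeline: the per-feature complete-case linear models
tolerate missingness directly, and imputing MAR plex-block dropout
mostly manufactures data.

# Per-layer modeling

`buildDesign()` produces treatment-coded (reference level = first
lexicographically unless specified) design matrices with an intercept;
numeric covariates are mean-centered so the intercept stays
interpretable. Rank deficiency is refused at construction with the
aliased coefficients named — catching, e.g., a factor confounded with
batch before any model is fit.

`fitLinearModel()` runs per-feature ordinary least squares on each
feature's observed samples (complete-case per feature, residual df
reduced accordingly), and `ebayesModerate()` shrinks the residual
variances toward a scaled inverse chi-square prior fitted across
features by moment matching on log s², yielding moderated t statistics
on d0 + d_g degrees of freedom. Both steps are delegated to limma,
whose estimator is exactly this moment-matching scheme; when the
variances show no excess spread d0 is infinite and the test reduces to
a normal test at the pooled variance. Features with zero residual df
keep missing t/p and are excluded from prior estimation. The robust
(winsorized) variant and consensus intra-block correlation are
deliberately out of scope: batch enters as a fixed covariate only.
Batch-corrected matrices (`correctBatchEffect()`) are produced for
visualization only — the modeling path keeps batch inside the design so
its variance is accounted for rather than removed beforehand.

# The integration statistic

`layerStats()` standardizes each layer's logFCs:
z = (logFC − μ)/σ with μ, σ the layer mean and sample sd, and assigns
the layer weight w = u/√N with N the number of features carrying a
finite logFC. Two readings of "N" were possible (features vs samples);
features was chosen because it is the only reading under which layers
of very different sizes (10⁴ proteins vs 2×10⁴ phosphosites) receive
the materially different weights the weighting is meant to provide.

`integrateLayers()` full-joins on gene symbol (case-sensitive, no fuzzy
matching) and computes per gene

S = Σ w·z / √(Σ w²)

summing over **all** contributing feature records: a gene with m
phosphosites in one layer contributes m terms to both sums. This
convention was chosen over collapsing because it is the one that keeps
S exactly unit-variance under the null for any multiplicity pattern;
an optional `collapse = TRUE` mode (max-|z| per gene per layer) exists
for users who prefer one-vote-per-layer semantics, and is off by
default. User multipliers enter numerator and denominator, so scaling
all layers by a common factor cancels and calibration survives any
weighting. p = 2Φ(−|S|), BH across all emitted genes; only measured
genes are emitted (annotation-only genes with no data have no
evidence to combine).

The closed forms used as exactness tests follow directly: one layer
and one feature per gene gives S = z; k identical layers give
S = √k·z; a gene observed in a single layer keeps its single-layer z.

# Enrichment

`ora()` is the one-sided hypergeometric upper tail of the
query/set overlap, both restricted to the measured universe (the
default universe is what was measured, not the genome — testing
against the genome inflates everything), set sizes bounded to
[3, 500], BH across sets. `gseaPreranked()` is the classic running-sum
statistic: stable ordering by (score desc, gene asc), hit increments
|score|^exponent normalized to sum 1 (exponent 1 default; 0 gives the
Kolmogorov–Smirnov form invariant under monotone score maps), uniform
miss decrements, ES = signed extremum. The null is gene-label
permutation (the only permutation scheme compatible with
integrated-score input, where no sample-level data exist), fixed seed,
add-one p values so no p is exactly zero, and NES = ES divided by the
mean |null ES| of the same sign. Defaults: 1000 permutations.

# Subnetwork discovery

Interaction edges are kept at confidence ≥ 0.7 (the conventional
high-confidence STRING cutoff; scores on the 0–1000 scale are detected
by max > 1 and divided by 1000), simplified to a loop-free simple graph
keeping the maximum confidence among duplicates. Edge cost is
c(e) = 1 − confidence clamped to [10⁻⁶, 1] — the minimal monotone
decreasing map from confidence to cost, floored so no edge is free.

Node prizes are |S| for genes significant at adjusted p < α (sign kept
as a node attribute for export — prizes must be non-negative), 0
otherwise; a hub penalty μ·deg(v) on the raw prize, floored at 0 and
using degree in the filtered base network, discourages high-degree
hubs. Defaults λ = 1, μ = 0; both are exposed everywhere.

**The optimization model.** The objective is
max Σ_{V′} p(v) − λ Σ_{E′} c(e). Taken over arbitrary forests with
freely chosen components this objective is degenerate — edges only ever
cost, so the all-singleton solution would always win and the algorithm
would never connect anything. The model implemented is therefore:
within each connected component of the base network the solution is a
single tree (possibly one node, possibly empty), and the forest arises
across components. Under this model connecting two prized neighbours
through an edge (or a zero-prize Steiner node) is exactly the
trade-off the objective prices, singleton prized nodes remain
admissible, and λ → ∞ degenerates to single best-prize nodes.
`bruteForcePCSF()` — the validation oracle, capped at 15 nodes —
enumerates connected induced subsets per component and scores each by
its minimum-spanning-tree cost, giving the exact optimum.

`solvePCSF()` is the production heuristic: grow from up to 3
highest-prize seeds per component along cheapest shortest paths to the
remaining terminals (accepting a path while the prizes collected
exceed the λ-scaled path cost), re-cost the selection with an MST,
then polish with deterministic single-node add/remove local search
(removals that disconnect are rejected; zero-prize leaves are always
removed because the saved edge cost is pure gain). The contract is:
never below the best singleton terminal, deterministic for fixed input
order, and within a factor 2 of the brute-force optimum on small
instances — in the validation sweep of 200 random ≤ 10-node instances
it attains the exact optimum throughout.

Modules come from greedy modularity maximization
(confidence-weighted fast-greedy agglomeration); because greedy
merging can strand a tiny component's nodes as singletons, the
per-component one-cluster partition replaces the greedy one when it
scores at least as well with fewer clusters. Hub scores average
min-max-normalized degree and betweenness within the solution; ties
break by prize, then name. This composite is a documented stand-in for
richer influence metrics whose parameters are not standardized.

# The synthetic-data generator

`generateMultiOmics()` emulates a two-condition multiplexed TMT study:

* log2 intensity = gene baseline N(20, 2²) + layer offset + group
  effect (differential genes only) + feature×plex batch offset
  N(0, 0.3²) + measurement noise N(0, 0.25²). The defaults mirror a
  36-sample TMT18-style design: 2 groups × 18 replicates balanced
  across 2 plex sessions; a proteome layer with one feature per gene
  and a phospho layer with 1–5 sites per gene; 10% differential genes;
  cross-layer sign concordance 0.9; contaminant rows (2%) appended with
  flags.
* Missingness is plex-block MAR: a feature is dropped from an entire
  plex with probability 0.1 — the characteristic dropout unit of
  multiplexed DDA acquisition, where a peptide not selected in one
  plex's runs is missing for all its channels.

What it does **not** emulate: intensity-dependent (MNAR) dropout
(available as a diagnosis target in real data but off here, since the
emulated regime is MAR), ratio compression, isotopic interference,
peptide-level roll-up, or correlated noise between a protein and its
phosphosites beyond the shared effect. Passing the validation suite
therefore demonstrates correctness of the statistics under the stated
generative model, not robustness to every artifact of real
acquisitions.

The power validation plants per-layer effects of 0.4× the noise sd
with full cross-layer concordance in 10% of 1200 genes — individually
sub-threshold for each layer's moderated test after BH, but jointly
detectable: the integrated test recovers strictly more planted genes
than either single layer in ≥ 15 of 20 simulation seeds (observed:
19–20 of 20). Problem sizes throughout the validation (10,000 null
genes × 20 seeds for calibration, 1200 genes × 36 samples × 2 layers ×
20 seeds for power, 200 random instances for the solver oracle, a
200-gene 2×3 fixture for the end-to-end run) were chosen to make each
check statistically decisive at interactive runtimes.

# Numerical conventions and degenerate inputs

* Sample standard deviation (ddof 1) everywhere; raw MAD without the
  consistency constant.
* BH is `stats::p.adjust`'s step-up with cumulative-minimum
  enforcement; missing p values pass through untouched.
* Ties: GSEA ranking is stabilized by gene id; gene-level rank metrics
  (`rankMetric()`: sign(logFC)·−log10 p) keep the largest-magnitude
  score per gene with |logFC| then feature id as tie-breaks;
  normalization recommendation ties resolve to list order; PCSF
  enumeration keeps the first optimum in deterministic subset order.
* Degenerate inputs fail loudly and early: all-flagged datasets,
  all-missing columns, zero-MAD columns under `medianMAD`, constant
  layers (σ = 0) in `layerStats()`, contrasts that are all zero or
  name no coefficient, aliased designs, prize maps with no in-network
  significant gene.
* All randomness (GSEA permutations, the generator, the pipeline) is
  seed-threaded through private RNG streams that restore global state.

# Known limitations

* Gene-symbol joins are exact strings; no orthology or alias
  resolution. An offline two-column mapping table is the supported
  harmonization path.
* Variance-stabilizing normalization and robust eBayes are not
  provided; duplicateCorrelation-style block correlation is not
  modeled.
* The PCSF heuristic is exact only empirically on small instances; on
  large dense networks it inherits the usual limitations of
  path-growth heuristics (no approximation proof beyond the singleton
  bound).
* FragPipe multi-site rows are preserved as given, one row per
  reported site record; no per-site collapsing is attempted.
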