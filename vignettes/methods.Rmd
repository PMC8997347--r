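---
title: "Inferring cell-shape signaling networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-shape signaling networks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapesig)
```

`shapesig` derives a phenotype-specific signaling network from two data
modalities: bulk expression profiles of cell lines and per-line morphology
features derived from imaging. This vignette documents the statistical
models behind each stage, the parameters that matter, and the design
decisions taken where the methodology admitted more than one reasonable
reading. It states no empirical claims beyond what the package's tests and
acceptance script themselves compute.

## Coexpression modules

The adjacency between genes $i$ and $j$ is the signed soft-thresholded
transform

$$a_{ij} = \left|\frac{1 + \mathrm{cor}(x_i, x_j)}{2}\right|^\beta,$$

computed on log2-transformed expression with $\beta = 9$ by default. The
signed reading is taken literally: strongly anticorrelated genes receive
adjacency near zero rather than being folded into the same module. Constant
genes (possible after filtering edge cases) are assigned correlation 0,
i.e. adjacency $(1/2)^\beta$, and noted in the log; the upstream filter
(`filter_genes`, coding genes with FPKM > 1 somewhere) normally removes
them first.

The unsigned topological overlap
$t_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$
converts shared-neighbor structure into a similarity; `1 - TOM` feeds
average-linkage hierarchical clustering.

**Static cut height.** Module extraction uses a static cut at a fraction of
the maximum merge height, followed by a minimum-size rule (30) and
iterative merging of modules whose eigengenes correlate above 0.85. The
default fraction is **0.9**. The choice comes from the structure of the
average-linkage dendrogram under the latent-factor model the generator
implements: coherent modules complete their merges well below ~0.75 of the
maximum height, while merges among independent background genes concentrate
in the top decile. A cut placed inside that top decile absorbs background
genes into real modules; 0.9 sits in the gap between the two regimes and is
insensitive to moderate changes (0.85–0.95 behave identically on the
default conditions).

**Eigengenes** are the first principal component of the gene-standardized
module submatrix, scaled to unit variance and oriented to correlate
non-negatively with the module's mean profile, so that "module up" always
means its members go up.

**Module–shape correlation.** Pearson correlations between eigengenes and
morphology features get Student asymptotic p-values
($t = r\sqrt{(n-2)/(1-r^2)}$). Multiplicity is handled by a rank-based
permutation procedure: shape rows are label-permuted $B = 1000$ times, the
full $|r|$ matrix is recomputed and sorted each time, and the observed
statistic of rank $k$ is compared to the permutation distribution of
rank-$k$ statistics, $p = (1 + \#\{\text{null}_k \ge \text{obs}_k\})/(B+1)$
with a Clopper–Pearson interval. Permutation is at the sample level (not
gene level), and absolute correlations are ranked; both choices were open
and are fixed here. A module–feature pair is called when $|r| > 0.5$ and
$p < 0.05$.

## Enrichment machinery

All over-representation tests are one-sided Fisher exact tests
(hypergeometric upper tail); odds ratios use a Haldane 0.5 correction only
when a cell of the table is zero. Regulon–module tests run separately for
activatory and inhibitory target sets, with unknown-sign targets joined to
both — the union reading of "used in both". The default test universe is
the set of genes surviving the expression filter; it is configurable
because annotation-restricted universes are equally defensible.

The TF→pathway combined score is $-\ln(p) \cdot z$, where $z$ measures how
far a pathway's p-value rank sits from its expected rank over `B_rank`
(default 200) random query sets of matched size. The exact z used by
popular enrichment web services is unpublished, so this explicit
rank-permutation definition is a documented stand-in.

The pathway-bias null repeats the whole TF-enrichment → pathway-enrichment
chain on 1000 random module sets matched for the observed size profile.
Chains in which no TF reaches the overlap threshold contribute p = 1 for
every pathway (a "failed test"), making the null conservative where TF
enrichment is rare. Empirical p-values use the +1 correction and are BH
adjusted.

Preranked GSEA uses the weighted Kolmogorov–Smirnov statistic (weight
exponent 1) with a gene-permutation null, $NES = ES / \mathrm{mean}(|ES_0|$
of the same sign$)$, and a two-sided p counting null scores at least as
extreme in absolute value.

## Clusters, differential expression, activities

Samples are clustered on z-scored shape-feature medians with k-means
($k = 3$, 50 restarts, best within-cluster SS). The differential-expression
test is a deliberately simplified negative-binomial Wald test standing in
for the off-the-shelf packages a full analysis would call: median-of-ratios
size factors, pooled method-of-moments dispersion floored at $10^{-8}$,
log2 fold change of normalized means with pseudo-count 0.5, delta-method
standard error, and a **t reference with residual degrees of freedom**
rather than a normal — the plug-in dispersion makes the statistic
heavier-tailed at the small group sizes this design uses (7 vs 7), and the
t reference restores type-I calibration (verified in the test-suite:
empirical rate on 2000 null genes within [0.03, 0.08], power at planted
log2FC = 1 above 0.8). Shrinkage, outlier removal by Cook's distance, and
independent filtering are intentionally not reproduced.

Regulon/module activity is a one-tailed signed rank-sum:
gene statistics become normal scores $z_i = \Phi^{-1}(r_i/(n+1))$ and
$NES = \sum_i m_i z_i / \sqrt{n_T}$ with mode $m_i = +1$ for activated and
unknown-sign targets, $-1$ for repressed. This reduces the multi-tail
enrichment machinery of dedicated activity tools to the part consumed
downstream (sign and magnitude ordering); it is standard normal under
random regulons (checked by simulation). Kendall's tie-corrected tau-b is
used for activity–activity correlation, after restricting to samples where
both activities are individually significant.

## Network assembly

Edge costs are the inverse source count $1/n_{\text{sources}}$, min–max
scaled to $[0,1]$, so the best-documented edge in the input is free and a
single-source edge costs 1. The alternative reading (scaling the count
itself) is available by constructing costs directly. Prizes are 100 for
every anchor node, tuned as $b \cdot p - \mu \cdot \mathrm{degree}$ with
$\mu = 0.005$ on the full prior network and floored at zero.

The prize-collecting Steiner forest is solved by a deterministic heuristic:
a virtual root joins every prize node at cost $w = 40$ (which therefore
controls forest fragmentation), candidate Steiner trees are built from (a)
the expansion of the metric-closure MST over terminals, (b) the union of
direct root-to-terminal shortest paths, (c) the MST of the augmented graph,
each is strongly pruned (subtrees whose collected prize cannot pay their
connection cost are dropped), and the best objective wins, followed by one
refinement pass on the surviving terminals. When the prior network is a
forest the solver switches to an exact dynamic program. On random small
instances the heuristic is verified against exhaustive enumeration (exact
on trees, within 10% elsewhere); the randomized variant perturbs costs by
±5% over 30 runs and returns the union of solutions.

Supernodes are wired by exactly the thresholds used elsewhere: TF→module
edges for in-network TFs with regulon-overlap p < 0.1; undirected
module–phenotype edges for $|r| > 0.5$ and p < 0.05; feedback edges of
weight exactly 1 from each module to its in-network members. Phenotype
nodes carry no prizes (they are added after solving, as the stage order
implies).

## Propagation

Information content of an ontology term is $-\ln$ of its annotation
frequency including descendants, over the annotated universe; gene–gene
similarity is Resnik best-match-average over the two annotation sets.
Similarities on protein–protein edges are min–max scaled to $[0,1]$, signed
by the prior interaction sign (weights in $[-1,1]$); supernode and feedback
edges keep weight 1. The unsigned scaled similarity is kept as the edge
capacity for flow analysis.

The random walk with restart uses restart probability $r = 0.95$ and
transition probabilities proportional to the **positive part** of the edge
weight (default): how a signed network should feed a non-negative walk is
genuinely underdetermined, so the absolute-value alternative is available
via `negative = "abs"`, and the default treats inhibitory edges as
non-conductive. Dangling nodes restart fully. The iteration is run to an L1
tolerance of $10^{-10}$ and matches the closed-form linear solve.

Seed significance randomizes seed locations uniformly over **all** network
nodes (supernodes included), preserving the seed masses, 10000 times;
$p = (1 + \#\{\text{rand} \ge \text{obs}\})/(n_{\text{rand}}+1)$ with
$\ge$ chosen conservatively. A consequence worth knowing: a node's
attainable p is bounded by the probability that the randomization seeds the
node itself, so hubs adjacent to most of the network can never reach the
counting floor of $1/(n_{\text{rand}}+1)$ — the calibration tests account
for this.

## Drug influence and flow

Kinase-inhibitor profiles keep binding-class-1 targets only and drop drugs
with more than five such targets. The influence score multiplies the summed
PageRank (damping 0.85, undirected $|w|$ view — the algorithm's standard
parameters, which the methodology names but does not fix) of in-network
targets by the Szymkiewicz–Simpson overlap $|K \cap N| / \min(|K|,|N|)$;
the factored form and the per-term form of this product are algebraically
identical. Per-drug morphological effect is summarized as the mean absolute
log10 fold change per feature before Spearman correlation. Max flow runs on
the directed view with semantic-similarity capacities; the undirected view
is a flag.

## The synthetic study conditions

The generator is first-class code and defines the conditions under which
everything is tested:

* **Expression**: 3 planted modules of 40 genes plus 120 background genes
  over 100 samples. Each module is one latent factor; a member gene is
  $\sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$ on the log2 scale with
  $\rho = 0.8$, giving exactly controllable within-module correlation (a
  latent-factor model rather than copula sampling — the simplest
  construction with that property). Shape features are linear combinations
  of the factors calibrated to targets (0.8, −0.8, 0.7), the rest pure
  noise; 10% of background genes sit below the FPKM filter.
* **Counts**: NB with mean 100 and dispersion 0.05, library-size factors in
  [0.7, 1.3], 10% planted differential genes at log2FC 1.
* **Prior network**: 300 nodes grown by out-degree preferential attachment
  (2 edges per node), 70% activating edges, citation counts geometric
  truncated at 25 — the citation skew of real curated interactomes. Nodes
  reuse measured gene names plus unmeasured signaling proteins.
* **Regulons**: 20 TFs of 15 targets; half are planted inside modules as
  enrichment positive controls; 20% of targets have unknown sign.
* **Drug screen**: 40 drugs, 1–5 class-1 targets each, alternating between
  in-network and external kinase pools; per-cell log10 effects have mean
  `slope × influence / max influence` on the first five features (random
  sign per drug) and zero elsewhere, with per-cell noise SD 0.2 around the
  per-line value; 15 cells per drug plus controls. Per-cell shape
  expansions for ANOVA draw Gaussian cells around line medians (SD 0.5) —
  the per-cell noise structure of real imaging data is not specified by the
  source methodology, and this Gaussian assumption is the one deliberate
  simplification.

What passing tests on these conditions do **not** show: robustness to
heavy-tailed or batch-confounded expression noise, to correlated background
genes, to annotation bias in real ontologies, or to the off-target spectra
of real inhibitors. The generator makes planted structure recoverable by
construction; the tests verify the machinery, not biology.

## Problem sizes and numerical choices

The test-suite and the acceptance script run the pipeline at the default
conditions above; Monte-Carlo depths inside the test-suite are scaled to
what the properties need (1000 permutations where calibration is asserted,
100–500 where only determinism or ordering is asserted; these sizes are
stated in the tests themselves). Convergence tolerances: RWR L1
$10^{-10}$; TOM oracle agreement $10^{-12}$; PageRank oracle agreement
$10^{-10}$. Tie-breaking: strong pruning drops a subtree whose worth
exactly equals its connection cost (prefer smaller networks); quantiles use
linear interpolation with ties at the flow threshold included. Degenerate
inputs: empty prize sets return empty solutions; modules below minimum size
go to an explicit unassigned pool; zero-control-mean features are masked
per batch rather than producing infinities.

## Known limitations

* The DE stand-in handles the 1-vs-rest design only through pooled
  dispersion; single-sample contrasts inherit its anticonservatism.
* The PCSF heuristic guarantees optimality only on forest priors; on dense
  graphs it is validated empirically, not by bound.
* Resnik similarity is quadratic in annotation-set sizes per edge; for
  ontologies with thousands of terms per gene a precomputed MICA table
  would be needed.
* The rank-based permutation correction controls rank-wise error, not FWER
  or FDR in the usual sense; its calibration is verified empirically under
  the generator's null.
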