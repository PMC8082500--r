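---
title: "From multi-tissue expression to regulatory triads: models and choices"
author: "triadnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multi-tissue expression to regulatory triads: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadnet)
```

`triadnet` chains four analyses that are usually run as separate tools:
weighted co-expression network analysis, expression-pattern and
tissue-specificity profiling, mixed regulatory-network assembly, and
three-node motif statistics with composite importance scoring. This
vignette explains the models behind each stage, the parameters that
matter, the numerical conventions, and what the synthetic-data tests do —
and do not — establish about behaviour on real data.

## The co-expression model

The network stage assumes that expression of functionally related genes is
driven by shared latent factors, so pairwise Pearson correlation is a
meaningful similarity. The unsigned adjacency

$$a_{ij} = \lvert \mathrm{cor}(x_i, x_j) \rvert^{\beta}$$

soft-thresholds correlations: raising to the power $\beta$ (integer
$\ge 1$) shrinks weak correlations toward zero without a hard cutoff.
$\beta$ is chosen by `pick_soft_threshold()` as the smallest power at which
the connectivity distribution approximates a scale-free law, measured by
the signed fit index: connectivities are binned (10 equal-width bins) and
$\log_{10}$(frequency) is regressed on $\log_{10}$(mean connectivity);
the $R^2$ is signed by the negated slope so only decreasing relationships
count. The selection goal defaults to $R^2 \ge 0.85$. On dense simulated
modules a moderate $\beta$ (the pipeline default is 6, the conventional
unsigned-network choice) is sufficient; on real multi-tissue data the
selected power is typically much higher (around 20), which the grid
accommodates.

Direct correlation is noisy, so module detection clusters on the
**topological overlap**

$$\omega_{ij} = \frac{\ell_{ij} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad
\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},$$

which asks whether two genes share *neighbourhoods* rather than merely
correlate. Modules are branches of an average-linkage tree on
$1-\omega$.

### The static cut and its height

`detect_modules()` cuts the tree at a fixed fraction of its height range
(default `cut_height = 0.95`) and discards branches below `min_size`
(default 30) as `"unassigned"` — a deliberate simplification of dynamic
branch cutting, which needs shape parameters the analysis does not
otherwise constrain. The height fraction matters: on 36-sample unsigned
networks the background genes' merges crowd the top few percent of the
height range, so a cut at 0.99 absorbs unrelated genes into real branches,
while 0.95 leaves genuine modules intact and background unassigned. This
was verified on the generator's planted modules across seeds; 0.95 is the
package default, and the parameter is exposed for data with different
height profiles.

Modules whose eigengenes (first principal components of the
gene-standardized module submatrix; unit norm, sign-aligned to the module
mean so "up" means up) correlate above 0.9 are merged iteratively, highest
correlation first; each merge strictly reduces the module count, so the
procedure terminates.

### Key modules, GS and hubs

Gene significance (GS) is the absolute Pearson correlation between a
gene's expression and the binary indicator of a tissue, computed within
one condition (18 samples in the default design). Encoding the trait as a
0/1 indicator is a convention — the methods these thresholds descend from
never specify the trait encoding — and a signed variant is available. A
module is key for a tissue when its eigengene-indicator correlation
p-value (two-sided Student t, $n-2$ df; no distributional machinery
beyond that is warranted at these sample sizes) beats
$\alpha/(\text{modules} \times \text{tissues})$ *and* median GS exceeds
0.8. With 21 modules and 6 tissues this threshold is
$0.05/126 = 3.97\times10^{-4}$. Hub calls use the three inclusive
criteria GS $\ge 0.8$, MM $\ge 0.95$, kWithin rank
$\le \lceil 0.2\,n \rceil$ (ties by kWithin then gene id). Topology
concepts (density, mean cluster coefficient, centralization,
heterogeneity) use the weighted formulas with the diagonal excluded and
*population* variance in the heterogeneity — the standard conventions for
weighted-network concepts.

## Tissue specificity and expression patterns

$\tau = \sum_i (1 - x_i/x_{\max})/(N-1)$ is computed on per-tissue
replicate means within one condition (means, not per-sample values, is
the standard convention for $\tau$ and is what the generator's planted TS
genes are designed against; a per-sample variant would only add replicate
noise). $\tau$ is scale-invariant and monotone in the dominant tissue;
all-zero genes have no defined $\tau$ and are excluded with a warning
rather than imputed. TS calls use the strict $\tau > 0.9$.

Fuzzy c-means runs on per-gene standardized profiles (mean 0, sd 1 across
tissues) because pattern clustering should compare shapes, not levels.
Defaults: 8 clusters (the operating point for lung-module multi-tissue
patterns), fuzzifier $m = 2$ — the software this stage emulates estimates
$m$ from data, but its estimator is undocumented, so a fixed documented
default with a parameter is preferable. Initialization picks random
distinct genes as centroids under a fixed seed. The objective
$\sum u^m d^2$ is recorded every iteration and is non-increasing (a
property the test suite asserts on every run); convergence is declared
when the largest centroid shift drops below `tol`. A gene coincident with
a centroid takes membership 1 there (the $d \to 0$ limit). As
$m \to 1^+$ memberships harden toward k-means, which the tests verify.

## Regulatory-network assembly

PWM scanning scores every window on both strands by the log-odds sum
against a uniform background, after adding a pseudocount of 0.01 to the
normalized column probabilities (scan behaviour upstream of this choice is
unreconstructible from the published settings, so it is a documented,
configurable default). The **relScore** rescales the score between the
PWM's attainable extremes, so the consensus scores exactly 1 and the
anti-consensus exactly 0; hits require relScore $\ge 0.85$. Windows
containing N are skipped; hits are strand-symmetric under reverse
complementation, and relScore is invariant to rescaling the count matrix
— both are tested properties. miRNA target records pass at total score
$\ge 140$ and energy $\le -20$ kcal/mol, both inclusive; the alignment
itself is out of scope, only its output filter is implemented.

The mixed network keeps regulation arcs (typed TF/miRNA, one per ordered
pair, best relScore retained) and undirected co-expression edges
($a_{ij} \ge$ `coexpr_cutoff`, default 0.1). Which co-expressed pairs
enter the network is a reporting convention with no published rule; edge
counts are sensitive to the cutoff, so it is exposed prominently and
recorded in the pipeline manifest. Arcs whose endpoints fall outside the
module-gene/TF/miRNA universe are dropped with a warning — detected
module assignments legitimately lose an occasional planted target.

## Triad census, null model and significance

A directed-triad census needs a fully directed graph, so `directify()`
expands each co-expression edge into a mutual arc pair; when a pair
carries both a regulation arc and a co-expression edge, the default lets
the co-expression edge complete a mutual dyad (the alternative,
`collapse = "keep_arc"`, keeps only the directed arc). The 13 weakly
connected 3-node classes are indexed in the standard
significance-profile order with the anchored identities FFL = 7,
Regulated mutual = 9, Regulating mutual = 10, Clique = 13; the canonical
representatives are published by `triad_classes()` and verified
non-isomorphic by exhaustive enumeration when the lookup table is built.
The census enumerates candidate triples from each node's neighbour pairs
(every weakly connected triple has a centre node adjacent to both
others), deduplicates, and classifies by a 6-bit code lookup; it equals
the exhaustive all-triples count, which the tests assert against both a
brute-force oracle and an independent library census.

The null model preserves each node's in-degree, out-degree and
mutual-dyad count exactly: single arcs switch only with single arcs,
mutual dyads only with mutual dyads (as units), and proposals creating
self-arcs, duplicates or single/mutual conversions are rejected. The
burn-in is 100 attempted switches per switchable unit by default. One
caveat worth knowing: on degenerate graphs where *every* proposal
succeeds (e.g. disjoint arcs), the attempt count fixes the permutation
parity of the outcome; real networks reject proposals and mix on their
own. Whether the original analysis also conserved node roles (TF vs
non-TF) in its nulls is unstated; these nulls conserve degrees only.

Per class, $Z = (N_\text{real} - \bar N_\text{null})/s_\text{null}$
(sample sd; zero-sd classes get $Z = 0$ and a `degenerate` flag), and the
significance profile $SP = Z/\lVert Z\rVert_2$ has unit Euclidean norm
whenever any $Z \ne 0$. Empirical p-values are reported raw (resolution
$1/n_\text{random}$, so 10,000 networks support statements like
$p < 10^{-4}$) alongside add-one-corrected variants.

## Importance scores

The published description of the node and motif scores lists their
components but not the functional form (it lives in unavailable
supplementary formulas), so the package implements a documented
reconstruction and labels it as such:

$$S_\text{node} = w_C \hat C + w_D \hat D + w_\tau \tau + w_{TF}
\mathbf{1}_{TF},$$

with equal default weights (normalized to sum to 1), $\hat C$ the
min–max-normalized mixed-network degree (regulation arcs in + out plus
co-expression edges, each once), $\hat D$ the min–max-normalized
$|\log_2((m_1+\varepsilon)/(m_2+\varepsilon))|$ of focal-tissue replicate
means between conditions ($\varepsilon = 1$), and $\tau$ from the
profiling stage. miRNA nodes have no expression profile; their $\hat D$
and $\tau$ are set to 0 rather than dropping the nodes. Degenerate
components (min = max) become 0 for all nodes with a warning. Edge scores
are the adjacency of the endpoint pair (co-expression edges carry it
directly; "the weight from the co-expression network" is read as
adjacency, with TOM available upstream for callers who prefer it); miRNA
arcs take a fixed documented 0.5. Motif scores mix
$\alpha \cdot \text{mean}(S_\text{node}) + (1-\alpha) \cdot
\text{mean}(S_\text{edge})$ over an instance's typed edges
($\alpha = 0.5$). Reproducing any published table of score *values* is
explicitly not a goal — only the scoring pipeline and its rankings are.

`extract_top_complex()` takes the best class-10 instance (ties broken by
sorted node ids), then groups every size-3 instance sharing at least two
of its nodes by co-regulated target.

## The synthetic study and what the tests show

`sim_config()` defaults encode the emulated study design: 2 conditions ×
6 tissues × 3 replicates (36 samples), 500 genes. Four latent-factor
modules (60/50/45/50 genes; muscle, spleen, kidney, lung) are generated
as `baseline + loading × factor + noise`, the factor being a per-tissue
base level (sd 0.5) elevated by 5 units in the target tissue plus
per-sample jitter (sd 0.5); the gene noise sd is set from the factor
variance so the expected within-module correlation is `cor_level` (0.9) —
exactly the correlation structure the module detector assumes. 24
strictly TS genes (level 50, noise sd 3) are planted in the tissues that
carry no module, keeping "individually tissue-specific" and
"module-co-expressed" as distinct planted signals. Eight TFs are elevated
in lung with condition-dependent level (12 vs 4) plus an individual
secondary tissue and broad noise (sd 16 on baseline 15); these constants
were chosen so that (a) every signal gene outranks the background in the
MAD filter (the zero floor otherwise collapses the MAD of low-baseline
noisy genes), and (b) TF–TF and TF–module-gene correlations stay below
the co-expression cutoff at the default $\beta$, so planted triads keep
their classes in the assembled network. The regulatory truth plants the
class-10 complex (mutual `tf1`–`tf2` pair sharing the TF target `tf3`
and six module genes), FFLs through `tf3` and `tf4`, a class-9 instance
whose mutual pair is co-expression-borne, a three-TF clique, and miRNA
arcs; the complex pair is the *only* mutually connected regulator pair
with shared targets, so class-10 instances in the network are exactly the
planted ones.

Passing tests therefore establish: the filter, network, module, key/hub,
$\tau$, clustering, census, null-model and scoring machinery all do what
their formulas say, and the whole chain recovers planted structure
(module ARI $\ge 0.8$, exact key-module calls, every planted triad at its
class, the planted complex as top) under a correlation structure the
model family matches. They do **not** establish performance under
count-distribution realism (no negative-binomial marginals or
library-size effects), batch structure, unbalanced designs, or modules
that violate the single-latent-factor assumption — on real data the
module detector and $\beta$ selection need the usual diagnostics
(`autoplot()` of the soft-threshold report, the dendrogram, eigengene
heatmaps).

## Problem sizes and determinism

Default analysis sizes are desk-scale by design: 500 genes, 36 samples,
null ensembles of a few hundred networks for exploration (the full-size
operating point of 10,000 random networks is a parameter away). All
stochastic steps — the generator, centroid initialization, switching
randomization — take explicit seeds, and `run_pipeline()` records every
parameter and seed in a JSON manifest next to its outputs; identical
configurations reproduce identical artifacts byte for byte.

## Known limitations

* The static branch cut replaces dynamic tree cutting; deeply nested or
  very unequal-height module structures may need the full algorithm.
* Promoter definition is input data — the package never extracts promoter
  windows from a genome.
* The importance-score composite is a reconstruction; rankings are
  comparable within a run, not against published score tables.
* Empirical motif p-values cannot be smaller than
  $1/n_\text{random}$; claims below that resolution need larger
  ensembles.
* The miRNA side trusts upstream target predictions; only the score and
  energy filter is applied.
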