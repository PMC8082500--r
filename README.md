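# triadnet

Multi-tissue co-expression networks, regulatory triad motifs and gene
importance scoring in R.

`triadnet` is for transcriptome analysts who have gene expression across
several tissues in two conditions (e.g. two populations or breeds) and want
to go beyond per-gene differential expression: which gene *modules* track
which tissue, which genes are hubs, which transcription-factor/miRNA
circuits regulate them, which three-node wiring patterns (motifs) are
over-represented, and which regulatory "complex" matters most.

## The methods in brief

**Weighted co-expression networks.** Genes are filtered by median absolute
deviation (top 50% by default), then connected with the soft-thresholded
unsigned adjacency *a<sub>ij</sub>* = |cor(x<sub>i</sub>, x<sub>j</sub>)|<sup>β</sup>,
with β chosen so the connectivity distribution approximates a scale-free
law (signed fit R² ≥ 0.85). Modules are branches of an average-linkage tree
on the topological-overlap dissimilarity 1 − TOM, merged when module
eigengenes (first principal components) correlate above 0.9. A module is
**key** for a tissue when its eigengene–tissue correlation beats the
Bonferroni threshold α/(modules × tissues) *and* the module's median gene
significance (GS, |cor| with the tissue indicator) exceeds 0.8. **Hub
genes** satisfy GS ≥ 0.8, module membership ≥ 0.95 and top-20%
intramodular connectivity. Per-module topology is summarized by density,
mean cluster coefficient, centralization and heterogeneity.

**Expression patterns and tissue specificity.** Multi-tissue profiles are
soft-clustered by fuzzy c-means (default 8 clusters, fuzzifier 2), and the
tissue-specificity index τ = Σ(1 − x<sub>i</sub>/x<sub>max</sub>)/(N − 1)
grades each gene from 0 (housekeeping) to 1 (strictly tissue-specific;
τ > 0.9 calls a TS gene).

**Mixed regulatory networks.** TF→target arcs come from PWM promoter scans
at relScore ≥ 0.85 (min–max-normalized log-odds), miRNA→target arcs from
miRanda-style records filtered at total score ≥ 140 and energy ≤ −20
kcal/mol, and undirected co-expression edges from the adjacency at a
cutoff. For motif analysis each co-expression edge becomes a mutual arc
pair.

**Triad census and significance.** All weakly connected three-node
subgraphs fall into 13 isomorphism classes (FFL = class 7, Regulated
mutual = 9, Regulating mutual = 10, Clique = 13). Counts are compared with
a null ensemble of degree-preserving switch-randomized networks
(in/out/mutual degrees conserved exactly); per-class Z scores are
normalized to the unit-length **triad significance profile (TSP)**, with
empirical over/under-representation p-values.

**Importance scores.** Each node scores
S<sub>node</sub> = ¼(Ĉ + D̂ + τ + 1<sub>TF</sub>) — normalized
connectivity, normalized |log2 fold change| between conditions in the
focal tissue, tissue specificity, TF status (weights configurable). Edges
score their co-expression weight; a size-3 instance scores
α·mean(S<sub>node</sub>) + (1−α)·mean(S<sub>edge</sub>). The top
regulating-mutual instance and the targets its regulator pair jointly
controls form the reported complex. A validation module replicates
candidate co-expression edges in independent datasets (confirmed when
p < 0.05 with positive r) and reports the replication rate.

All of this is testable end to end without external data: the
`simulate_*()` generators plant modules, TS genes, TFs, miRNAs and triad
instances with known ground truth.

## Worked example

One command simulates a 500-gene, 2-condition × 6-tissue × 3-replicate
study with planted structure and runs the full pipeline:

```r
library(triadnet)
res <- demo_pipeline(outdir = "demo", seed = 1, n_random = 50)

res$key_modules[res$key_modules$is_key,
                c("module", "tissue", "r", "p", "median_gs")]
#>   module tissue     r        p median_gs
#> 1     M1 muscle 0.929 2.71e-08     0.887
#> 2     M2   lung 0.966 7.64e-11     0.929
#> 3     M3 spleen 0.969 3.77e-11     0.920
#> 4     M4 kidney 0.931 2.13e-08     0.880
```

Each detected module is key for exactly the tissue it was planted to
track: the eigengene–tissue correlations (~0.93–0.97) crush the Bonferroni
threshold 0.05/(4 × 6) ≈ 2.1e-3 and every median GS clears 0.8.

```r
res$network
#> <mixed_network> 217 nodes (8 TF, 4 miRNA, 44 hub), 5254 edges
#>                 (44 regulation, 5210 co-expression)

res$significance[res$significance$count > 0,
                 c("class_id", "name", "count", "z", "p_over")]
#>   class_id name              count      z p_over
#> 1        1 V-out                14 -16.2    1
#> 2        2 3-chain              24  -1.09   0.88
#> ...
#> 7        9 Regulated mutual    122  16.6    0
#> 8       10 Regulating mutual     7   0      0
#> 9       13 Clique            87611 623.     0
```

Regulated-mutual motifs (a TF driving a co-expressed gene pair) and
cliques (co-expression triangles) are strongly over-represented relative
to the degree-preserving null, exactly what the planted regulation atop
dense modules should produce.

```r
res$scores$complex
#> <complex_report> core: tf1-tf2 -> tf3 (S_motif = 0.2511)
#>   11 member instance(s), 6 co-regulated target(s)
res$scores$complex$targets
#>   target n_motifs
#> 1 g0156         3
#> 2 g0157         3
#> 3 g0158         1
#> ...
```

The extracted top complex is the planted one — a mutually regulating TF
pair (`tf1`, `tf2`) sharing the TF target `tf3` — together with the six
module genes the pair co-regulates, each listed with the number of size-3
instances it closes.

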