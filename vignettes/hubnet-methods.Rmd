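---
title: "Methods: from multi-study expression to network hub genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multi-study expression to network hub genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubnet)
```

## The problem

Individual microarray cohorts of a tumor type routinely disagree about which
genes are differentially expressed: sample sizes are modest, platforms differ,
and study-level batch effects shift every measurement. `hubnet` implements a
multi-stage strategy for nominating robust candidate genes from several such
cohorts at once: a rank-based meta-analysis that never mixes raw intensities
across studies, a protein-interaction context that promotes genes sitting
amid the expression changes, and two independent concordance checks (the
"validated rate" on held-out cohorts, and immunoreactivity scores at the
protein level).

## Rank-product meta-analysis with permutation pfp

Within each study, genes are ranked by linear fold change
$FC_g = 2^{\overline{\log_2 x}_{tumor} - \overline{\log_2 x}_{control}}$
(rank 1 = most extreme in the requested direction, average ranks on ties).
Because only ranks leave a study, additive study-level batch offsets — which
shift tumor and control samples equally — cancel in $FC$ and never cross
study boundaries. For a gene measured in $k \ge 2$ studies of a platform
group, the rank product is the geometric mean $RP_g = (\prod_i r_{gi})^{1/k}$;
genes measured in fewer than two studies are reported but unranked, which is
how partially overlapping platform panels are accommodated (each study ranks
only the genes it measured, and each gene is judged on its own $k$).

Significance is attached by permutation: each study's rank vector is permuted
independently `n_perm` times, null rank products are recomputed, and for a
gene with observed $RP = r$ at position $x$ of the observed ranking,

$$\mathrm{pfp}(g) = \frac{\#\{\text{null } RP \le r\}}{n_{perm} \cdot x},$$

the estimated proportion of false predictions (an FDR-type quantity) among
all genes called at least as extreme. The estimate is then made monotone
non-decreasing down the observed ranking (running maximum) and capped at 1.

Two numerical choices matter here. Rank products of small integer ranks form
a discrete set, so observed and null values tie exactly in theory but can
differ by one ulp in floating point; counts therefore use a $10^{-9}$
relative tolerance on the $\le$ comparison. Tie positions $x$ use
`ties.method = "max"`, the conservative choice. Both choices are exercised by
a test that compares the sampled estimator against exhaustive enumeration of
all 36 joint permutations of a 3-gene, 2-study instance.

A gene is a DEG when $\mathrm{pfp} < $ `fdr_thresh` *and* its group fold
change clears `fc_thresh` (inclusive, so $FC = 2.0$ qualifies); down-calls
use $FC \le 1/\texttt{fc\_thresh}$. The default `fdr_thresh = 0.01` follows
the stricter of the two conventions in circulation for this design
(0.05 is equally accessible as an argument — both appear in practice). The
group fold change is the geometric mean of per-study fold changes, the
mean consistent with log-scale ranking; per-study values are always reported
alongside. The two platform groups are analyzed separately and intersected:
a gene survives only when called in both groups with the same direction.

**Power depends on the DE fraction, not only the effect size.** Under the
permutation null the expected pfp at observed position $x$ in a $G$-gene
panel grows like $G \cdot P(RP_{null} \le x)/x \approx c\,x^2/G^2$ (for
$k = 3$), so the *fraction* of genes carrying signal bounds the achievable
pfp of the weakest of them. The recovery checks in this package therefore
plant 2% of a 1000-gene panel (10 up + 10 down), matching the concordant-DEG
fraction seen in real multi-cohort tumor analyses (on the order of one to
two hundred genes of a genome-wide panel); with log2 effect 1.5, residual SD
0.7 and 20 tumor / 10 control samples per study this leaves a comfortable
margin below the 0.01 threshold.

## Interaction background and Steiner subnetwork

Edge lists from any number of interaction databases are unioned into one
simple undirected graph ((A,B) ≡ (B,A), self-loops dropped, multiplicity
kept as `source_count`); no confidence weights are parsed, so all edges are
unit cost. DEGs are mapped onto this background (unmapped symbols are
reported, never silently dropped; symbol canonicalization is uppercase +
whitespace only — aliases such as BGH3/TGFBI are deliberately not rewritten,
because alias maps are version-dependent).

The mapped DEGs (terminals) are connected by the Kou–Markowsky–Berman
2-approximation of the Steiner minimal tree, per terminal-connected
component: metric closure over the terminals, minimum spanning tree of the
closure, expansion of closure edges into shortest paths, spanning tree of
the expansion, and pruning of non-terminal leaves. Every BFS and MST step
breaks ties by lexicographic node order, making the output a pure function
of the input graph. On instances small enough for exhaustive search the
approximation is verified to stay within the guaranteed factor 2 of the
optimum (and is nearly always much closer).

A bare tree would make density-based module detection degenerate, so the
subnetwork handed downstream is the subgraph *induced* by the union of the
Steiner nodes, the terminals, and the "one-intermediary" candidates
(non-terminal proteins adjacent to at least two terminals). This union
construction is a design choice of this package: tree reduction and
one-intermediary linking are two natural readings of how a minimal DEG
context should be assembled, and the union keeps both while restoring the
internal edges that density and cohesiveness computations need.

## Cohesiveness modules

Dense, possibly overlapping regions are found by greedy cohesiveness
maximization. The cohesiveness of a node set $V$ is

$$f(V) = \frac{w_{in}(V)}{w_{in}(V) + w_{bound}(V) + p\,|V|}$$

with $w_{in}$ the internal edge count, $w_{bound}$ the boundary edge count,
and a per-member penalty $p = 2$ (default) modeling undiscovered
interactions. The per-node scaling of the penalty is essential, not
cosmetic: under a constant penalty, adding a degree-1 external neighbor
*always* increases $f$, so every grown module provably ends up carrying its
pendant fringe. With $p\,|V|$ a pendant is absorbed only while
$w_{bound} + p|V| > w_{in}$, i.e. only into sets that are not yet clearly
denser than their surroundings. A `penalty_scale = "constant"` mode is kept
for comparison.

Growth starts from every node (decreasing degree, lexicographic on ties,
skipping covered nodes) and repeatedly applies the single best
add-external-neighbor or remove-member step that strictly increases $f$,
stopping at a local maximum; ties prefer addition, then the
lexicographically smallest node, so detection is deterministic including
output order. Candidates whose overlap score
$\omega(A,B) = |A \cap B|^2/(|A||B|)$ reaches 0.8 are merged. Because the
absorb-a-pendant condition above still holds for moderately dense planted
modules (an 8-node module at internal density 0.9 sits near the boundary),
a *haircut* postprocess (threshold 0.5) iteratively trims members whose
in-module degree falls below half the module mean — the same transformation
the reference cohesiveness-clustering tool offers — restoring the dense-core
semantics that the size/density filters assume.

Surviving modules must have at least `min_size = 7` nodes, density
$2m/(n(n-1)) \ge 0.3$, and a quality p-value below 0.05. The quality test is
not standardized anywhere; this package uses a one-sided Mann–Whitney U
comparing, across member nodes, in-module versus out-of-module edge counts
(a one-sided binomial test on edge endpoints is available via
`p_method = "binomial"`).

## Hub criterion

Within each module, every member's average unweighted shortest-path distance
to the DEG nodes of the subnetwork is computed (self-distance excluded for
DEG members; unreachable DEGs excluded from the mean and counted in the
report; the distance *sum* is reported alongside the mean). A member is a
hub when its average distance is strictly below the module's lower quartile
of such distances (25th percentile, linear interpolation, `type = 7`;
configurable) and its degree in the analysis subnetwork is at least
`degree_min = 6`. The inclusive `>=` is deliberate: hub reports in practice
include nodes sitting exactly at the cutoff degree, and a strict mode is
available via `strict_degree = TRUE`. Modules smaller than four members have
no meaningful lower quartile and are rejected. Distances are independently
checked against a from-scratch BFS in the test suite.

## Validated rate

For a candidate gene and one study, the validated rate is the fraction of
tumor samples whose expression lies strictly on the gene's DEG-direction
side of the mean control intensity (strictly above for up genes, strictly
below for down). Strictness at the threshold is pinned for testability; ties
have measure zero on real intensities. Comparison happens on the stored log2
scale, equivalent to linear for this monotone threshold. Rates pooled over
dataset groups are count-pooled — total concordant tumor samples over total
tumor samples — never means of per-dataset rates, so large cohorts weigh
more.

## Enrichment and IHC statistics

Over-representation of the DEG list in gene-set collections (GMT) uses the
one-sided hypergeometric upper tail $P(X \ge k)$ with Benjamini–Hochberg
correction across tested sets; sets are intersected with the background
first and zero-overlap sets are excluded before correction. The background
is the set of genes measured in both platform groups, the standard
correction for platform coverage. The test is verified against full
combinatorial enumeration for backgrounds up to 15 genes.

Immunohistochemistry cohorts are summarized by the immunoreactivity score
IRS = intensity grade (0–3) × percent positive cells (0–100), range 0–300.
Grade 0 is admitted for negative staining — a reported group mean of exactly
zero requires a zero factor. Group comparisons use the classical one-way
ANOVA F (via `lm`/`anova`; zero within-group variance everywhere is flagged
as undefined rather than reported as an arbitrary F), and protein–protein
co-expression uses the Pearson correlation with its t-based two-sided
p-value.

## The synthetic cohort generator

`simulate_expression_studies()` emulates exactly the structure the
meta-analysis assumes: shared gene baselines (log2 means drawn
Normal(7, 1.5), the scale of RMA-style output), per-study additive batch
offsets (SD 0.5) — deliberately creating the cross-study hazard that
rank-based aggregation is meant to dodge — planted up/down log2 effects
applied to tumor samples only, Gaussian residual noise (SD 0.7), and
per-study gene panels that always contain the planted genes
(`panel_overlap` controls coverage). `simulate_network()` plants dense
modules (and optionally an explicitly wired hub) in an Erdős–Rényi
background; the ER model is the simplest one under which the density and
cohesiveness thresholds are meaningful, and a preferential-attachment
option exists for degree-criterion stress tests. `simulate_ihc_cohort()`
draws clipped Gaussian intensity grades and percent-positive values per
group. All three generators are pure functions of their configuration
(seed included).

What the generator does *not* emulate: probe-level effects and
normalization artifacts, heavy-tailed or intensity-dependent noise,
correlated gene blocks outside the planted sets, scale-free global topology,
and annotation errors in gene symbols. Passing recovery tests on this
synthetic cohort therefore demonstrates correctness of the inference
machinery under its own model assumptions, not performance on any real
cohort.

## Problem sizes used in the checks

The bundled demonstration analysis uses a 300-gene panel, six training
studies (3 per platform group, 8 tumor / 5 control each), one testing study,
a 30-protein toy network containing a 7-node wheel module around a mildly
up-regulated non-DEG hub and a 6-gene down-regulated chain, and 200
permutations — a configuration chosen so the full pipeline, including the
permutation null, runs in about a second and is byte-identical across
reruns. Statistical checks run at 500–1000 genes, 10 seeds, 150–250
permutations; Steiner oracles use 12-node graphs with 4 terminals (where
exhaustive search is exact); module recovery uses two planted 8-cliques
(internal edge probability 0.9) in a 60-node background at edge probability
0.02 over 100 seeds.

## Known limitations

- Gene identity is string-based; no alias or ortholog resolution.
- Unit edge weights only; interaction confidence scores are ignored.
- The module quality p-value is a pragmatic stand-in for an undefined
  convention; both offered tests treat member nodes as independent, which
  they are not.
- The permutation null permutes whole rank vectors, so it preserves
  per-study rank marginals but not inter-gene correlation.
- The pairwise tumor×control rank-product variant (ranking every
  tumor/control pair rather than class means) is not implemented; class-mean
  fold changes keep the permutation null well-defined at small sample
  counts.
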