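---
title: "Methods: multi-layer biomarker-phenotype network discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-layer biomarker-phenotype network discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertlink)
```

`vertlink` induces three network layers — gene co-expression, clinical
feature correlation, and ontology-anchored conceptual knowledge — and
cross-links them so that vertical biomarker-phenotype chains spanning all
three can be extracted. This vignette records the models behind each
stage, the parameters that matter, the numerical and design choices that
were genuinely open, and what the synthetic generators do and do not
emulate.

## The gene layer

### Model

Co-expression is measured by the Pearson coefficient per dataset. Each
dataset contributes a graph with an edge wherever $|\rho| \ge$
`graph_rho`; the cross-dataset *summary graph* keeps an edge only if it
occurs in at least `min_support` datasets, recording the supporting
dataset set and the mean $\rho$. Dense modules are subgraphs with
connectivity ratio

$$r = \frac{L}{n(n-1)/2} > r_{\min}$$

for $n$ nodes and $L$ edges. A second-order *coherence* score — the mean
pairwise Jaccard similarity of the edges' dataset-support sets — captures
whether a module's edges co-occur in the same datasets; modules below
`min_coherence` are dropped. Anchor-gene lists (genes passing
`anchor_rho` against a fixed marker such as ZAP70 or CD38) are compared
across datasets by the upper-tail hypergeometric probability
$P(X \ge k)$ over a stated gene universe.

### Mining algorithm

The dense-subgraph step is specified here exactly, because it is the one
place a published pipeline of this kind typically defers to an external
algorithm without restating it. Each connected component is processed
recursively:

* if $r \le r_{\min}$, the minimum-degree vertex is removed (ties broken
  by lexicographic gene order) and the remainder is reprocessed — classic
  minimum-degree peeling with density tracking;
* if $r > r_{\min}$, the component is emitted, unless it contains a
  bridge (an edge whose removal disconnects it, tried in canonical edge
  order) whose two sides are each *strictly denser* than the whole; in
  that case the component splits and both sides are reprocessed.

Two properties motivated this form. First, a rule that always chases the
densest subset would shatter moderately dense modules into their densest
cliques ($r$ is maximized by any triangle), destroying recovery of
planted structure; keeping a qualifying component whole unless a bridge
separates strictly denser parts avoids that failure mode. Second, every
step is deterministic and reproducible by exhaustive-primitive recursion,
so the whole miner is verified against a brute-force oracle (adjacency
matrices, explicit subset enumeration, no graph library) on a battery of
structured and random graphs of up to 12 nodes in the test suite.

### Phenotype screening

Differential expression is an unadjusted Welch two-sample $t$ per gene at
$\alpha =$ 0.05 (a Benjamini-Hochberg switch is available); "significant"
was left unqualified in the lineage of methods this follows, and the
unadjusted test is the weakest assumption. The classifier is a diagonal
linear discriminant — per-gene class means with pooled per-gene variances,
assignment to the nearer standardized mean — evaluated by repeated
stratified holdout (`holdout` = 0.2, `n_repeats` = 50 by default).
"Supervised linear classifier" admits many readings; the diagonal LDA was
chosen because it is the simplest member of the family that is
well-defined for more genes than samples and has no tuning parameters.

### Overlap-test convention

The overlap test is implemented as the one-sided over-representation tail
because enrichment is the question being asked of intersecting anchor
lists. Published tables of this kind do not always state their tail
convention or the exact 2x2 margins used; on the intersection counts the
package's convention reproduces the boundary rows exactly (probability 1
for a zero overlap against a single-gene list; below $10^{-6}$ for the
strongly enriched pair) and the interior rows to within 0.05 absolute.
The test itself is verified against full enumeration of all draws for
universes up to 12.

## The clinical layer

Mixed encounter variables are made ordinal before correlation:

* categorical variables with at most `max_cats` (8) categories keep one
  code per declared category, in declared order;
* categorical variables with more categories are merged into 8 contiguous
  near-equal ranges;
* continuous variables with a laboratory reference range $(low, high)$
  become below/normal/above codes; without a range, tertiles.

Correlation is pairwise-complete Spearman (average ranks for ties),
declared *undefined* when fewer than `min_pairs` (20) complete pairs
remain or a restricted column is constant. Undefined is a first-class
outcome: such pairs are reported with a sentinel and never coerced to
zero, because a silent zero would delete exactly the information the
minimum-pair rule is meant to protect. Attributes that can never yield a
defined correlation (fewer than 20 non-null entries overall, or constant
after binning) are dropped up front with a logged count — the only
mechanism available to explain a smaller final correlation matrix than
the raw variable count.

The network keeps pairs with $\rho \ge$ `clinical_rho` (0.95). The
threshold is one-sided by default (an absolute-value mode exists but is
off), matching the stated focus on highly positively correlated
attributes. The degree distribution is summarized by a least-squares line
through the nonzero $(\log_{10} k, \log_{10} N_k)$ histogram points —
one bin per integer degree, no logarithmic rebinning — whose correlation
$R$ is the usual operational scale-free check.

A practical caveat established while validating the generators: coarse
binning attenuates rank correlation. A latent Spearman target of 0.99
survives 8-level binning at roughly 0.977 but drops to about 0.94 under
3-level binning, below the 0.95 threshold. Planted blocks intended to
appear as edges must therefore live on attributes with enough ordinal
resolution; the package's demonstrations use 8-level attributes for the
correlated block.

## The knowledge layer

Elements of a data dictionary are mapped to ontology concepts by
normalized lexical matching: case-folded, punctuation-stripped token sets
compared by Jaccard similarity against each concept's name and synonyms,
keeping matches with score $\ge$ `min_score`. The default of 1/3 admits
the canonical partial match (an element sharing its head token with a
concept name, e.g. one shared token among three) while rejecting
single-shared-token coincidences among longer names, which otherwise
saturate the mapped set and leave no unmapped concepts to route through.

A conceptual knowledge construct (CKC) is a simple relation path between
two mapped concepts belonging to different elements, routed through 1 to
`max_intermediates` *unmapped* interior concepts. Three choices here were
genuinely open:

* **Granularity.** The filter keeps an interior concept only if its is-a
  depth (shortest path from any hierarchy root) differs from each
  endpoint's depth by at most `granularity_delta` (default 1). Depth is
  the only granularity proxy computable from an ontology's structure
  alone; shortest-path semantics make it well-defined on multi-parent
  hierarchies.
* **Direction.** Relations are traversed direction-agnostically — both
  associative labels and is-a in either direction — because exemplary
  published chains mix relation directions freely.
* **Deduplication.** A chain and its reversal are the same construct; the
  orientation whose first concept id is lexicographically smaller is
  kept. When several relations join the same concept pair the
  lexicographically smallest label is used, keeping generation
  deterministic.

Expert validity/meaningfulness ratings are an *input* (an annotation
table), never computed: they are human judgments. CKC generation is
verified against an independent brute-force path enumerator on ontologies
of up to 25 concepts.

## Integration

Cross-layer links are evaluated over all node pairs between the
conceptual (hub) layer and each of the gene and clinical layers — direct
gene-clinical links exist as an option but default off, since the
knowledge layer is what anchors the semantics. A pair links as
`identical` (same concept id), `parent_child` (one direct is-a edge,
either direction), or `sibling` (at least one shared is-a parent), with
that precedence; a grandparent-grandchild pair does not link. Vertical
complexes are simple paths over the union of within-layer edges and
cross-links that touch at least two layers, found breadth-first up to
`max_len` hops and sorted by layers spanned, then length, then
lexicographically. The default `max_len` of 12 accommodates the worked
CLL chain (11 hops). Simple-path enumeration is exponential in dense
subgraphs — a mined module is a near-clique — so pipeline-scale runs use
a short hop budget (4) and resolve only marker genes to concepts; the
combinatorial behaviour is a property of simple paths, not of the
implementation, and the extractor is verified against exhaustive search
on fixtures.

## Synthetic generators

The generators provide the statistical structure each stage assumes, at
desk scale and fully seeded:

* **Expression panels.** A single-latent-factor model per module: gene
  $g$ in module $m$ has value $\lambda_g f_m(s) + \varepsilon$, with
  $f_m$ standard normal per sample, loadings uniform on `loading_range`
  (default [0.9, 1.1]) and noise sd `noise_sd`; background genes are pure
  noise; module genes may carry a mean shift (`effect_size`) between the
  two balanced phenotype groups. The defaults give within-module true
  correlations of roughly 0.76-0.83 — detectable but not trivial at the
  0.75 edge threshold with 100 samples. One factor per module is the
  weakest model that gives direct control over pairwise correlation.
* **Encounter tables.** A latent Gaussian copula; block Spearman targets
  are converted to latent Pearson correlations via
  $r = 2\sin(\pi\rho_s/6)$, so targets are interpretable on the scale the
  clinical stage measures. Categorical values come from equal-probability
  thresholding of the latent; nulls are missing-completely-at-random.
* **Ontologies.** A rooted is-a tree with fixed branching plus random
  associative cross-links; synonyms by token permutation; a mapping file
  pairs element names (concept name plus a qualifier token) with leaf
  concepts so lexical matching is exercised rather than trivial.

What they do *not* emulate: real CLL biology, batch effects,
informative missingness, longitudinal within-patient correlation, or the
skewed category distributions of real clinical repositories. Passing
tests therefore demonstrate that the machinery recovers the structure it
assumes, not that real repositories contain such structure.

## Problem sizes and reproducibility

The shipped demonstrations and checks run at deliberately small sizes:
panels of 6 datasets x 100 genes x 100 samples (20 replicate seeds for
recovery and classification summaries), encounter tables of 1,000 rows,
ontologies of 25-40 concepts, and fixtures of at most a few dozen nodes
for the exhaustively verified kernels. Every stochastic quantity flows
from a named seed — the generators are pure functions of their arguments
— and the full pipeline is byte-identical across repeated runs under a
fixed configuration.

## Known limitations

* The miner is a deterministic greedy procedure; it carries no optimality
  guarantee beyond its oracle-verified behaviour on small graphs, and its
  bridge rule only splits on single-edge cuts (two modules joined by two
  or more edges are kept together if jointly dense enough).
* Token-set Jaccard is a deliberately simple stand-in for a full lexical
  knowledge-source search; it has no notion of word order, morphology or
  abbreviation.
* Is-a depth is a coarse granularity proxy; ontologies with very uneven
  hierarchy depth will filter unevenly.
* Undefined correlations are reported but not imputed; attributes that
  fail the pre-filter vanish from the network rather than appearing as
  isolated nodes.
* Simple-path complex extraction is exponential in dense regions; hop
  budgets are the intended control, and results below the budget are
  complete, not sampled.
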