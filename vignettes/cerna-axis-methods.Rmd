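---
title: "Methods: assembling ceRNA regulatory axes from direction-call evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembling ceRNA regulatory axes from direction-call evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ceRNAxis)
```

## The model

A competing endogenous RNA (ceRNA) axis is an ordered triple
lncRNA–miRNA–mRNA in which the lncRNA carries a response element for
the miRNA and competes with the mRNA for it. Under this model the
steady-state expectation in a disease-versus-normal comparison is a
sign pattern, not a magnitude: the sponge and the protected mRNA move
together, the shared miRNA moves against both. ceRNAxis operates
entirely on that sign pattern. It consumes per-study *direction calls*
(up/down) rather than expression matrices — the form in which
literature-curated multi-omics evidence is actually available — and
treats interaction catalogs (miRNA–target, lncRNA–miRNA,
protein–protein, gene sets) as explicit inputs rather than database
queries, so a run is fully reproducible from its input files.

The assumptions this buys, and their price:

* **Directions suffice.** No effect sizes, p-values or study weights
  enter the consensus; a small, noisy study counts as much as a large
  one. This matches curated evidence tables, but it means the pipeline
  cannot distinguish a strong consistent signal from a marginal one.
* **Catalog completeness bounds recall.** A true axis absent from the
  supplied catalogs cannot be discovered; the pipeline is a consistent
  *join*, not an inference engine. (Sponge-effect quantification —
  correlation or conditional-independence testing on expression
  matrices — is deliberately out of scope.)
* **String-keyed joins.** All cross-catalog matching is by normalized
  identifier (upper-cased gene symbols, `hsa-miR-…` miRNA ids with
  preserved arm suffixes). Synonym resolution beyond casing is the
  user's responsibility through the alias-table hook; the package does
  not bundle a synonym source, because any fixed choice would silently
  change joins.

## Stage by stage

### Consensus direction calling

`call_consensus()` applies a strict majority: `up` iff more than half
of the voting units say up, `ambiguous` on an exact tie. Ambiguous
molecules stay in the table, flagged `excluded`, and never reach later
stages. With transcript-annotated evidence the rule is two-level:
studies vote within a transcript, transcripts vote for the gene.

Two decisions here were genuinely open. First, a transcript that ties
internally *abstains* at the gene level rather than entering the
denominator — this keeps "more than 50% of the transcripts"
well-defined (3 transcripts voting up/down/abstain give 1/2 each, not
1/3). Second, each evidence row is one vote: a study reporting a
molecule in both directions (e.g. two probes) contributes two opposing
votes rather than being collapsed first. Both choices are simple,
order-independent, and exhaustively tested against a brute-force
majority oracle for every vote pattern up to size six.

### Pairing and confidence

`expression_pair()` keeps edges whose miRNA and target both have
definite calls in opposite directions; `confidence_filter()` keeps
experimentally observed edges and predicted edges with CWCS ≤ −0.4
(boundary inclusive; the cumulative weighted context score is more
negative for stronger predicted repression, so the cutoff admits
scores *at or below* −0.4). The two filters commute — a property the
test suite checks on random catalogs — so their order is an
implementation detail.

`integrate_layers()` unions the transcript-derived and protein-derived
retained sets keyed by (miRNA, target). An edge retained in **both**
layers marks its target `dual_level`; `dual_concordant` additionally
requires the mRNA- and protein-level calls to agree. We define
dual-level by both-layer *retention* rather than by the target merely
having calls in both classes: retention is what certifies that the
inverse-pairing predicate held against both layers. Since both layers
share the miRNA call, both-layer retention actually forces
concordance; the discordant flag exists for inputs that bypass pairing
and is kept, warned about, and excluded from `dual_concordant`.

### Hub identification

`build_graph()` thresholds STRING-convention combined scores
(inclusive at `min_score`, default 900; scores supplied as 0–1 floats
are scaled by 1000 at load). Hubs are the intersection of the top-k
lists (default k = 10) under four centralities, all implemented in the
package and all verified against independent brute-force oracles
(Floyd–Warshall distances, explicit shortest-path enumeration,
explicit tree construction) on 200 random graphs per run of the test
suite, plus igraph as a second opinion for the three classical
metrics:

* **Degree** — neighbor count.
* **Closeness** — by default the *harmonic* form
  $C(v) = \sum_{w \ne v} 1/d(v,w)$, which stays well-defined on the
  disconnected graphs that aggressive score thresholding produces
  (unreachable nodes contribute 0). The classical
  $(n_c - 1)/\sum d$ restricted to components is available as
  `mode = "classic"`; the two can rank nodes differently on
  disconnected graphs, which is why the choice is an explicit flag.
* **Betweenness** — unnormalized over unordered pairs, endpoints
  excluded, via Brandes accumulation. Only ranks are consumed, and
  normalization is rank-invariant.
* **BottleNeck** — for each root's shortest-path tree, a non-root node
  scores 1 when its subtree exceeds a quarter of the tree
  (strictly). Shortest-path trees are not unique, so the metric is
  made deterministic by construction: BFS in sorted label order,
  parent = lexicographically smallest equal-distance predecessor. The
  strictness of the threshold and the root exclusion follow the
  metric's published description; both are arguments.

`top_k()` includes all ties at the k-th boundary (the list may exceed
k) with a secondary sort on labels; whether published top-10 lists
expand ties is generally unknowable, so the rule here is declared
rather than inferred, and deterministic.

### Over-representation analysis

`hypergeom_test()` is the one-sided upper tail
$p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$,
computed through the standard distribution function (stable far beyond
$N = 10^5$) and checked against complete enumeration for small
universes. The universe defaults to the union of the supplied
collection — the only self-consistent default when no annotation
background is given — and is overridable, because the universe choice
moves every p-value. Both raw-p and Benjamini–Hochberg FDR flags are
reported at the same `alpha` (default 0.05): different upstream tools
quote one or the other, and −log10 p > 1.3 is the same criterion as
p < 0.05.

### Triad assembly

`assemble_triads()` takes each anchor's retained miRNA partners,
expands arm-less miRNA ids to both mature arms **only for the
lncRNA–miRNA join** (the miRNA–target edge keeps the id its evidence
was recorded under, and the triad records the arm-resolved id with an
`arm_expanded` flag), joins the lncRNA catalog, and keeps triads
satisfying the sponge predicate
`lnc_direction == target_direction != mir_direction`. The predicate is
symmetric under a global direction flip, monotone under catalog
removal, and the assembly equals a brute-force triple loop on random
instances — all three are property tests. Anchors with no surviving
triad are reported explicitly rather than silently absent. Evidence
tiers ride along on both edges: strong iff at least one of
reporter assay / western blot / qPCR supports the edge.

## Synthetic data: what it emulates, and what it does not

The `gen_*` generators produce every pipeline input with a known
ground truth: per-study direction calls with independent per-study
flip noise; interaction catalogs in which each planted axis is
observed, strong, and direction-consistent, and each decoy violates
exactly one labeled retention predicate (wrong sign, CWCS above
cutoff, or no lncRNA partner); an Erdős–Rényi PPI background with
hubs wired at a degree that must dominate the expected background
degree by a factor of four, plus sub-threshold decoy edges so that the
score cutoff is actually exercised; and gene-set collections with one
planted set whose overlap is raised until its hypergeometric p falls
below $10^{-4}$.

Decoys are adversarial-by-predicate rather than uniform noise: this
gives each filter a dedicated violator class, which is what makes
"precision = recall = 1 on the planted axes" a meaningful end-to-end
statement. The default bundle's expression calls are noise-free —
they stand in for *curated literature assertions*, which arrive as
fixed calls, not as raw measurements; flip noise is a separate knob
(`flip_noise`) exercised in the consensus-recovery experiments, where
the expected recovery has a binomial closed form
($\sum_{i=0}^{2}\binom{5}{i}0.2^i0.8^{5-i} = 0.94208$ at five studies
and 20% noise).

What passing these tests does **not** show about real data: the
generators do not emulate expression magnitudes, correlated studies,
annotation bias in catalogs, symbol-synonym ambiguity, or the
hairball topology of real PPI networks. They certify the *logic* of
the pipeline, not the biological yield of any particular catalog set.

## Problem sizes and numerical choices

The shipped test suite uses sizes chosen to make the oracles exact and
the suite quick: random graphs up to 25 nodes (200 per run) for the
centrality oracles, complete enumeration up to a 12-gene universe for
the hypergeometric check, 2,000 molecules for the binomial recovery
experiment, and 100 seeded replicates of the planted-hub graph
(60 background nodes, edge probability 0.05, three hubs of degree 30).
All randomness flows from explicit integer seeds; `gen_bundle()`
derives per-generator sub-seeds from one seed by fixed small offsets.

Degenerate inputs are defined, not accidental: empty graphs and empty
networks warn and produce valid empty outputs; a graph smaller than k
warns and uses all nodes per metric; isolated nodes score 0 closeness;
an empty evidence catalog yields an empty consensus table. Exact
boundaries are inclusive where the stated cutoffs are inclusive
(CWCS −0.4 kept, PPI score 900 kept) and the tests pin both sides of
each boundary.

## Limitations

* Axes are catalog joins with sign consistency; no quantitative sponge
  statistic is computed, so the output is a candidate list ranked by
  evidence tier, not by effect.
* Consensus ignores study size and quality; a curation step upstream
  remains essential.
* BottleNeck centrality is inherently tree-ambiguous; the package's
  determinism is a convention (documented above), and other tools may
  rank differently on graphs with many tied shortest paths.
* Identifier normalization handles casing and prefixes, not biology:
  merged or renamed gene symbols must be resolved through the alias
  table.
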