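---
title: "Methods: gene age/origin classification and network assortativity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene age/origin classification and network assortativity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite or
the acceptance script does not itself compute.

## The scientific question

Genes enter a genome by different routes. Duplication copies a complete
gene, so the daughter is born with a foldable structure, established
functions, and plausible access to its ancestor's interaction partners.
Novel genes — from de novo origination, gene fusion/fission, or domain
shuffling — start without that inheritance. If origin and age shape how a
gene integrates into cellular networks, the signature should be visible
genome-wide: in per-group functional attributes, in centrality within the
protein–protein interaction (PPI) network, and in who interacts with
whom. The whole-genome duplication (WGD) in the yeast lineage provides a
sharp, datable boundary for "old" versus "young", and itself creates a
third age class: the retained WGD duplicate pairs.

`genesisnet` packages that analysis: classify genes by age and origin
from evidence tables, measure network integration per group, and test
group-level interaction preferences against a degree-preserving null.

## Classification model

Inputs are four evidence tables (catalog, family map, ancestral
reconstruction, ortholog profiles). The classifier's assumptions:

* **The reconstruction is input, not inference.** Ancestral gene order
  and the A/B syntenic track assignment of descendants are taken as
  given. The WGD-pair signature therefore reduces to a structural test:
  one ancestral locus with descendants on both tracks. Each (locus,
  track) maps to at most one gene in our format; curatorial ambiguity
  must be resolved upstream.
* **Rule precedence is explicit** because the source rules are
  individually stated but unordered: WGD pair ≻ ancestral presence ≻
  subtelomeric ortholog rule ≻ post-WGD default. A gene both present in
  the reconstruction and flagged subtelomeric keeps its reconstruction
  age (the stronger evidence), with a logged message.
* **Origin = family size**, counting only non-dubious catalog genes,
  after unioning families that contain the two members of a WGD pair
  (family inference and the reconstruction are independent sources and
  sometimes split an ohnolog pair). WGD-pair members are `duplicate` by
  construction, which is why the (wgd, novel) group is structurally
  empty. Dubious ORFs are dropped before anything else, so they neither
  receive labels nor prop up family sizes.
* **Each gene is aged individually.** A family that existed before the
  WGD can still contain a post-WGD member: the new copy is young even
  though its family is old. This matches a group definition based on
  when *the gene* appeared, not when its family did.

The **progenitor variant** is an alternative origin labeling: within
every multi-member family, the gene with the deepest ortholog (largest
divergence rank in a user-supplied species table; ties uniform at random
under the given seed) is relabeled `novel` as the family's presumed
ancestral copy. Families with no ortholog data get a uniformly random
progenitor, logged. Ortholog "depth" is an integer rank per species
rather than a time calibration — only the ordering matters.

## Network statistics

The analyzed graph is simple and undirected, over exactly the genes with
at least one retained interaction. Self-interactions (homodimers) are
dropped at parse time: the centrality definitions assume a simple graph,
and the drop is logged so users can audit it.

**Sticky-protein filter.** Proteins with more than 50 interactions are
treated as likely experimental artifacts and removed iteratively. The
package removes, per round, *all vertices at the current maximum degree*
among those above threshold, then recomputes. We considered the
alternative "remove everything above threshold at once": since removal
can only lower degrees, that rule always terminates after a single round,
which makes "iterative" vacuous and — more importantly — deletes border
cases that only exceed the threshold through their edges to a bigger hub.
Under the max-first rule a protein whose degree falls back to the
threshold once the dominant hub is gone survives; the procedure is
deterministic and independent of vertex order. The removal log records
each round.

**Betweenness.** bc(v) = [Σ over unordered pairs s&lt;t, both ≠ v, of
σ_st(v)/σ_st] / [(n−1)(n−2)/2], with disconnected pairs contributing
zero. The normalization makes "fraction of all shortest paths" literal
and bounds values in [0, 1] (a star center scores 1). Whether the
original analysis normalized, or counted ordered pairs, is unknowable
from the text; every downstream use is a relative comparison between
groups, which is invariant to the constant factor. The implementation
delegates to igraph's Brandes algorithm; the test suite checks it to
1e-12 against an independent BFS + exhaustive path-enumeration oracle on
50 random graphs.

**Length normalization** (degree / aa, betweenness / aa) addresses the
physical confound that a larger protein can maintain more simultaneous
interfaces; group contrasts that survive it are not driven by length
alone.

## The assortativity test

Every edge is assigned to one unordered group pair. Observed counts are
compared to an ensemble of `n_random` (default 1000) degree-preserving
randomized networks:

* **Null model.** Stub rewiring: every edge is cut into two half-edges,
  the stub multiset is shuffled and rematched; any self-loop or
  multi-edge rejects the whole matching and a fresh attempt starts, so
  accepted samples are uniform over simple realizations of the exact
  degree sequence. After 100 failed matchings (heavy-tailed sequences
  collide often) the sampler falls back to a double-edge-swap Markov
  chain from the observed graph, run for 10·|E| accepted swaps; both
  schemes preserve every vertex's degree exactly, hence each group's
  degree sum and the global edge total. The scheme used is recorded per
  sample. Preserving exact per-vertex degrees is the strictest reading of
  "maintain the degree distribution within groups" and subsumes the
  group-level one.
* **Empirical p-values** are plain proportions: P(null ≥ observed) for
  enrichment, P(null ≤ observed) for depletion, ties inclusive. No
  (r+1)/(n+1) pseudo-count is added — a reported 0 means "beyond every
  null sample", and the ensemble size is attached so users can add
  pseudo-counts themselves. The depletion tail is the symmetric
  extension of the stated enrichment tail.
* **Effect size** is Glass's Δ = (observed − mean(null)) / sd(null) with
  the sample (n−1) SD. A degenerate ensemble (sd = 0, e.g. a forced
  unique realization) yields a flagged-undefined `NA`, never an
  infinity.
* **Calls**: `p_enrich < α` → enriched, else `p_deplete < α` → depleted,
  else neutral; both tails below α (possible only with a nearly
  degenerate null) is logged as anomalous and called enriched.

## The synthetic world

The generator emulates the *structure* of the study's inputs with known
ground truth; its defaults are a stated world, not a fit.

* **Group sizes** default to 1434/2696/1087/314/239
  (pre-WGD-duplicate, pre-WGD-novel, WGD, post-WGD-duplicate,
  post-WGD-novel) — the published magnitudes. The WGD group is rounded
  down to an even count because the fixture format encodes WGD genes
  strictly as double-track pairs; the odd published count reflects pairs
  with one lost or ambiguous member, which we deliberately do not model.
* **Attributes** echo the published per-group magnitudes: median lengths
  450/398/430/400/180 aa (lognormal, sdlog 0.55 — a typical dispersion
  for protein-length distributions; only the young-novel 180 vs
  young-duplicate 400 contrast is load-bearing in tests), essentiality
  0.30/0.30/0.08/0.02/0.00, molecular-function annotation coverage
  0.88/0.67/0.76/0.60/0.22, interaction participation
  0.81/0.77/0.72/0.55/0.25, mean Pfam coverage
  0.57/0.36/0.45/0.53/0.12. Annotated genes draw 1–3 terms from a
  40-term pool with one 10× up-weighted signature term per group, giving
  enrichment tests planted signal. Subtelomeric probability is 0.35 for
  the young groups, 0.02 for old, 0 for WGD (subtelomeres are excluded
  from synteny reconstruction), echoing the ~300 mostly-young
  subtelomeric genes in the study.
* **Evidence fixtures** are constructed so classification recovers truth
  *exactly*: this is the defining contract, tested over 20 seeds. Half
  the WGD pairs are emitted as split singleton families so the
  family-merging step does real work; half the novel genes are omitted
  from the family file to exercise the implicit-singleton rule. A unique
  deepest-ortholog gene is planted per family so the progenitor variant
  has deterministic truth.
* **Network**: degree-corrected block model. Participating vertices get
  degree propensities from a truncated discrete power law (exponent 2.5,
  range [1, 50] — heavy-tailed like real PPI data, capped at the sticky
  threshold so the filter can be exercised by raising the cap); edge
  (i, j) appears with probability min(1, θ_i θ_j ω_{g(i)g(j)} / C), C
  normalizing the expected mean degree (default 6). A plain SBM without
  degree correction would make the degree-preserving null trivially
  calibrated; degree heterogeneity is precisely what the null must
  absorb.

What a green test does **not** establish: the generator draws edges
independently (no triadic closure, no complex-driven cliques), its
annotation terms are flat labels (no ontology DAG, no propagation), and
study bias — more interactions known for old, well-studied genes — enters
only through per-group participation rates. Calibration and power
results transfer to real data only to the extent these simplifications
are benign.

## Numerical and interface choices

* All randomness flows through R's RNG, including inside the C++
  rewiring kernel, so a single `set.seed` (or the pipeline's root seed
  with fixed per-stage offsets) reproduces everything byte-for-byte;
  pipeline logs contain no timestamps for the same reason.
* Mann–Whitney uses the exact null when min(n_a, n_b) ≤ 8 without ties
  (verified against full rank-arrangement enumeration for all
  n ≤ 6), otherwise the tie-corrected normal approximation with
  continuity correction.
* Enrichment restricts the background to annotated genes by default
  (conditioning on annotation, as period enrichment tools did), uses the
  upper-tail hypergeometric without DAG propagation — inputs are flat
  term lists — and Bonferroni correction over the terms tested
  (era-appropriate; configurable off).
* Edge canonicalization (lexicographic ordering, duplicate collapse,
  self-pair drop) is idempotent and logged; unknown gene ids are dropped
  with a warning by default, with a strict mode available.
* The pipeline config file is JSON rather than YAML: the target
  environment pins no R YAML parser, and the config maps one-to-one onto
  `run_config()` arguments either way.
* A stub-matching attempt that keeps failing falls back to the swap
  chain; for degree sequences with a *unique* simple realization (stars,
  triangles) even the chain cannot move, and the sampler returns the
  original graph — which is then also the correct (only) null sample.

## Known limitations

* Classification accuracy is bounded by the upstream family and
  reconstruction inference; the package propagates, it does not
  second-guess. Alternative family maps are simply alternative inputs.
* The finer pre-divergence age split, ancestral-reconstruction
  algorithms, GO DAG semantics, and two-way ANOVA robustness checks are
  out of scope.
* Betweenness on the filtered graph treats components independently
  (disconnected pairs contribute zero); comparing betweenness across
  networks of very different connectivity is not meaningful.
* Empirical p-values are bounded below by 1/n_random; with the default
  1000 randomizations, "p = 0" means "< 0.001", not zero.
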