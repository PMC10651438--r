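---
title: "Bridging gene and disease ontologies for embedding-based association prediction"
author: "OntoKGE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridging gene and disease ontologies for embedding-based association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Gene ontologies (such as OGG, which catalogues specific genes) and disease
ontologies (such as DOID) are disjoint subclass hierarchies: no term of one is
an ancestor, descendant or cross-reference of a term of the other. Any method
that embeds ontology terms into a vector space from graph structure alone will
therefore place the two ontologies in arbitrary relative position, and the
embedding carries no signal about which genes relate to which diseases.

OntoKGE addresses this by *bridging*: it mines a sentence-level gene–disease
corpus for frequently co-asserted pairs, maps the most-mentioned pairs onto
ontology terms, and adds a bidirectional `associated` edge for each — joining
the two hierarchies into one knowledge graph. Knowledge-graph-embedding (KGE)
models trained on the joint graph can then rank candidate disease terms for a
gene (and vice versa), proposing associations the corpus never stated.

## Pipeline

1. **Ontology ingestion** (`parseOBO()`, `parseEdgeList()`). Only the
   subclass (`is_a`) axis is extracted — the one intra-ontology relation the
   joint graph uses. Obsolete terms are dropped with their edges; other OBO
   relationship types are ignored and logged. Identifiers are normalized to
   `PREFIX:LOCAL` CURIEs (underscore forms such as `OGG_3000007157` become
   `OGG:3000007157`); comparison is case-sensitive.
2. **Corpus handling** (`readCorpus()`, `binarizeLabels()`,
   `balanceDataset()`, `countAssociations()`). Corpora are JSON-lines, one
   sentence per record with exactly one gene, one disease and a four-class
   label (`NA`, `therapeutic`, `biomarker`, `genomic`). The three associated
   classes collapse into one positive class; balancing downsamples the
   majority class (seeded, without replacement) to a target positive
   fraction, by default 0.5. `samplePairDataset()` draws positives from a
   pair table and equally many never-associated negatives from the observed
   gene × disease universe; `makePrompts()` renders pairs with the fixed
   template `"Is {DISEASE} related to {GENE}?"`.
3. **Bridge building** (`selectBridges()`, `mapPairsToBridges()`,
   `buildJointKG()`). Selection is deterministic top-K by non-NA mention
   count with a lexicographic `(gene, disease)` tie-break, which makes the
   historically manual annotation step reproducible and prefix-monotone
   (the top-45 set is always inside the top-120 set). Id-to-CURIE mapping is
   externalized to user-editable tables; an optional OGG heuristic
   (`OGG:3000<ncbi id>`) is applied only when enabled and only when the
   constructed CURIE resolves. Every bridge contributes both directed
   `associated` triples, so the joint triple count is exactly
   `|S1| + |S2| + 2B`.
4. **Training and evaluation** (`initModel()`, `trainModel()`,
   `evaluateRanking()`), described below. `splitAssociatedTriples()` holds
   out test associations *by undirected pair*, never by directed triple —
   otherwise the reverse direction of every test edge would sit in the
   training set and leak the answer.

## The seven scoring families

All scores are "higher = more plausible". With entity embeddings `e` and
relation parameters as given, the implemented closed forms are:

| family  | score `s(h, r, t)` | parameters |
|---------|--------------------|------------|
| UM      | `-||e_h - e_t||^2` | real vectors; relation-blind |
| TorusE  | `-sum_i min(d_i, 1 - d_i)`, `d_i = frac(h_i + r_i - t_i)` | points on `[0,1)^d` (L1 torus metric) |
| RotatE  | `-||e_h \circ e^{i\theta_r} - e_t||_2` | complex entities, phase relations |
| PairRE  | `-||e_h \circ r^H - e_t \circ r^T||_1` | unit-norm entities, paired relation vectors |
| ComplEx | `Re(sum_i e_{h,i} w_{r,i} \bar e_{t,i})` | complex entities and relations |
| SimplE  | `(⟨h_h, w_r, t_t⟩ + ⟨h_t, w_{r^{-1}}, t_h⟩) / 2` | dual role vectors, inverse relation |
| KG2E    | `-KL(N(\mu_h - \mu_t, \Sigma_h + \Sigma_t) || N(\mu_r, \Sigma_r))` | diagonal Gaussians |

Every formula is verified in the test suite against an independent scalar
reimplementation (complex arithmetic via R's `complex` type, KL additionally
against numeric quadrature) at relative tolerance 1e-9.

A practical note on the symmetric `associated` relation: because both
directions of every bridge are present with the *same* relation label, purely
translational models can only represent association as proximity (`r ≈ 0` on
the torus), while RotatE (`θ = π` is an involution), PairRE, ComplEx with a
real relation component, SimplE and KG2E all have exact symmetric solutions.

## Training: losses, conventions, and why they look the way they do

- **Loss assignment.** Distance families (UM, TorusE, RotatE, PairRE, KG2E)
  use the margin ranking loss `max(0, γ − s(pos) + s(neg))`; bilinear
  families (ComplEx, SimplE) use the softplus logistic loss with L2 weight
  decay (`lambda`, default 1e-4). This follows each family's original
  formulation.
- **Negative sampling.** Each positive is contrasted with `nNegatives`
  (default 10) corruptions: a fair coin picks head or tail, a uniform
  replacement entity is drawn, and draws that reproduce a known training
  triple or leave the entity unchanged are rejected and resampled.
- **Gradient convention.** Every sampled (positive, negative) pair — and for
  the logistic loss every sampled example — contributes one full-weight
  gradient term, the convention of the original methods. Updates are plain
  mini-batch SGD (batch 64 positives), which keeps the whole trajectory
  bitwise-reproducible for a fixed seed; adaptive optimizers were
  deliberately avoided for that reason.
- **Projections.** After every batch each family's parameter-space invariant
  is re-imposed: torus coordinates wrapped to `[0,1)`, RotatE phases wrapped
  to `[0,2π)`, PairRE entity rows renormalized to unit length, KG2E diagonal
  covariances clamped to `[cMin, cMax]` (default `[0.05, 5]`). UM entity
  vectors and KG2E mean vectors are additionally projected onto the unit
  ball, as in their original formulations: without this constraint the
  repulsive half of the ranking loss inflates norms until every hinge is
  satisfied and learning silently stops.
- **Per-family defaults.** Dimension 100, margin `γ = 1`, learning rate
  0.01, 200 epochs — except TorusE, whose geometry forces two changes. Its
  L1 torus distance grows linearly with dimension (a random pair sits at
  distance ≈ `d/4`), so a fixed margin of 1 is already satisfied at
  initialization and the hinge never activates; the default margin is
  therefore `0.2·d`. And its hinge gradient is a constant-magnitude sign
  vector on a compact space, so steps must be an order of magnitude smaller
  than the Euclidean families'; the default learning rate is 0.001. Both
  match the training regime of the method's original description. All
  defaults are overridable via `kgeConfig()`.
- **Batch size 64.** At the benchmark sizes used here (~2000 training
  triples) this yields ≈30 SGD steps per epoch, enough for the
  slower-converging families (KG2E, ComplEx) to reach a stable solution
  within the 200-epoch budget; larger batches were observed to leave them
  visibly under-converged at identical epoch counts.

## Evaluation protocol

`evaluateRanking()` ranks, for every test triple, the true entity against
candidate replacements of the corrupted slot, on the head side, the tail
side, or both (default both, ranks pooled), and reports MR, MRR and
Hits@{1,3,5}. Decisions where the literature varies:

- **Filtered by default**: candidates that form a *different* known positive
  (training ∪ test) are removed before ranking — never the true entity — so
  filtered ranks are never worse than raw. Raw is selectable.
- **Ties average**: the rank of a score tie is the mean of the optimistic
  and pessimistic ranks, so a degenerate constant scorer calibrates to the
  uniform expectation `(N+1)/2` instead of rewarding ties.
- **Candidates all-entities by default**: every model entity competes,
  the prevailing convention in KGE benchmarks; `"type-constrained"`
  restricts candidates to the true entity's namespace (only diseases compete
  for a disease slot), which is the application-facing view and never worsens
  MR. Both are exposed; all reported package results use the default.
- MRR is always reported alongside MR: mean rank alone is scale-bound to the
  candidate count and the two together are more comparable across candidate
  policies.

## The synthetic study and what it does (not) show

The generators emulate the statistical shape of the real inputs with no
download: `genOntology()` grows seeded rooted trees with bounded branching;
`genCorpus()` plants gene–disease pairs whose non-NA mention counts follow a
Zipf law (exponent 1.1) plus an NA-co-mention background (default half of all
sentences), mirroring the long-tailed, NA-dominated character of real
relation-extraction corpora; `genPlantedKG()` partitions genes and diseases
into matched latent blocks and samples associations only within blocks — a
signal every one of the seven families can represent, unlike, say, strict
compositional patterns.

The package's benchmark conditions, fixed once: 200 terms per ontology,
branching 4, 4 blocks, 1000 planted pairs (2000 directed associated
triples), 20% of pairs held out, embedding dimension 32, 200 epochs,
recovery averaged over 3 training seeds. At those conditions six of the
seven families place the held-out partner in the top 5 at several times the
5/N random baseline. The exception is UM: it is relation-blind, and because
subclass edges are training positives too, a gene's nearest neighbours after
training are its own hierarchy relatives, which crowd the top ranks ahead of
any disease term. This is a structural property of the unstructured model,
not a convergence failure — it is also by far the weakest model at Hits@1 in
published comparisons on real biomedical joint graphs.

Passing these tests shows the machinery is correct and that learnable
block-structured signal is recovered; it does not show that real OGG/DOID +
corpus graphs (three orders of magnitude larger, with heavy-tailed degree
distributions and annotation noise) would yield comparable metric values.

## Numerical choices and degenerate inputs

- All randomness flows through explicit integer seeds (`withr::with_seed`);
  generators, initialization, splits and loss traces are bitwise
  reproducible.
- RotatE's distance gradient is guarded at distance 0 (gradient taken as 0);
  PairRE renormalization skips rows already on the unit sphere so a
  zero-learning-rate run is a strict no-op.
- Negative sampling rejects for at most 1000 rounds and then aborts with an
  explanation — reachable only on graphs whose corruption space is
  exhausted (e.g. a complete bipartite association set).
- Non-finite losses abort training with a diagnostic instead of propagating
  NaNs into the parameters.
- `balanceDataset()` errors on an empty minority class;
  `samplePairDataset()` errors when the never-associated complement is
  smaller than the requested negative count; `splitAssociatedTriples()`
  errors when no associated triples exist.

## Open questions resolved here

- "Most mentioned" pair counts exclude NA co-mentions: bridges encode
  association, and an NA sentence asserts its absence.
- Balancing is applied per split (the package takes no position on the
  upstream corpus's split construction); users balancing before splitting
  should do so upstream.
- Bridge selection supports `k = Inf` ("all pairs") in addition to the
   45/120-style thresholds, since a KGE graph built from *all* corpus
  associations is a natural variant of the same construction.
- Ontology release term counts are never asserted: they are
  version-dependent facts about external artifacts, not invariants of this
  code.

## Known limitations

- OWL ingestion (logical constructors, equivalence axioms) is out of scope;
  OBO flat files and edge lists cover the subclass content the joint graph
  uses.
- No GPU path, no self-adversarial negative sampling, no 1-N scoring: the
  implementation favours determinism and auditability over raw throughput,
  and is sized for graphs in the 1e4–1e5 triple range on one CPU.
- Bridges attach exactly to the mapped terms; no propagation to ancestors.
- Scores are rankings, not calibrated probabilities.
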