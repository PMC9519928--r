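---
title: "Predicting miRNA-disease associations from heterogeneous gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA-disease associations from heterogeneous gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdnet)
```

## The problem

MicroRNAs (miRNAs) regulate protein-coding gene (PCG) expression, and their
dysregulation is implicated in many diseases. Known miRNA-disease
associations are scarce, so direct link prediction on the miRNA-disease
bipartite graph struggles — especially for *new* diseases with no known
miRNA partner at all. `mdnet` follows a multi-source strategy: miRNAs and
diseases are described by the PCGs they are associated with, the PCG
profiles are *enriched* by propagation over a directed PCG functional
interaction network, *filtered* by an ontology-supervised feature selector,
*embedded* jointly with the miRNA-disease training graph, and finally
*classified* pair by pair with a random forest.

The four stages, in pipeline order:

1. **Message passing.** Each miRNA (or disease) starts with a weight vector
   over PCG nodes: 1 (or a confidence score in $[0,1]$) for known
   associations, 0 otherwise. One synchronous propagation step infers
   weights for unknown nodes from their parents in the directed PCG graph:
   $$w_t(i) = \frac{1}{\sqrt{d_{in}(i)}} \sum_{j \in Par(i)}
     \frac{w_{t-1}(j)}{\sqrt{d_{out}(j)}}$$
   Known entries are never modified; unknown nodes without parents stay 0.
   Iterating moves information one hop per step, and every unknown node is
   recomputed from the full previous state each iteration (previously
   inferred values are overwritten, not frozen). The step is degree
   normalised on both ends, so hubs neither flood their neighbours nor
   accumulate unbounded weight, and it is parameter-free.

2. **Ontology-supervised feature selection.** Tens of thousands of PCGs is
   too many, and most carry no disease signal. As a *side task*, each
   disease is labeled with a coarse ontology category (its first-level
   tree-code prefix; second-level under the infection branch, whose
   first level is too heterogeneous; categories with fewer than 10 members
   collapse into "Others"). ReliefF then scores every PCG feature by how
   well it separates disease categories on the enriched disease-PCG
   profiles, and the top K = 100 PCGs are kept — for both disease *and*
   miRNA profiles, since the selection is a property of the PCG feature,
   not of the entity kind.

3. **Structural embedding.** An undirected heterogeneous graph over
   [miRNAs | diseases | selected PCGs] is assembled as the symmetric block
   matrix
   $$A = \begin{pmatrix} 0 & A_{md} & A_{mp} \\ A_{md}^T & 0 & A_{dp} \\
     A_{mp}^T & A_{dp}^T & A_p \end{pmatrix}$$
   with *training* miRNA-disease edges at weight 1, enriched profile
   weights on the entity-PCG edges, and the undirected projection of the
   PCG graph (weight 1) on the PCG block. A structural deep network
   embedding (SDNE) autoencoder — sigmoid encoder layers of size
   [1000, 128], one sigmoid decoder — maps every adjacency row to a 128-dim
   code minimising
   $$L = \sum_i \|(\hat x_i - s_i)\odot b_i\|^2
       + \alpha \sum_{i<j} s_{ij}\,\|y_i-y_j\|^2 + \nu\,\|W\|_2^2,$$
   where $b_{ij} = \beta > 1$ on observed edges. The second-order term makes
   nodes with shared neighbourhoods similar, the first-order term makes
   linked nodes similar. Crucially, diseases unseen in the training
   association set still sit in this graph through their PCG edges, so
   their embeddings are informative rather than arbitrary.

4. **Classification.** Each pair $(m, d)$ is represented as
   $X_{md} = [E_m,\, E_d,\, F_m,\, S_d]$: the two embedding rows, the
   miRNA's family one-hot vector, and the disease's semantic-similarity row
   over the training disease set. A 350-tree probability forest outputs the
   association probability. Disease semantic similarity is the Wang
   measure over ontology positions: each ancestor $t$ of $d$ contributes
   $\Delta_d(t) = \delta^{h}$ ($h$ levels above $d$, best position), and
   $$sim(d_1,d_2) = \frac{\sum_{t\in T_1\cap T_2}\Delta_{d_1}(t)+\Delta_{d_2}(t)}
     {DV(d_1)+DV(d_2)}.$$

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `iterations` | 1 | propagation steps; 1 adds direct parents only, which is the operating point used throughout |
| `K` | 100 | PCGs kept after ReliefF ranking |
| `k_neighbors` | 10 | ReliefF hits/misses per class (truncated for small classes, normalised by the actual count) |
| `min_category_size` | 10 | categories smaller than this collapse into "Others" |
| `delta` | 0.5 | semantic-similarity decay per ontology level (the standard value for the Wang measure) |
| SDNE `alpha` | 0.05 | first-order loss weight |
| SDNE `beta` | 5 | reconstruction penalty on observed edges (must be > 1; 1 would treat zeros and edges alike) |
| SDNE `nu` | 1e-4 | L2 weight penalty |
| SDNE `epochs`, `lr` | 200, 1e-3 | Adam, full batch up to `batch_size` = 256 nodes |
| `n_estimators` | 350 | random-forest size |
| `train_neg_ratio` | 1 | training negatives per positive (balanced) |

SDNE optimisation settings are recorded defaults rather than published
values: the embedding method's original description leaves them to its
implementation, so we fixed one conventional configuration (Glorot
initialisation, Adam, sigmoid activations, seed 0) and kept it.

## The synthetic world

Real inputs (miRNA-PCG, disease-PCG, PCG-PCG, association, ontology, family
tables) come from large curated databases that cannot be bundled. The
package therefore ships a seeded generator, `simulate_world()`, whose
defaults are the study conditions used by the tests: 200 PCGs, 50 miRNAs,
30 diseases, 3 disease categories, mean PCG out-degree 4, 15 signal PCGs
per category, background link density 0.05, label noise 0.05.

The planted mechanism mirrors the modelling premise that miRNA-disease
relevance is mediated by shared PCG neighbourhoods: each category owns a
disjoint set of signal PCGs; its diseases link them with high confidence
scores (U(0.6, 1)) over a low-score background (U(0, 0.4)); its miRNAs link
them as binary interactions; a pair is associated exactly when the latent
categories match, then flipped with probability 0.05. The ontology has one
root per category with diseases as leaves (roots start at C02 so the flat
synthetic categories stay out of the infection branch, which the labeler
treats as having one extra level), and miRNAs of one category share one
family.

What the generator does *not* emulate: scale (two to three orders of
magnitude fewer entities than the curated databases), heavy-tailed degree
distributions (Poisson out-degree only matches the mean), correlated
noise, multi-category diseases, and incomplete profiles. The last point
matters for interpretation: because every entity links *all* of its
category's signal PCGs, message passing cannot demonstrate its real-data
role of recovering missing direct links — its enrichment here adds
one-hop context that is largely redundant with an already-complete signal,
so ablating it moves performance very little in either direction. Passing
tests therefore show correctness of each stage and end-to-end recovery of
a planted signal, not real-data effect sizes.

## Numerical choices and edge cases

- Propagation is implemented as one sparse operator product per iteration;
  a matrix row and the per-profile path agree to 1e-12, and the per-node
  rule is cross-checked against a literal brute-force evaluation in tests.
  Unknown nodes with no parents are 0 by the empty-sum convention, never
  `NaN`; known entries are restored bit-identically after every step.
- ReliefF uses Manhattan distance on range-normalised features (profiles
  are continuous after enrichment); constant features have zero diff by
  convention; neighbour ties break by sample index, so with `n_samples =
  all` the weights are deterministic and permutation-invariant. Rankings
  break weight ties by feature index.
- Association scores already inside [0, 1] pass through; a table with any
  score outside is min-max rescaled (the minimal assumption, since curated
  confidence scores are natively unit-scaled); duplicate records keep the
  maximum weight.
- Semantic similarity of a disease absent from the ontology is 0 to every
  other disease and 1 to itself; similarity feature rows are computed
  against the fixed training disease set, so new diseases get features
  from their ontology position alone.
- SDNE aborts with diagnostics on non-finite loss; embeddings of entities
  absent from the training graph are zero vectors by contract.
- MCC is defined as 0 when its denominator vanishes, matching the
  degenerate all-positive predictor convention (SN 1, SP 0, ACC 0.5 on
  balanced data); precision and F1 are likewise 0 on empty denominators.
- Average precision is the discrete sum over the descending-score sweep
  with tied scores entering as one group — no precision-recall
  interpolation.

## Design choices where the design was open

- **Training negatives** are sampled uniformly from unlabeled pairs *within
  the training entity universe*. Sampling from all entities would leak the
  split: held-out diseases would enter training as guaranteed negatives and
  the forest would learn to score their embedding signature down.
  Test negatives are sampled within the test entity universe, excluded
  from all known positives, at the configured positive:negative rate.
- **Feature selection is fit on disease profiles only** (the side task is
  disease-category prediction); the selected PCG set is then applied to
  both entity kinds.
- **Edge weights in the heterogeneous graph** are the enriched profile
  values, not binarised; miRNA-disease edges are weight 1; the PCG block
  is the undirected either-direction projection at weight 1 (the embedding
  loss needs a symmetric adjacency).
- **A disease with several ontology positions** takes its category from the
  lexicographically smallest code — a deterministic, auditable rule.
- The classifier threshold for the confusion-matrix metrics is 0.5.

## Problem sizes used by the tests

The shipped test-suite and the acceptance script run the generator defaults
(200 PCGs / 50 miRNAs / 30 diseases), chosen so a full pipeline run —
enrichment, selection, embedding (200 epochs), forest — takes seconds on a
laptop core while leaving the planted structure statistically recoverable:
transductive held-out AUC is typically 0.91-0.97 and new-disease inductive
AUC 0.92-0.98 under these conditions (the tests assert the looser floors
0.80 / 0.65 over ten seeds).

## Known limitations

- The embedding is transductive at heart: scoring a disease added after
  training requires rebuilding the heterogeneous graph (its PCG edges must
  be present at training time) or accepting the zero-vector fallback.
- ReliefF is quadratic in the number of diseases; for ontology-scale label
  sets one would subsample instances (`n_samples`).
- With very small or very imbalanced category labelings the side task
  degrades gracefully (classes below `k_neighbors`+1 use what they have),
  but a single surviving category is a hard error — by design, since the
  selector is meaningless there.
- Scores from the forest are probabilities under the balanced training
  prior; at test rates of 1:5 or 1:10 the ranking metrics (AUC, AP) remain
  meaningful while thresholded metrics shift with the prior, as expected.
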