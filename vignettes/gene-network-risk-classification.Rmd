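---
title: "Classifying disease-risk genes on a protein interaction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying disease-risk genes on a protein interaction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(generisk)
```

## The problem

Curated disease-gene catalogues such as SFARI Gene score each listed gene by
the confidence of its association with autism spectrum disorder (1 = highest
confidence, 3 = lowest) and flag genes whose mutations produce a recognizable
syndrome. Most genes, however, are in no catalogue at all. Because risk genes
tend to interact with each other, a protein interaction network (PIN) carries
signal about unlisted genes, and a gene's cytogenetic address (its chromosome
band, e.g. `7q22`) carries complementary positional signal: several loci are
recurrently implicated.

`generisk` frames gene prioritization as node classification on the graph
`G = (V, E, C)`: nodes are genes observed in the human-filtered PIN, edges
are reported interactions, node features are one-hot (or multi-hot)
chromosome-band indicators, and labels come in three tasks:

* **binary** — catalogued (any confidence score) vs. not;
* **multiclass** — no association / low / moderate / high association, where
  score 1 maps to *high*, 2 to *moderate*, 3 to *low* (scores are ordered
  most- to least-confident);
* **syndromic** — syndromic flag vs. not.

## Models

All four classifiers share the shape: two representation layers with a ReLU
between them, a linear head, and a log-softmax output trained with the
negative log-likelihood.

**GCN.** Each propagation layer computes
$h_v^{(l+1)} = \sigma\!\big(\textstyle\sum_{u \in N(v)} \tfrac{1}{c_v} W^{(l)} h_u^{(l)}\big)$.
The package defaults to the standard practical variant — self-loops added and
symmetric normalization $c_{vu} = \sqrt{\deg v \cdot \deg u}$ — because the
literal rule discards a node's own features; `normalization = "row"`,
`self_loops = FALSE` gives the literal form, and both are tested against a
brute-force per-node oracle.

**GraphSAGE.** The mean-aggregated neighborhood is concatenated with the
node's own embedding before the linear transform:
$h_v^{(l+1)} = \sigma\!\big(W^{(l)} [\, h_v^{(l)} \,\|\, \mathrm{mean}_{u\in N(v)} h_u^{(l)}\,]\big)$.
A sum aggregator is available; LSTM aggregation is not implemented.

**Graph transformer.** All-pair attention
$z_u^{(k+1)} = \sum_v \frac{\exp(q_u^\top k_v)}{\sum_w \exp(q_u^\top k_w)} v_v$
in its exact dense form, and the kernelized linear-cost form
$z_u^{(l+1)} = \frac{\phi(q_u)^\top \sum_v \phi(k_v) v_v^\top}{\phi(q_u)^\top \sum_w \phi(k_w)}$
in which the two global sums are computed once and shared across nodes. The
default feature map $\phi$ is the positive random-feature approximation of
the exponential kernel, $\phi(x) = m^{-1/2}\exp(Wx - \|x\|^2/2)$ with
$W_{ij} \sim N(0,1)$ drawn once per layer from a derived seed; an `elu+1`
map is available, and a user-supplied $\phi$ (e.g. a truncated closed-form
kernel expansion) is accepted by the exported layer function. Tests verify
that the kernelized layer equals dense attention exactly for a single node,
matches it through the closed-form 1-D exponential-kernel map, and converges
monotonically as the random-feature count grows.

Two departures from the bare equations are deliberate. First, attention here
is *attention-only*: no relational (adjacency) bias term is added, so the
transformer sees graph structure not at all — it is effectively a set model
over featurized nodes, which is also why its featureless ablation is the
weakest configuration. Second, by default queries and keys are
L2-normalized and divided by a temperature ($\tau = 0.25$, so logits lie in
$[-4, 4]$), a practice of the kernelized graph-transformer lineage this
model follows. Without it, one-hot band features under Glorot initialization
give attention logits with a standard deviation of about $0.03$: attention
is then numerically uniform, every node receives the same global average,
and because the classes are balanced the gradient of every layer is ~0 — the
model provably sits at chance indefinitely (the AdamW epsilon of $10^{-4}$,
large relative to these gradients, removes the rescaling that would
otherwise compensate). `qk_norm = FALSE` restores the literal equations.

**MLP baseline.** Three dense layers on the band features alone; the
adjacency is ignored. It isolates how much the network structure itself
contributes.

**Featureless ablations.** Each graph family can be run with the band
features replaced by a sparse identity surrogate (one indicator per node),
so the model can only exploit connectivity (or, for the transformer,
nothing). Comparing featured with featureless variants measures the value
of the chromosome-band features.

## Class balancing on the graph

The catalogued classes are severely imbalanced (about 214 : 530 : 69 :
11,403 at reference scale). Before training, each minority class is
upsampled to the majority count by sampling source nodes with replacement;
each duplicate copies its source's feature row and inherits exactly its
source's adjacency row and column (duplicates link to their source's
neighbors, not to the source or to each other — the equations place a
node's information in its neighborhood, and the source's neighborhood is
what a faithful copy needs). A GraphSMOTE-style `interpolate` mode instead
blends the duplicate's features with a random same-class neighbor.

The default split protocol is *split after upsampling* (stratified 25% test),
which mirrors the experimental protocol this package reproduces. Its known
caveat: duplicates of one gene can land on both sides of the split, so test
metrics are optimistic about truly novel genes. A leakage-safe
`before_upsample` protocol is provided and recommended for real
prioritization work: originals are split first and only training nodes are
duplicated. `evaluate()` additionally reports originals-only metrics under
either protocol.

## Training regimen

Defaults follow the study regimen: AdamW (learning rate $10^{-3}$, weight
decay $5 \times 10^{-4}$, epsilon $10^{-4}$), log-softmax + NLL, 5000
epochs. "Batch size 64" is honored where it is meaningful: the MLP trains on
shuffled minibatches of 64 rows, while the message-passing families train
full-batch (a graph layer needs the whole adjacency; the flag is ignored
there). Hidden width defaults to 64. Training runs in a compiled
(RcppArmadillo) engine; a pure-R reference engine implements the identical
updates, the two agree to ~1e-15 on loss traces and parameters, and every
family's gradient is checked against central finite differences. All
randomness (initialization, random attention features, minibatch order,
splits) derives from a single seed via fixed stage offsets, so every run is
exactly reproducible.

## The synthetic cohort generator

No accession is available for the original SFARI/PIN snapshots, so the
package ships a generator that emulates their statistical structure and
writes the exact two delimited files the ingest functions consume:

* class sizes in the reference ratio 214 : 530 : 69 : 11,403 scaled to
  `n_genes`, and a syndromic flag count scaled from 169 / 12,216 (80% of
  syndromic genes drawn among risk genes, mirroring the catalogue's overlap);
* a 471-band vocabulary; a risk gene draws its band from a risk-enriched
  subset covering 10% of the vocabulary with probability `band_signal`
  (default 0.8) — a caricature of reported locus enrichment, not a model of
  cytogenetics;
* edges from a degree-corrected planted partition: lognormal degree
  propensities (`theta_sd = 0.75`) give the heavy-tailed hubs typical of
  PINs; pairs in the *same risk class* have their edge rate multiplied by
  `homophily` (default 5); expected mean degree 20. Sampling is by Poisson
  block counts with endpoints drawn proportional to propensity, so
  generation is linear in the edge count;
* 5% decoy interactions labeled with non-human species, exercising the
  human filter.

Every gene appears in the gene table with its true band (score empty for
non-risk genes). This matters: if only catalogued genes had known bands, the
unknown-band indicator would leak the binary label outright and the
featureless/featured and MLP/SAGE contrasts would be meaningless.

The generator's degree distribution and homophily are stipulations — the
real datasets' values are unreported — so passing model-ordering checks on
synthetic cohorts shows the pipeline recovers *planted* signal of this kind,
not that it reproduces any particular dataset's accuracies. The accuracies
reported for the original SFARI/PIN analysis (85.80% binary, 81.68%
multi-class, 90.22% syndromic) required data snapshots that were never
deposited; they are external reference points, not results this package
computes or claims.

## The model-ordering study

`run_ordering_study()` regenerates, per seed, a 1,222-gene cohort
(`band_signal = 0.8`, `homophily = 5`), builds and balances the binary-task
graph, splits after upsampling, trains all seven variants (four families
plus three featureless ablations) for 200 epochs — the quick profile, also
used by the pipeline's CI configuration; full runs use 5000 — and records
upsampled-test accuracy. Across 20 seeds the study checks the qualitative
conclusions the reproduced analysis reports: GraphSAGE beats the MLP
baseline, and every featured graph model beats its featureless ablation,
each with a one-sided paired sign test at the 5% level. The binary task is
used because, at this cohort size, it runs in minutes while expressing both
planted signals (bands separate risk from none; homophily makes risk
neighborhoods distinctive); the multiclass task balances to ~4× the nodes
for the same information.

## Numerical choices and degenerate inputs

* ROC curves sweep every observed score as a cutoff; tied scores collapse to
  one operating point, and the trapezoid AUC is tested to equal the
  rank-statistic (concordance) AUC to 1e-9. The operating threshold
  maximizes Youden's J with ties broken toward higher specificity.
* One-vs-rest specificity/sensitivity for multiclass; classes absent from a
  test set report `NA`, never 0. F1 is the positive-class F1 for the two
  binary tasks and macro-F1 for multiclass; both are always available.
* Isolated nodes without self-loops receive a zero message (logged once),
  not an error. Empty classes cannot be upsampled. A degenerate kernelized
  denominator (all φ mass ~0) aborts rather than dividing.
* t-SNE (exact, O(n²), perplexity calibrated per point by binary search,
  early exaggeration, adaptive gains) is implemented in the package and
  refuses fewer than 3 × perplexity points. It is meant for the few-thousand
  node graphs this package targets.
* `upsample()` on an already balanced graph is the identity (empty origin
  map). Rebuilding a graph from its own plain-text dump reproduces it
  exactly, and a second dump is byte-identical.

## Limitations

Band features are treated as opaque categories (no cytogenetic distance),
exact symbol matching only (no HGNC alias resolution), no mini-batched or
multi-head attention, no hyperparameter search. The synthetic generator
plants pairwise class homophily and a single enriched band subset; real
interaction data has richer structure (complexes, pathway modularity,
study-bias hubs) that these cohorts do not emulate, so synthetic results
bound what the pipeline can detect, not what real data contains.
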