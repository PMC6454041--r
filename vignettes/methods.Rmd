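---
title: "Network embeddings, autoencoder compression and SVMs for disease-gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network embeddings, autoencoder compression and SVMs for disease-gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Most disease genes are discovered one costly experiment at a time, while
protein–protein interaction (PPI) networks encode a cheap, global prior:
under the guilt-by-association hypothesis, genes causing the same disease
cluster in the same network neighbourhood. `n2asvm` turns that prior into a
ranking of candidate genes in three stages.

**Stage 1 — biased random-walk embeddings.** A second-order random walk
explores the network. With the walker at node $v$, having arrived from node
$t$, the unnormalized probability of stepping to a neighbour $x$ of $v$ is

$$\pi_{vx} = \alpha_{pq}(t, x)\, w_{vx}, \qquad
\alpha_{pq} = \begin{cases}
1/p & d_{tx} = 0\\
1 & d_{tx} = 1\\
1/q & d_{tx} = 2
\end{cases}$$

where $w_{vx}$ is the edge weight and $d_{tx} \in \{0, 1, 2\}$ is the
shortest distance from $t$ to $x$ (necessarily at most 2, because $x$ is
adjacent to $v$). The return parameter $p$ penalizes immediate
backtracking; the in-out parameter $q$ interpolates between a BFS-like
local exploration ($q > 1$) and a DFS-like outward drift ($q < 1$). Since
$x$ is a neighbour of $v$, $d_{tx}$ can be decided locally: $0$ iff
$x = t$, $1$ iff $\{t, x\}$ is an edge, else $2$ — no global shortest-path
computation is needed. The first move of a walk, which has no previous
node, uses the first-order distribution $w_{vx} / \sum_x w_{vx}$; this is
the convention of the node2vec construction the sampler follows.

Skip-gram with negative sampling (SGNS) is then trained on the walk
corpus: for every (center, context) pair within a window along a walk, the
objective
$\log \sigma(u_c \cdot v_{ctx}) + \sum_k \log \sigma(-u_c \cdot v_{neg_k})$
is maximized by SGD, with negatives drawn from the unigram distribution
raised to the power 0.75. The input (center) vectors are the exported gene
representation. Genes that share network neighbourhoods co-occur on walks
and end up geometrically close.

**Stage 2 — autoencoder compression.** The embedding $x \in \mathbb{R}^n$
is compressed to a code $y \in \mathbb{R}^m$ ($m < n$) by an
encoder/decoder pair trained by mini-batch gradient descent to minimize
the mean squared reconstruction error $\lVert x - z \rVert^2$. The decoder
mirrors the encoder widths in reverse; hidden layers are sigmoid by
default and the output layer is linear.

**Stage 3 — maximum-margin classification.** Known disease genes are the
positive class; an equal-sized uniform sample of the remaining genes forms
the negative class. An RBF-kernel SVM is trained on the code vectors and
evaluated by stratified ten-fold cross-validated AUROC, which equals the
Mann–Whitney statistic (probability that a random positive outranks a
random negative, ties counted half). For prediction, the model is refitted
on all labeled genes, a sigmoid (Platt) calibration is fitted on
cross-validated decision values, and every unlabeled gene is ranked by its
calibrated probability.

Three baselines share the evaluation protocol, each oriented so that
larger score = more disease-like: random walk with restart (RWR; the mean
over positives of the candidate's entry in each positive's diffusion
state), shortest-path length (SPL; negated mean BFS distance to the
positives), and Euclidean distance (ED; negated mean distance between
binary adjacency rows). Two ablations isolate the stages: N2V-SVM feeds
the raw embeddings to the SVM, RWA-SVM replaces the embeddings with RWR
diffusion-state rows before the autoencoder.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `p` | 2 | return penalty; larger = fewer immediate backtracks |
| `q` | 0.1 | in-out bias; < 1 explores outward (DFS-like) |
| `walk_length`, `walks_per_node` | 80, 10 | corpus size per gene |
| `dimension` | 512 | SGNS embedding width |
| `window`, `negatives`, `epochs` | 10, 5, 5 | SGNS training |
| `layer_sizes` | 512 → 200 | encoder widths; code = 200 |
| `restart_prob` | 0.5 | RWR restart probability |
| `kernel`, `C`, `gamma` | rbf, 1, scale | SVM; `gamma = 1/(d \cdot var(X))` |
| `k` | 10 | stratified CV folds |

The defaults target interactome scale (order $10^4$ genes): 512-dim
embeddings compressed to a 200-dim code, which is where a code-size sweep
plateaus on such networks, and $(p, q) = (2, 0.1)$, the first point of the
usual sweep grid ($p \in \{2, 20, 200\}$, $q \in \{0.1, \dots, 10^{-4}\}$,
available via `cmd_evaluate(..., sweep = TRUE)`). Walk length 80 and 10
walks per node are the standard node2vec reference settings. The RWR
restart probability, SVM kernel and cost are conventional midpoints, all
exposed through `run_config()`.

`demo_config()` is the package's reference setting for the bundled
300-gene planted fixture: 5 walks of length 40 per node, 64-dim SGNS
(window 5, 3 epochs), a 64→16 autoencoder (150 epochs, learning rate
0.01), and $q = 0.5$ (on a 3-block graph the outward drift saturates
quickly, so a milder bias suffices). A 512→200 architecture on 300 points
would be badly over-parameterized; the demo sizes keep the variance of the
fold AUROCs low while exercising every stage.

## What the synthetic generator emulates — and what it does not

`planted_partition()` draws a stochastic block model: blocks of 60/120/120
genes, within-block edge probability 0.15, between-block 0.01, with 30
"known" disease genes sampled from block 1 and the remaining 30 block-1
genes held out as undiscovered truth. This embodies exactly the
guilt-by-association premise — a single dense disease module — and gives
every stage a measurable target (the suite requires seed-averaged
ten-fold AUROC ≥ 0.9 for the full pipeline, a chance-level AUROC after
label shuffling, and ≥ 7 of the top 10 predictions drawn from the held-out
truth).

Real interactomes differ in ways the fixture deliberately ignores:
heavy-tailed degree distributions, overlapping and nested pathways,
disease genes scattered over several weak modules, study bias in edge
ascertainment, and three orders of magnitude more nodes. Passing the
planted tests therefore demonstrates that the machinery is correct and
that it recovers a clean module signal — not that it attains any
particular AUROC on a real PPI network, where the signal is far weaker.

## Numerical and design choices

* **Walk sampling.** Node order is sorted and a single seeded RNG stream
  drives all draws, so a corpus is byte-reproducible. Alias tables give
  O(1) categorical draws; per-state second-order distributions are built
  on the fly (precomputing one table per directed edge trades memory for
  speed and is unnecessary at these scales). Only isolated nodes terminate
  a walk early — in a simple undirected graph the walker can always step
  back.
* **SGNS.** Input vectors start uniform in $[-0.5/d, 0.5/d]$, context
  vectors at zero; the learning rate decays linearly to 1% of its initial
  value over the total pair count; training is single-threaded so the same
  seed gives bit-identical embeddings. No frequent-word subsampling: walk
  corpora visit nodes far more uniformly than natural text. A negative
  sample equal to the context word is skipped.
* **Autoencoder.** Glorot-uniform initialization from the seeded stream;
  plain mini-batch gradient descent with a fixed learning rate (no
  adaptive optimizer — fewer moving parts, exact reproducibility); loss
  trace recorded per epoch and non-finite loss reported as a training
  error with its epoch. On data lying exactly in a $k$-dim subspace, the
  linear autoencoder with code $k$ reaches the principal-component
  truncation error to numerical precision — the test suite enforces this
  against an eigendecomposition oracle.
* **RWR.** Power iteration on the column-stochastic operator with L1
  stopping (default 1e-10); agrees with the direct linear solve to 1e-8.
  An isolated source returns the indicator vector exactly: every restart
  puts all mass back on the source.
* **SPL.** Unweighted BFS distances; a positive unreachable from the
  candidate contributes (diameter of the candidate's component + 1),
  keeping scores finite and rank-meaningful. The candidate is excluded
  from its own positive-distance mean. Mean aggregation is used for both
  SPL and ED (min available via argument) for symmetry between the two
  path-based scores.
* **ED.** Defaults to binary adjacency rows as the gene representation;
  any feature matrix (e.g. embeddings) can be substituted.
* **Classification.** Stratified folds (plain ten-fold on a 2×178-sized
  balanced set risks single-class folds); decision values, not
  probabilities, feed the fold AUROCs; ranking probabilities come from a
  Platt sigmoid fitted on cross-validated decision values, so calibration
  never sees its own training scores. Ranking ties break lexicographically
  by gene id. Negative sets are resampled per repetition in
  `cmd_evaluate(..., repetitions = R)`, since one negative draw is
  high-variance.
* **Seeds.** Every stage seed is derived as a polynomial hash of
  (master seed, stage name), so one integer reproduces a whole run and
  stages remain independently reproducible.
* **Degenerate inputs.** Self-loops are dropped with a warning (the
  $d_{tx}$ semantics assume simple graphs); duplicate edges keep the first
  weight seen and warn on conflicts; gene identifiers are opaque strings,
  and positives are intersected with the graph before anything else runs.

## Evaluation protocol on the planted fixture

The suite and `scripts/acceptance.R` run the problem sizes stated above:
the default 300-node fixture for the end-to-end checks (5 master seeds),
500×32 exact-rank data for the autoencoder/PCA comparison, random 30–100
node graphs for the RWR, SPL, AUROC and alias-sampler oracle checks. The
baselines are evaluated on the identical positive/negative gene sets used
by the classifier, scored with the candidate excluded from its own
positive set.

## Known limitations

* The pipeline ranks genes already present in the PPI network; genes
  without interactions cannot be scored (isolated nodes embed from
  length-1 walks, i.e. essentially at random).
* Negative sampling treats all non-positive genes as negative; true
  undiscovered disease genes in the negative sample bound the attainable
  AUROC below 1 by construction.
* The autoencoder uses a fixed epoch budget rather than early stopping;
  reproducibility is exact but the epoch count is a tuning knob on new
  data.
* No identifier mapping layer is provided: edge lists and gene sets must
  already share a namespace.
* Multi-threaded SGNS training is deliberately absent; determinism is
  prioritized over speed at the scales the package targets.
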