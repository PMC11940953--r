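---
title: "Methods: random-walk embeddings with distance-weighted neighborhood aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-walk embeddings with distance-weighted neighborhood aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkaggr)
```

# The model

`walkaggr` learns unsupervised node representations for downstream node
classification (e.g. protein-function prediction on protein–protein
interaction networks, community membership in social networks). The
pipeline is strictly feed-forward, in five stages.

**1. Self-representational vectors.** Truncated random walks (uniform
next-step choice) sample node sequences; skip-gram with negative sampling
over those sequences yields one vector $r_v \in \mathbb{R}^{d}$ per node
($d$ = 128 by default). Nodes that co-occur on short walks — i.e. nodes
that are structurally close — end up close in embedding space. This stage
captures *global* structure but is known to under-use the immediate
neighborhood.

**2. Neighbor weighting.** For a center $u$ with one-hop neighbors
$n(u)$, the Euclidean distances $d_{uv} = \lVert r_u - r_v\rVert_2$ are
computed in the frozen embedding. Weights $\alpha_{uv} > 0$,
$\sum_v \alpha_{uv} = 1$, come from one of:

* the **closed-form (non-learning) rule**: distances are
  sigmoid-normalized, $d'_{uv} = 1/(1+e^{d_{uv}})$ (mode `N`, closer ⇒
  heavier) or $d'_{uv} = 1/(1+e^{-d_{uv}})$ (mode `F`, farther ⇒
  heavier), then passed through a softmax
  $w_{uv} = e^{d'_{uv}} / \sum_j e^{d'_{uj}}$. Note the mode-`N`
  normalizer actually maps nonnegative distances into $(0, 0.5]$ rather
  than the full unit interval; we implement the formula exactly as
  defined and treat the "(0,1)" description as nominal.
* **one-head / multi-head self-attention** trained on a
  *distance-regression* task: the input matrix $I$ stacks the center row
  and its (zero-padded) neighbor rows; per head,
  $\mathrm{softmax}(QK^\top/\sqrt{d_k})V$ with
  $Q = IW_Q$, $K = IW_K$, $V = IW_V$ and $d_k = d/h$; multi-head output
  concatenates the $h$ heads and mixes them with $W_{out}$. The attention
  output (padded rows zeroed, flattened row-major) feeds a three-layer
  MLP of sizes $(n d,\; n d/2,\; n{-}1)$, $n = 1 + $ `maxNeighbors`,
  whose $n-1$ outputs estimate the center–neighbor distances; training
  minimizes the masked mean squared error $(d' - d)^2$. No labels are
  involved — the geometry of the embedding is the supervision signal.
  The per-context weights are the center row of the head-averaged
  attention matrix ($\alpha = \tfrac1h\sum_i \alpha_i$), with the self
  and padded columns dropped and the rest renormalized.
* **hybrid policies** (`1H+N`, `MH+N`): attention for nodes of full
  degree ≤ `degreeThreshold`, the closed-form `N` rule above that
  cutoff. This keeps attention tractable on hub-heavy networks.

**3. Weighted aggregation.** The local representational vector is the
convex combination $r'_u = \sum_{v \in n(u)} \alpha_{uv} r_v$; with
uniform weights it reduces to the plain neighborhood mean.

**4. Fusion.** Per node, self and local vectors are concatenated (self
first) to a $2d$ row, columns are mean-centered (not variance-scaled:
both halves already live on comparable scales), and the matrix is
projected onto its top `outDim` = $d$ principal components, returning to
a single unified $d$-dimensional space.

**5. Evaluation.** Repeated random splits (default 10 repeats at
training proportions 0.2–0.8), one L2-regularized logistic regression
per label (one-vs-rest), Micro-F1 pooled over all label decisions.
Single-label data take the arg-max label; multi-label data take each
test node's top-$k_i$ labels with $k_i$ its true label count — the
standard convention for this protocol, without which multi-label
Micro-F1 values are not comparable across methods.

# Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `dim` (`dModel`) | 128 | embedding width; all comparisons run at the same width |
| `walksPerNode`, `walkLength` | 80, 40 | the original DeepWalk sampling budget |
| `window` | 10 | skip-gram context radius (walk positions) |
| `sgEpochs`, negatives | 5, 5 | standard SGNS training budget |
| `maxNeighbors` | 10 | neighbor cap; also sets the attention input size $n = 11$ |
| `heads` | 4 | multi-head count; $d/h$ must divide exactly |
| `attnEpochs`, `learningRate`, `batchSize` | 100, 1e-3, 32 | Adam on the distance regression (unstated upstream; chosen as the standard adaptive first-order setting and logged) |
| `degreeThreshold` | `maxNeighbors` | hybrid dispatch cutoff; the substitution is motivated by "large" degree, never given a number, so the neighbor cap is reused |
| `lambda` | `1/|train|` | ridge strength of the one-vs-rest classifier (the common unit-C setting) |

# Design choices where the design was open

* **Weight extraction.** Which attention entries become $\alpha_{uv}$ is
  under-determined; we use the center node's row restricted to neighbor
  columns, renormalized — the only row that relates the center to every
  neighbor.
* **Padding.** Variable degree is handled by zero-padding contexts to
  `maxNeighbors` rows, masking padded keys to $-\infty$ before the
  softmax and excluding padded slots from the loss. Padded slots provably
  receive zero weight.
* **One model, not one per node.** The MLP input size depends on $n$, so
  contexts are padded to a fixed size and a single global model is
  trained.
* **MLP input.** The attention-transformed value matrix (flattened) is
  fed to the MLP; feeding raw weights is a possible alternative reading,
  not taken.
* **Neighbor truncation.** Degrees above `maxNeighbors` are reduced by a
  seeded uniform sample without replacement, drawn once per run.
* **PCA sign rule.** Each component's sign is fixed so its
  largest-absolute loading is positive, making fusion bit-deterministic.
* **Degree-0 nodes** keep their own self vector as the local vector
  (identity fallback, warned); they never enter classifier splits unless
  labelled.
* **Splits** are unstratified uniform draws; `|train| = round(pN)`;
  repeat $r$ uses seed `base + r`.

# What the synthetic generators emulate

Real benchmark networks for this task are external downloads, so the
package ships seeded generators instead:

* `sbmGraph()` — planted partition: near-equal blocks, within-block edge
  probability `pIn`, cross-block `pOut` (strictly `pOut < pIn`); block
  identity is the single label. This emulates assortative
  community-labelled networks at desk scale.
* `multilabelGraph()` — overlapping memberships: each node draws 1–3
  labels; sharing a label lifts the pair's edge probability from `pOut`
  to `pIn`. `pIn == pOut` degenerates to a label-independent
  Erdős–Rényi graph, useful as a null.

The default fixture used in the end-to-end checks is $n = 300$, 3
blocks, `pIn` = 0.05, `pOut` = 0.005 (mean within-degree ≈ 5, cross ≈
1) — a sparse, strongly assortative graph.

What these fixtures do **not** emulate: degree heterogeneity (hubs),
labels only partially aligned with topology, label noise, and the
10³–10⁴-node scale of the real benchmarks. A green directional test on
the fixture therefore establishes that the pipeline's machinery behaves
as specified — not that the real-data rankings are reproduced. One
consequence worth stating plainly: on a *purely* homophilous planted
partition the label signal is entirely topological, so the smoothed
local-only embedding can match or slightly exceed the fused one; the
advantage of fusing self and local views materializes when the two views
carry complementary information, as on real networks. The package's
end-to-end checks therefore primarily assert the full-pipeline ≥
bare-embedding direction.

# Numerical and reproducibility notes

* Walk simulation and SGNS run single-threaded with a self-contained
  xorshift64 generator: a fixed seed gives bit-identical corpora and
  embeddings across platforms. R-level stages use R's RNG under a
  save/restore wrapper, so library calls never disturb the caller's RNG
  state.
* Attention backpropagation is analytic (verified against central
  differences in the test suite) and optimized by Adam
  ($\beta_1 = 0.9$, $\beta_2 = 0.999$); a non-finite loss aborts with a
  learning-rate diagnostic.
* Weight vectors validate $\sum w = 1$ within $10^{-9}$; aggregation
  checks weight/neighbor alignment within $10^{-6}$ before combining.
* Time scaling: SGNS cost is linear in
  `walksPerNode × walkLength × window × epochs`. The packaged end-to-end
  tests and `scripts/acceptance.R` run the n = 300 fixture with a reduced
  budget (20 walks/node, 3 epochs) so the whole suite fits a small
  single-CPU time box; the API defaults remain the full DeepWalk budget.

# Known limitations

* Only one-hop neighborhoods are aggregated; multi-hop aggregation is
  out of scope.
* The base embedder is replaceable only via the text embedding format
  (`embeddingFile =`); alternative embedders (LINE, node2vec, SDNE) are
  not implemented.
* Attention training is pure R and sized for desk-scale graphs
  (hundreds to low thousands of contexts); hub-heavy graphs should use
  the hybrid policies.
* Autoencoder or ICA fusion variants are not provided; PCA only.
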