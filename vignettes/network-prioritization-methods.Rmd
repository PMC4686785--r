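---
title: "Concordance-weighted shortest-path prioritization of disease genes"
author: "neri package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concordance-weighted shortest-path prioritization of disease genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neri)
```

## The problem

Candidate disease genes are routinely prioritized by walking a
protein-protein interaction (PPI) network outward from *seed* genes with
prior evidence (e.g. GWAS hits). Purely topological methods — random walks
with restart, degree-aware variants — inherit the network's *ascertainment
bias*: well-studied proteins accumulate recorded interactions and float to
the top regardless of disease relevance. This package implements a method
that couples the network to two-condition (control/disease) expression data
and ranks genes by how much their coexpression with the seed neighborhood
*changes* between conditions, which a topology-only score cannot see.

The method rests on three network-medicine hypotheses: disease-gene products
cluster in a network region (disease module), genes of similar diseases
interact directly (local hypothesis), and shortest paths between disease
genes trace disease pathways (network parsimony).

## The procedure

1. **Integration** (`read_edge_list`, `merge_edge_lists`,
   `aggregate_transcripts`, `integrate_network`). PPI edge lists are merged
   by set union; transcript-level expression is collapsed to genes by the
   per-sample median; the network is restricted to genes with expression in
   both conditions and then to its largest connected component.
2. **Neighborhood** (`grow_seeds`, `build_pathsets`). The seed set $S$ is
   grown to $S \cup N$, $N$ the seeds' direct interactors. For every ordered
   pair $(s \in S,\; t \in S \cup N,\; s \neq t)$ *all* shortest paths are
   enumerated from the BFS geodesic DAG in deterministic lexicographic
   order.
3. **Path selection** (`w_max`, `select_paths`). Each path is scored by
   $W_{max}$ — Kendall's coefficient of concordance $W$ among the path
   genes' expression profiles, maximized over all $2^{m-1}$ per-gene profile
   inversions so that coordinated up- and down-regulation count equally. Per
   pair, the paths with $W_{max}(P) \ge (1-\varepsilon)\,W_{max}(P^{*})$ are
   kept (tied with the best path $P^{*}$); selection is done independently
   under each condition's samples.
4. **Scoring** (`sigma_scores`). Per condition,
   $$\sigma(g) \;=\; \sum_{s,t}\;\sum_{P \in P^{*}_{st}}
     \lambda^{-d_{sg}}\; W_{max}(P)\; \mathbf{1}[g \in P],$$
   with $d_{sg}$ the graph distance from the pair's seed to $g$ on the full
   integrated network. $\sigma$ blends closeness (the decay), betweenness
   (path membership counts) and coexpression ($W_{max}$).
5. **Differential analysis** (`compute_xdelta`, `fit_powerlaw`,
   `compute_delta_prime`, `rank_and_select`). Writing $X = \sigma_C +
   \sigma_D$ and $\Delta = (\sigma_D - \sigma_C)/X \in [-1, 1]$, the natural
   spread of $\Delta$ shrinks as $X$ grows (the familiar MA-plot intensity
   effect). A power law $f(x) = a\,x^{-k}$ is fitted by log-log least
   squares to the third quartile of $|\Delta|$ in sliding windows along $X$,
   and $\Delta'(g) = \Delta(g) / f(X(g))$ normalizes the alteration. Genes
   are ranked by $|\Delta'|$; the sign records the dominant condition.

`rank_agreement` and `overlap_stats` reproduce the ranking-comparison and
replication-overlap analytics used to contrast such rankings with external
methods and across studies.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `lambda` | 2 | per hop | distance decay in $\sigma$; 2 halves a path's contribution per hop from the seed |
| `epsilon` | 0.05 | fraction | path tie rule; best $W_{max}$ 0.6 admits everything $\ge 0.57$ |
| `w_len` | 2 | $X$ units | sliding window length for the envelope fit |
| `w_step` | 1 | $X$ units | sliding window step |
| `x_ini` | 5 | $X$ units | intensity floor: genes must have $X > 5$ (strictly) to enter the envelope fit and the reported selection |
| `max_path_genes` | 12 | genes | cap on $2^{m-1}$ inversion enumeration |
| `path_cap` | 10000 | paths | per-pair geodesic cap, lexicographically first kept |
| `min_points_per_window` | 5 | genes | window occupancy for the fit (adaptively relaxed, see below) |
| `top_fraction` | 0.1 | fraction | reported selection size |

`lambda` deserves emphasis: it has no published reference value, and results
should always be reported together with it. The default of 2 is a common
choice for hop-decay weights; larger values localize the score around the
seeds, values near 1 flatten the distance penalty.

## Design choices in genuinely open corners

- **Ties in expression.** Mid-ranks with the standard Kendall tie
  correction are used throughout; repeated values are common after median
  aggregation of transcripts. Under mid-ranks, negating a profile before
  ranking and reversing its ranks ($r \mapsto n + 1 - r$) coincide, so the
  inversion in $W_{max}$ is implemented as profile negation. The tie
  structure — hence the $W$ denominator — is inversion-invariant, which is
  also why only the numerator is re-evaluated across the $2^{m-1}$ sign
  assignments.
- **Exact, not heuristic, inversion search.** Shortest paths in sparse PPI
  networks are short ($m$ rarely above 6-7), so exhaustive enumeration with
  the first gene's sign fixed is cheap; `max_path_genes` guards pathological
  inputs. Ties in the maximum resolve to the lexicographically smallest sign
  vector, keeping results deterministic.
- **Ordered pairs.** The double sum runs over ordered $(s, t)$ exactly as
  written, so a seed-seed pair contributes in both directions; $t = s$ is
  excluded (a zero-length path has no concordance). Endpoints belong to
  their paths, and a seed scores its own pairs at full weight
  ($\lambda^{0} = 1$).
- **$d_{sg}$ is the global graph distance**, not the position within the
  path — the score formula references the network metric, and the
  convention matters when both endpoints are seeds.
- **Quartiles.** $Q_3$ uses linear interpolation between order statistics
  (R's default quantile type 7); quartile conventions shift the fit, so the
  choice is fixed and documented. The envelope is fitted to $|\Delta|$ — one
  symmetric envelope for both signs; `envelope = "signed"` fits the two
  sides separately for users who want asymmetric normalization.
- **Window geometry.** Windows live on the raw $X$ axis (not ranks, not
  logs), are $[x_{ini} + i\,w_{step},\; x_{ini} + i\,w_{step} + w_{len})$,
  and are summarized at their midpoints. Windows whose $Q_3$ is zero cannot
  enter the log-log fit and are dropped with a message.
- **Adaptive window occupancy.** On small or sparse problems the $X$ values
  above the floor can be too spread out for 5-point windows to exist; when
  fewer than two windows qualify, the occupancy minimum is relaxed stepwise
  (to as low as one point, with a message) instead of aborting. A hard
  error remains when even single-point windows give fewer than two usable
  summary points.
- **The intensity floor bounds the fit and the reported selection, not the
  score table.** $\Delta'$ is tabulated for every path-covered gene (the
  envelope extrapolates as a power law); rank columns and the default
  selection universe cover only genes above the floor. Benchmark evaluation
  ranks the full scored universe (`rank_and_select(..., universe =
  "scored")`) so that recovery is measured against all candidates — the
  floor's published value is calibrated to intensity scales reached with
  tens of seeds on interactome-sized networks, and on small instances it
  would otherwise leave too few genes to evaluate a ranking at all.
- **Determinism.** Component tie-breaks, path order, ranking tie-breaks and
  output formats are all deterministic: identical inputs and parameters
  give byte-identical outputs.

## The synthetic benchmark

`simulate_benchmark` generates the structure the method assumes, with known
truth labels:

- a connected preferential-attachment network (default 300 genes,
  attachment 2 — exactly $a(n-a)$ edges, heavy-tailed degrees like a sparse
  interactome);
- seeds: the 5 highest-degree nodes. Seed genes with GWAS support sit in
  the well-connected part of real interactomes; uniformly drawn seeds in a
  scale-free graph land in the tree-like periphery, where no seed
  neighborhood exists to analyze;
- a planted module: the 20 most-connected genes within 2 hops of the seeds,
  per the disease-module hypothesis that disease genes form a cohesive
  cluster around the seeds. Randomly chosen peripheral nodes would lie on
  no seed-target geodesic and would be invisible to *any* path-based
  method — the planted truth must be detectable in principle for recovery
  to measure anything;
- expression from a per-condition single-factor model,
  $v = \rho F + \sqrt{1-\rho^2}\,\varepsilon$ (default $\rho = 0.9$, 30
  samples per condition): seeds follow the factor in both conditions,
  planted genes in disease only, and 10 high-degree *decoy hubs* in both
  conditions equally. A shared latent factor produces exactly the monotone
  rank-concordance that $W_{max}$ detects; within-group pairwise
  correlation is $\approx \rho^2$.

The decoys operationalize ascertainment bias: they are engineered to score
high on the intensity axis $X$ (central and coexpressed) while carrying no
differential signal, so a correct $|\Delta'|$ ranking must demote them. The
benchmark's recovery claim — median precision@20 of the $|\Delta'|$ ranking
at least 0.5 across ten generator seeds, with decoys depleted from the
$|\Delta'|$ top-30 relative to the $X$ top-30 — is what
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` recompute.

What the generator does **not** emulate: probe-level microarray noise,
batch effects, correlated background modules unrelated to the seeds,
multi-factor coexpression, or networks at interactome scale (9,000+ nodes,
mean degree above 10, combinatorially many tied geodesics). Passing the
benchmark therefore demonstrates the machinery and its differential
contrast, not field performance on real cohorts.

## Problem sizes and costs

The default benchmark (300 genes, 5 seeds, ~100 path-covered genes) runs in
a few seconds; the ten-seed acceptance sweep completes in well under a
minute. Cost is dominated by per-path $W_{max}$: $O(2^{m-1} m n)$ per path
after rank precomputation, with $m$ the path length and $n$ the sample
count. On interactome-scale inputs the shortest-path cap and
`max_path_genes` bound the worst case; distances are computed once per seed
by BFS and cached.

## Known limitations

- $\lambda$ is a free parameter with no reference value; rankings are
  reported conditional on it.
- With a single expression factor per condition, $W_{max}$ of short noise
  paths is itself sizable (small-sample concordance maxima are biased
  upward), so $\Delta$ of genuinely null genes is noisy at small $X$; the
  envelope normalization compensates only on average.
- The method ranks only path-covered genes: anything off every selected
  geodesic between $S$ and $S \cup N$ receives no score at all.
- Inputs must share a symbol vocabulary; the package intentionally performs
  no identifier mapping beyond upper-casing (a transcript-to-gene table is
  the user's responsibility).
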