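---
title: "Methods: age-annotated functionome networks in efnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-annotated functionome networks in efnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efnet)
```

## The model

`efnet` analyses the coevolution of elementary functional loop motifs and
protein domain superfamilies as an undirected, unweighted bipartite graph:
one node class for loop prototypes, one for SCOP superfamilies, and an
edge wherever a loop is embedded in a domain's structural scaffold.
Proteome hit counts are deliberately *not* used as edge weights — a single
embedding relation is the unit of observation, and weighting would
complicate the interpretation of the projections.

Evolutionary information enters through node ages. Domain superfamilies
carry a relative age `age_nd` in [0, 1] (0 = oldest) read from a
phylogenomic timeline; a calibrated linear molecular clock,
`t = -3.831 * nd + 3.628` (Gy), converts relative to geological age.
Loops have no independent placement on that timeline, so their ages are
inherited from associated domains under one of two schemes:

* `oldest` — the minimum neighbour age (the loop is as old as its first
  scaffold);
* `second_oldest` (default) — the second value of the ascending sort of
  neighbour ages, or the single neighbour's age. This dates the loop to
  the first *transfer* of its function between scaffolds and is the more
  conservative choice, which is why it is the default.

Both schemes are monotone in the neighbour multiset, so ties among equal
ages need no tie-breaking. A loop with no associations cannot be dated: it
keeps `NA`, is excluded from event assignment, and is reported. Connected
domains missing from the age table are an error, never silently imputed.

## Projections and the flow of time

Projecting the bipartite graph onto one class links two loops that share a
domain (they combine in the same scaffold) and two domains that embody a
mutual loop. The projection is simple — one arc per node pair — with the
multiplicity carried as an integer weight equal to the number of shared
counterparts. Arcs are directed from strictly older to younger node; for
contemporary (equal-aged) endpoints the direction is drawn uniformly at
random under the session RNG, so a fixed seed reproduces it exactly, and a
`tiebreak = "lexicographic"` option gives a fully deterministic variant
for testing. Weighted outdegree versus indegree classifies each node as a
donor (source of recruitment), acceptor (sink) or balanced.

Published summaries of such projections sometimes quote per-node average
degrees that cannot be reconstructed from the arc and node counts under
any single convention (arc degree, total degree, or weighted degree). The
package therefore reports all three conventions in
`source_sink_profile()` and the projection summaries rather than forcing
one; the densities, which are unambiguous (`arcs / (n (n - 1))`), are the
quantities checked in the test suite.

## Events and growing networks

Each distinct age value present among dated nodes is one evolutionary
event. The snapshot at an event is the subnetwork induced by all nodes at
least that old; a link first exists at the age of its *younger* endpoint —
forced by first-appearance semantics, since a link cannot predate either
endpoint. Snapshots are therefore nested step functions of time and the
final snapshot is the full dated network; per-event statistics computed on
the last snapshot equal the full-network statistics, which the tests
exploit as a consistency oracle.

Chronological accumulation coarse-grains the timeline into 10 equal-width
age bins (half-open `[l, r)`, last bin closed, bin 1 oldest) and counts,
for every node, arc partners per bin of the partner's age, split by
direction. Links between two equal-aged nodes belong to the same event and
count as intra-event links in the age partition.

## Power-law diagnostics

Two complementary estimates are computed per event:

* **Log–log regression**: OLS of `log P(k)` on `log k` over the support
  with `k > 0`, `P(k) > 0`; gamma is the negative slope and R² the fit
  quality. At least two support points are required; fewer flags the event
  instead of erroring.
* **Discrete MLE**: `P(X = x) = x^-alpha / zeta(alpha, xmin)` fitted by
  numerical likelihood maximisation (alpha searched on (1, 25]). `xmin` is
  fixed at 1 by default: the degree vectors analysed are whole-network
  distributions without tail truncation, and their support is routinely
  discontinuous, so a Clauset-style `xmin` scan — available via
  `xmin = "auto"` — is an option rather than the default. Goodness of fit
  is the Kolmogorov–Smirnov distance between empirical and fitted CDFs
  evaluated on the observed support (with an Euler–Maclaurin tail
  approximation beyond 10^5 so heavy-tailed bootstrap replicates stay in
  bounded memory), and a parametric bootstrap (default 100 replicates:
  simulate from the fitted law, refit, compare KS) supplies the p-value.
  The rejection rule is applied exactly as stated — reject when
  `ks_p < 0.05` or `ks_stat > 0.10` — and surfaced as a boolean.

Degenerate inputs (all degrees equal) and undersized inputs (fewer than 10
nonzero degrees by default) return flagged fits, never exceptions, so
per-event tables stay rectangular. Sampling from the fitted law uses exact
inverse-CDF lookup over a 10^4-term table with a continuous Pareto tail
beyond it.

Reference controls are grown with preferential attachment (one edge per
arriving node, hence trees with clustering coefficient exactly 0) and an
age-dependent variant whose attachment weight multiplies degree by a power
kernel of age rank; the kernel exponent defaults to -1 (older nodes lose
appeal) and is configurable, since the variant's exact kernel is a
modelling choice.

## Modularity

The Newman–Girvan index is evaluated exactly as
`Q = 1/(2m) * sum_ij (A_ij - k_i k_j/(2m)) delta(c_i, c_j)` with weighted
adjacency, weighted degrees and total weight `m`; directed projections are
symmetrized first (the index is defined on undirected weights). The
quality index VQ is computed independently by community-block summation,
`sum_i (e_ii - a_i^2)`. One printed formulation of this sum indexes it
over community pairs `i < j`; the `e`/`a` definitions and the stated
[0, 1] range only cohere under the diagonal-block reading, so that is what
is implemented, with the identity `VQ == NG` on shared partitions serving
as a cross-check in the tests.

Partitions come from four sources: age (one community per event; undated,
necessarily isolated nodes are pooled into one extra community where their
zero degree contributes nothing), fast-greedy agglomeration, walktrap
(walk length 4 — the conventional default, since no other value is
dictated), and `"vos"`, which is similarity-based modularity maximisation
(multilevel Louvain) scored by VQ. True VOS clustering is coupled to a
layout optimiser; this stand-in maximises the same quality measured by VQ,
so community *counts* from VOS runs are not expected to reproduce exactly.

The average clustering coefficient is the mean over nodes of triangles
over connected triples in the simplified graph, nodes of degree < 2
contributing 0. Bipartite graphs have no triangles, so calling it on one
is an error by design. Scaling exponents of `C` against network size and
age are OLS slopes on log–log scale; events with `C = 0` or `nd = 0` are
dropped with a count rather than patched with pseudocounts, which would
manufacture curvature.

Heatmaps use the scaled matrix `(A_ij - k_i k_j/(2m)) * M_nd` with rows
ordered by node age and Ward's minimum-variance linkage on squared
Euclidean row distances.

## The synthetic generator

The original loop–domain mapping is not redistributable, so the generator
emulates its statistical structure: 38 loops, 82 domains, 134 distinct
associations (density 0.043), a disconnected graph with isolated nodes
permitted, hub-dominated loop degrees, domain ages concentrated early, and
founder domains seeding waves at the origin. Concretely:

* non-founder domain ages are Beta(1, 4) on [0, 1] — the simplest
  one-parameter decreasing density, placing most innovation in the first
  half of the timeline; `wave_seeds = 2` founders are pinned at `nd = 0`
  and each receives a first edge, mirroring the two founder structures;
* each remaining edge joins a uniformly chosen domain to a loop chosen
  with probability proportional to `(degree + 1)^attachment_bias`;
  `attachment_bias = 1` (linear preferential attachment, the canonical
  rich-get-richer kernel) is the default, chosen once as the field's
  standard generative assumption;
* loop ages are never sampled — they flow through the age-transfer
  operation, preserving the causal structure of the analysis.

The generator reproduces dimensions, sparsity, skew and age concentration;
it does **not** reproduce the biological identity of hubs, the exact
community structure, the two waves' specific SCOP membership, or the
published per-event statistic values. Passing tests on synthetic data
therefore validate the machinery and its qualitative signatures (gamma
transfer between node classes, clustering in excess of density-matched
random controls, near-zero C-scaling exponents), not the published
figures, which depend on the unreleased empirical mapping.

## Numerical choices and test scale

Formula implementations (NG, VQ, heatmap elements, projections) are
checked against brute-force oracles to 1e-12 on random graphs of up to 30
nodes per side. Exponent recovery is verified at n = 10,000 samples
(alpha = 2.5 within ±0.1; Poisson degrees rejected) with 100 bootstrap
replicates; per-event bootstrap p-values default to off in `fit_series()`
because they dominate run time, and are enabled by a single argument. The
qualitative wave signatures are asserted across 5 generator seeds at the
default study dimensions. The mean degree's dispersion is reported as both
standard error and standard deviation, since published summaries rarely
state which convention a `±` uses.

## Limitations

* The generator is a stand-in: distributional choices are defensible but
  not fitted to data, and none of the published data-dependent values
  (community counts, modularity indices, event counts) should be expected
  from it.
* Age-tie arc directions are random by design; any statistic downstream of
  arc direction inherits that seed dependence (documented, reproducible).
* The `"vos"` method is a quality-equivalent substitute for
  layout-coupled VOS clustering.
* `NG` on directed projections symmetrizes weights; a genuinely directed
  modularity variant is out of scope.
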