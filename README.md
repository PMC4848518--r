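# efnet

Evolutionary network analysis of *elementary functionomes*: bipartite
graphs linking ancestral functional loop motifs (25–30 residue sequence
prototypes) to the SCOP domain superfamilies that embed them, annotated
with relative evolutionary ages and analysed as growing, time-directed
networks.

## The problem

Protein domains acquired their functions by embedding pre-existing
elementary functional loops into structural scaffolds. Given (a) a table of
loop–domain associations and (b) a phylogenomic timeline assigning each
domain superfamily a relative age *nd* ∈ \[0, 1\] (0 = oldest), `efnet`
reconstructs how that combinatorial process unfolded:

* **Age transfer** — loops inherit ages from their associated domains,
  either the age of the most ancient associated domain or (default, more
  conservative) the second value of the ascending sort of neighbour ages.
  A calibrated molecular clock, *t* = −3.831 · *nd* + 3.628, converts *nd*
  to geological age in Gy.
* **Projections** — the bipartite graph is projected onto each node class:
  two loops are linked when they share a domain scaffold, two domains when
  they embody a mutual loop. Arcs point from older to younger node
  (uniform random direction for contemporaries), weighted by the number of
  shared counterparts; weighted out/in degree classifies nodes as donors
  (sources) or acceptors (sinks) of functional material.
* **Event series** — each distinct age is one evolutionary event; the
  network grows as a step function over events and every statistic can be
  traced along the growing snapshots.
* **Scale-free diagnostics** — per event: the decay exponent γ from OLS on
  log *P(k)* vs log *k* (with R²), and the discrete maximum-likelihood
  power-law fit *P(X = x)* ∝ *x*^−α with Kolmogorov–Smirnov distance and a
  parametric-bootstrap p-value; the power-law null is rejected when
  *p* < 0.05 or KS > 0.10. Barabási and age-dependent Barabási graphs
  serve as reference controls.
* **Modularity** — six indices: the quality index VQ = Σᵢ(eᵢᵢ − aᵢ²), the
  clustering ratio, the average clustering coefficient *C* (projections
  only), fast-greedy community quality, and the Newman–Girvan index
  NG = 1/(2m) Σᵢⱼ (Aᵢⱼ − kᵢkⱼ/2m) δ(cᵢ, cⱼ) under age, detected (vos/fgc)
  and walktrap partitions, plus scaled pairwise-modularity heatmaps with
  Ward dendrograms and log–log regressions of *C* against network size and
  age.

Because the original loop–domain mapping is not redistributable, the
package ships a synthetic generator (`synth_ef()`) that reproduces the
study's dimensions and statistical structure — 38 loops × 82 domains × 134
associations, founder domains at *nd* = 0, early-concentrated ages,
preferential loop attachment — so the whole pipeline is testable end to
end.

## Worked example

```r
library(efnet)

synth <- synth_ef(synth_config(seed = 42))
net <- transfer_loop_ages(synth$network, synth$ages)
net
#> <ef_bipartite> 38 loops, 82 domains, 134 edges (density 0.043)
#>   domain ages set: 82/82; loop ages set: 28/38

mean_degree(net)
#> # A tibble: 1 × 4
#>    mean    se    sd n_nodes
#> 1  2.23 0.243  2.67     120
```

The density 0.043 = 134/(38 × 82) and mean degree 2.23 = 2·134/120 say the
network is sparse: a node takes part in ~2 loop–domain embeddings on
average. Projecting onto domains and measuring clustering:

```r
set.seed(42)
p <- project(net, "domain")
p
#> <ef_projection mode=domain> 82 nodes, 462 arcs (density 0.06956)
clustering_coefficient(p)
#> [1] 0.598
```

*C* ≈ 0.6 is far above density-matched random graphs (~0.13), the
signature of modular organisation. Tracing growth and age-assortativity:

```r
ev <- build_events(net)
ev
#> <ef_events> 81 events over nd [0, 0.762] on a ef_bipartite
head(ng_age_series(ev), 3)
#>   event      nd ng_age
#> 1     1 0        0
#> 2     2 0.00553 -0.125
#> 3     3 0.00742 -0.125
```

and fitting a power law to a known heavy-tailed sample:

```r
fit <- fit_power_law(rplaw(5000, 2.5), bootstrap = 50)
fit
#> <ef_powerlaw_fit> alpha = 2.478, KS = 0.0031, p = 0.68, loglik = -5176.2, not rejected
```

`run_pipeline()` chains all stages (load/synthesize → age transfer →
projections → events → statistics → exports) reproducibly from a config
list or YAML file; `plot_waterfall()`, `plot_accumulation_bars()` and the
`autoplot()` methods render the waterfall diagrams, chronological
accumulation bars and modularity heatmaps.

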