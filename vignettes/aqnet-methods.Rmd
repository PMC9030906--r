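---
title: "Methods: spatial correlation weighted networks and W_LGI influence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial correlation weighted networks and W_LGI influence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqnet)
```

## The model

`aqnet` treats georeferenced AQI monitoring sites (cities of an urban
agglomeration, or stations within a city) as nodes of an undirected
weighted graph and the contemporaneous co-movement of their daily AQI
series as the relation the graph encodes.

**Edge rule.** For a complete daily panel, every pair gets a Pearson
correlation $r_{ij}$. The edge threshold is the mean of all off-diagonal
correlations; a pair is connected when $r_{ij} \ge$ threshold. The
above-average rule adapts to the overall correlation level of the region
and tends to keep the size of the largest connected component stable under
small perturbations of the threshold, which is why it is preferred over a
fixed cutoff. The comparison defaults to $\ge$ (`comparison = "ge"`), with
strict $>$ available; the two differ only when correlations tie the
threshold exactly, which with continuous data essentially only happens in
degenerate panels.

**Weights.** Pollution transport attenuates with distance, so correlation
alone understates the spatial structure. Pairwise WGS-84 geodesic distances
are reduced to dimensionless coefficients by dividing by the maximum
pairwise distance (linear proportional transformation; coefficients in
$(0,1]$, farthest pair exactly 1). The raw weight of an edge is
$r_{ij}$ / coefficient$_{ij}$, and raw weights are renormalized by their
maximum over the edges that passed the threshold, giving final weights in
$(0,1]$ with the heaviest edge at exactly 1. Normalizing over edges (not
over all pairs) is deliberate: only pairs that pass the threshold carry
weights at all. A consequence worth noting: with a positive threshold,
negative correlations can never form edges; if a user forces a negative
threshold, the build aborts rather than emit weights outside $(0,1]$.

**Excluded nodes.** A node whose every correlation falls below the
threshold has no edges. It stays in the node universe (`all_nodes`) —
so the default density denominator still counts it — but is excluded from
all path-based computations and carries zero influence scores and the last
rank.

## Topology statistics

For $n$ nodes, $m$ edges:

* **Density** $G_d = m / \binom{n}{2}$. The node basis is configurable:
  `all` (default) counts excluded isolated nodes in $n$, `active` does not.
  The default reflects the convention used when reporting a station network
  in which one station dropped out: the study design still has $n$
  stations.
* **Efficiency** $G_e = 1 - V/\max(V)$, with $V = m - (n_a - c)$ the edges
  beyond a spanning forest of the $n_a$ active nodes in $c$ components, and
  $\max(V) = \sum_c \binom{n_c - 1}{2}$ the maximal possible redundancy
  given the component sizes. Forests score 1, complete graphs 0; *low*
  efficiency means many redundant correlation channels, i.e. a stable
  structure. Efficiency is always computed on active nodes: an isolated
  node belongs to no spanning forest. When $\max(V) = 0$ (trees, single
  edges) $G_e$ is defined as 1.
* **Rank degree** $G_r = 1 - S/\max(S)$, with $S$ the number of unordered
  mutually reachable pairs and $\max(S) = \binom{n_a}{2}$. In an undirected
  graph reachability is symmetric, so $G_r$ is simply the fraction of
  disconnected pairs — 0 for any connected network. The statistic is
  chiefly informative for directed graphs, which the function accepts
  directly as igraph objects; published values near 0.9 for networks
  described as undirected cannot be reproduced under this definition, and
  the package makes no attempt to guess the orientation that would produce
  them.

One caveat surfaced by the property tests: efficiency is monotone under
edge addition only within a fixed component structure. An edge that bridges
two components enlarges $\max(V)$ and can *raise* $G_e$; the monotonicity
test therefore runs on connected graphs.

## The W_LGI influence score

For each active node $v$:

* weighted degree $d_w(v) = \sum_j w_{vj}$ (local edge mass);
* local influence $W_{LI}(v) = d_w(v)/n$, with $n$ the node count of the
  analyzed network — by default the *active* count, which is the convention
  under which published ranking tables close ($W_{LI} = d_w/n$ at printed
  precision);
* global influence $W_{GI}(v) = \sum_{j \ne v} d_w(j)/(d_{vj} + \theta)$,
  where $d_{vj}$ is the shortest weighted distance and $\theta \ge 0$ damps
  the distance term. Unreachable nodes contribute 0, which keeps $W_{GI}$
  finite on disconnected networks;
* composite $W_{LGI}(v) = W_{LI}(v) \times W_{GI}(v)$, ranked descending.
  Ties break by descending $d_w$, then canonical node order, so output is
  deterministic.

**$\theta$ default 0.** No principled value is prescribed; with
$\theta = 0$ and weight-sum paths, rescaling all weights by a constant
cancels in $W_{GI}$ (numerator and denominator scale together), so the
ranking is invariant to the overall weight scale — a property the test
suite asserts. $\theta > 0$ progressively mutes the distance term.

**Path-length semantics.** The score's distance is defined literally as the
*sum of edge weights* along the shortest path (`mode = "weight_sum"`, the
default), even though a large weight means a strong connection. This
definition is implemented faithfully. It has a counterintuitive
consequence: every path out of a heavily connected node starts with one of
its own heavy edges, so exactly the strongest nodes acquire the largest
shortest distances and the smallest $W_{GI}$. For analyses where "strongly
tied" should mean "close", `mode = "inverse_weight_sum"` uses $1/w$ as the
edge length. Both modes are exposed throughout the pipeline.

## Synthetic data generator

`generate_panel()` draws
$$X_i(t) = \mu + A \sin(2\pi t/365) + \lambda_i F(t) + \varepsilon_i(t),$$
truncated at 0, with $F$ a unit-variance AR(1) regional factor and
$\varepsilon$ daily multivariate normal with covariance
$\sigma^2 e^{-d_{ij}/\rho}$ — the simplest kernel expressing "closer sites
co-move more". Defaults: $\mu = 75$ (moderate AQI), $A = 25$ AQI units
(seasonal heating/dispersion cycle), $\lambda_i = 20$, AR(1) coefficient
0.7 (multi-day episodes), $\sigma = 25$, $\rho = 300$ km, 13 sites over a
roughly 450 × 350 km box, 365 days. The loading/noise balance was
calibrated once, analytically, so that a one-year panel's mean pairwise
correlation sits near 0.75 — the level reported for real agglomeration
panels — and was then left alone.

What the generator emulates: seasonality, persistent regional episodes,
distance-decaying cross-correlation, nonnegativity, missingness. What it
does not: wind-field advection (directional transport), emission
inventories, heavy-tailed episode distributions, instrument drift. Passing
tests on synthetic panels therefore validate the *pipeline mechanics and
the score's recovery behavior under a known truth*, not meteorological
realism.

**Hub-recovery experiment.** `plant_hub()` relocates one site to the
geometric center of the others and doubles its factor loading, making it
the ground-truth most influential node. The recovery test (13 sites, 365
days, 50 seeds) uses the *grid* layout and the `inverse_weight_sum` path
mode, both deliberate:

* uniform-random layouts occasionally place two non-hub sites almost on top
  of each other; the distance-ratio weight then hands that accidental pair
  the dominant edge mass and the experiment measures layout luck, not score
  behavior. The lattice keeps inter-site spacing controlled.
* under the literal weight-sum semantics the planted hub's heavy incident
  edges inflate its own shortest distances and depress its $W_{GI}$ (see
  above), so a recovery experiment under that mode partly measures the
  semantics quirk rather than the planted signal. The inverse mode asks the
  coherent question — is the strongest node recovered when strong ties mean
  proximity — and that is what the test asserts (rank 1 in at least 90% of
  seeds).

## Numerical and degenerate-input choices

* Pearson correlation requires ≥ 3 dates, a complete panel, and errors on
  zero-variance series (naming the site) rather than emitting NaN.
* Missing-day imputation: single interior gaps take the mean of the
  flanking days; longer interior gaps are linearly interpolated between the
  flanking observed values (the same rule, applied proportionally); leading
  and trailing gaps take the nearest observed value. Imputation is
  idempotent and never leaves the observed range of a site. A site with no
  observations at all is a hard error.
* Daily aggregation averages whatever hours are observed; `min_hours`
  (default 1) marks cells with fewer observations as missing.
* Distinct sites with identical coordinates are a hard error at the
  distance-coefficient stage (a zero distance would make the edge weight
  unbounded). Ellipsoid distance falls back to the spherical value, with a
  warning, in the rare non-convergent near-antipodal case.
* Timestamps are taken as local civil time; no timezone conversion.
* An empty edge set after thresholding is a hard error ("empty network"),
  not an empty object.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
panels up to 13 sites × 365 days, oracle comparisons on graphs of ≤ 8
nodes (200 exhaustive-enumeration shortest-path checks), and a 50-seed
Monte-Carlo recovery experiment — sizes chosen so the full suite completes
in well under a minute while still exercising every code path at the scale
the method is used at (agglomerations of 9–48 sites).

## Known limitations

* Contemporaneous correlation only: no lags, no directionality, no
  causality. The networks cannot distinguish common forcing from transport.
* One representative coordinate per site; no areal geometry.
* The mean-threshold rule has no significance interpretation; edges are
  not tested against a null.
* The weight-sum path semantics penalizes exactly the nodes the weighted
  degree rewards; rankings under the two path modes can differ, and the
  package deliberately leaves the literal definition as the default while
  documenting the alternative.
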