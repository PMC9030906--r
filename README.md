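# aqnet — spatial correlation weighted networks for air quality data

Air pollution is not a site-by-site phenomenon: pollutants travel, so the
air quality index (AQI) of nearby cities or monitoring stations co-moves.
`aqnet` turns a panel of AQI time series from georeferenced sites into an
undirected *spatial correlation weighted network* and identifies the
influential nodes in it. It is aimed at environmental analysts studying
joint prevention and control of regional air pollution — which cities (or
which stations within a city) are the hubs through which pollution
correlates across a region.

## The model

Given daily mean AQI series for sites `i = 1..n` with coordinates:

1. **Edges.** Compute the Pearson correlation `r_ij` of each pair of daily
   series. Take the mean of all off-diagonal correlations as the threshold;
   an edge joins `i` and `j` when `r_ij >= threshold` (strict `>` optional).
2. **Weights.** Divide each pairwise WGS-84 geodesic distance by the maximum
   pairwise distance to get a distance coefficient in (0, 1]; the raw edge
   weight is `r_ij / coefficient_ij` (close, strongly correlated sites get
   heavy edges), then raw weights are rescaled by their maximum so final
   weights `w_ij` lie in (0, 1]. Nodes with no qualifying edge are flagged
   excluded but kept in the node universe.
3. **Topology.** Three whole-network statistics: density
   `Gd = m / (n(n-1)/2)`; efficiency `Ge = 1 - V/max(V)` with `V` the edges
   beyond a spanning forest and `max(V)` the per-component maximal
   redundancy (low `Ge` = many redundant channels = a stable correlation
   structure); rank degree `Gr = 1 - S/max(S)` with `S` the mutually
   reachable node pairs (a hierarchy measure, informative for directed
   graphs).
4. **Influence (W_LGI).** For each node: weighted degree
   `dw(v) = sum of incident w`, local influence `W_LI = dw/n`, global
   influence `W_GI(v) = sum over other nodes j of dw(j)/(d_vj + theta)`
   where `d_vj` is the weighted shortest distance, and the composite score
   `W_LGI = W_LI x W_GI`. Nodes are ranked by descending `W_LGI`.

A synthetic generator (seasonal cycle + persistent regional factor +
distance-decay correlated noise) makes every stage testable without
external data, including planted-hub rank-recovery experiments.

## Worked example

```r
library(aqnet)

cfg   <- synth_config(n_sites = 10, n_days = 120, seed = 3)
sites <- generate_sites(cfg)
panel <- impute_missing(generate_panel(sites, cfg))

corr <- pearson_matrix(panel)
net  <- build_network(corr, distance_coefficients(site_distances(sites)))
net
#> spatial_network: 10 nodes (10 active), 19 edges; threshold = 0.7049

topology_summary(net)
#> topology_summary: n = 10 (10 active), m = 19, components = 1
#>   Gd = 0.422  Ge = 0.722  Gr = 0.000

head(as.data.frame(wlgi_scores(net)), 3)
#>   node d        dw       W_LI     W_GI     W_LGI rank
#> 1  S05 5 1.9353842 0.19353842 63.77447 12.342810    1
#> 2  S06 5 1.6410228 0.16410228 60.04454  9.853446    2
#> 3  S03 7 0.8762145 0.08762145 98.32564  8.615435    3
```

The threshold 0.7049 is the mean pairwise correlation of the 120-day panel;
19 of the 45 possible pairs exceed it. Density 0.422 says 42% of possible
edges are realized; efficiency 0.722 says the network carries some but not
many redundant channels; rank degree 0 is the expected value for any
connected undirected network. Site S05 ranks first: it combines a high
weighted degree (heavy edges to its neighbors) with short weighted paths to
the rest of the network.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/aqnet.R simulate --out sim --seed 3 --n-sites 10 --n-days 120
Rscript inst/cli/aqnet.R build    --sites sim/sites.csv --readings sim/readings.csv --out net
Rscript inst/cli/aqnet.R metrics  --network net
Rscript inst/cli/aqnet.R rank     --network net --theta 0
```

writing edge list, GraphML, correlation matrix, JSON summaries and run
manifests under `net/`.

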