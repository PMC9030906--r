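#' Network density
#'
#' Gd = m / (n (n-1) / 2): realized edges over the maximum possible. By
#' default n counts every node of the original universe, including isolated
#' nodes excluded from the active network — the convention used when a
#' station drops out of the graph but still belongs to the study design.
#'
#' @param network a \code{spatial_network}.
#' @param node_basis "all" (default; includes excluded isolated nodes) or
#'   "active".
#' @return density in [0, 1].
#' @export
network_density <- function(network, node_basis = c("all", "active")) {
  node_basis <- match.arg(node_basis)
  n <- if (node_basis == "all") length(network$all_nodes)
       else length(network$active_nodes)
  if (n < 2L) stop("need >= 2 nodes for density")
  m <- nrow(network$edges)
  2 * m / (n * (n - 1))
}

#' Network efficiency
#'
#' Ge = 1 - V / max(V), where V is the number of redundant edges — edges
#' beyond a spanning forest of the active nodes, V = m - (n_active - c) with
#' c the number of connected components — and max(V) is the largest possible
#' redundancy, summed per component: (n_c - 1)(n_c - 2)/2 for a component of
#' n_c nodes. Low efficiency means many alternative channels between nodes
#' (a redundant, hence stable, correlation structure); a forest has
#' efficiency 1 and a complete graph 0. Computed on active nodes only.
#'
#' @param network a \code{spatial_network} with at least one edge.
#' @return efficiency in [0, 1]; defined as 1 when max(V) = 0.
#' @export
network_efficiency <- function(network) {
  if (nrow(network$edges) < 1L) stop("need >= 1 edge for efficiency")
  comp <- component_summary(network)
  n <- length(network$active_nodes)
  m <- nrow(network$edges)
  V <- m - (n - comp$count)
  maxV <- sum((comp$sizes - 1) * (comp$sizes - 2) / 2)
  if (maxV == 0) 1 else 1 - V / maxV
}

#' Network rank degree
#'
#' Gr = 1 - S / max(S), where S counts unordered node pairs that are
#' symmetrically reachable (i reaches j and j reaches i) and
#' max(S) = n(n-1)/2. It measures hierarchy: 0 when every pair is mutually
#' reachable, 1 when no pair is. In an undirected network reachability is
#' symmetric, so Gr reduces to the fraction of disconnected pairs and is 0
#' for any connected network; the statistic is chiefly informative for
#' directed graphs, which are accepted directly as igraph objects.
#'
#' @param network a \code{spatial_network} (active nodes are used) or an
#'   igraph graph (possibly directed).
#' @return rank degree in [0, 1].
#' @export
network_rank_degree <- function(network) {
  g <- if (inherits(network, "spatial_network")) {
    igraph::induced_subgraph(network$graph, network$active_nodes)
  } else if (igraph::is_igraph(network)) network
  else stop("expected a spatial_network or an igraph graph")
  n <- igraph::vcount(g)
  if (n < 2L) stop("need >= 2 active nodes for rank degree")
  d <- igraph::distances(g, mode = "out", weights = NA)
  reach <- is.finite(d) & is.finite(t(d))
  S <- (sum(reach) - n) / 2  # mutual pairs, diagonal removed
  1 - S / (n * (n - 1) / 2)
}

#' Connected components of the active network
#' @param network a \code{spatial_network}.
#' @return list with \code{count} and \code{sizes} (decreasing).
#' @export
component_summary <- function(network) {
  g <- igraph::induced_subgraph(network$graph, network$active_nodes)
  comp <- igraph::components(g)
  list(count = comp$no, sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}

#' Whole-network topology summary
#'
#' @param network a \code{spatial_network}.
#' @param node_basis basis for the density denominator; see
#'   \code{\link{network_density}}.
#' @return A list of class \code{topology_summary}: n_total, n_active, m,
#'   components, density, efficiency, rank_degree.
#' @export
topology_summary <- function(network, node_basis = c("all", "active")) {
  node_basis <- match.arg(node_basis)
  comp <- component_summary(network)
  structure(list(n_total = length(network$all_nodes),
                 n_active = length(network$active_nodes),
                 m = nrow(network$edges),
                 components = comp$count,
                 density = network_density(network, node_basis),
                 efficiency = network_efficiency(network),
                 rank_degree = network_rank_degree(network)),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0("topology_summary: n = %d (%d active), m = %d, ",
                     "components = %d\n  Gd = %.3f  Ge = %.3f  Gr = %.3f\n"),
              x$n_total, x$n_active, x$m, x$components,
              x$density, x$efficiency, x$rank_degree))
  invisible(x)
}

#' Write a topology summary as JSON and one-row CSV
#' @param summary a \code{topology_summary}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_topology_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(summary), file.path(dir, "topology.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(unclass(summary)),
                   file.path(dir, "topology.csv"), row.names = FALSE)
  invisible(dir)
}
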