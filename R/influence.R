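#' Weighted degree
#'
#' In a weighted network the degree of a node is the sum of the weights of
#' its incident edges. Isolated (excluded) nodes have weighted degree 0.
#'
#' @param network a \code{spatial_network}.
#' @param v a node id, or NULL for all nodes in canonical order.
#' @return named numeric vector (or scalar for a single node).
#' @export
weighted_degree <- function(network, v = NULL) {
  dw <- igraph::strength(network$graph,
                         weights = igraph::E(network$graph)$weight)
  dw <- dw[network$all_nodes]
  if (is.null(v)) return(dw)
  if (!v %in% network$all_nodes) stop("unknown node: ", v)
  dw[[v]]
}

#' Local influence
#'
#' W_LI = dw / n: the node's weighted degree relative to the size of the
#' network it sits in.
#'
#' @param dw weighted degree (scalar or vector).
#' @param n node count of the network.
#' @return W_LI value(s).
#' @export
local_influence <- function(dw, n) {
  stopifnot(n >= 1)
  dw / n
}

#' Weighted shortest-distance matrix
#'
#' The distance between two nodes is the minimum over connecting paths of the
#' sum of edge lengths. The default takes the edge weight itself as the
#' length ("weight_sum"), matching the definition the influence score is
#' built on; "inverse_weight_sum" uses 1/weight, so strongly connected nodes
#' become close. Distances are computed over active nodes; pairs in different
#' components are +Inf.
#'
#' @param network a \code{spatial_network}.
#' @param mode "weight_sum" (default) or "inverse_weight_sum".
#' @return symmetric matrix over active nodes.
#' @export
shortest_distance_matrix <- function(network,
                                     mode = c("weight_sum", "inverse_weight_sum")) {
  mode <- match.arg(mode)
  g <- igraph::induced_subgraph(network$graph, network$active_nodes)
  w <- igraph::E(g)$weight
  stopifnot(all(w > 0))
  len <- if (mode == "weight_sum") w else 1 / w
  d <- igraph::distances(g, weights = len)
  d[network$active_nodes, network$active_nodes, drop = FALSE]
}

#' Global influence
#'
#' W_GI(v) = sum over other active nodes j of dw(j) / (d_vj + theta), where
#' d_vj is the weighted shortest distance and theta a nonnegative adjustment
#' parameter. A node surrounded (at short distance) by heavy nodes scores
#' high. Unreachable nodes contribute 0; excluded nodes score 0.
#'
#' @param network a \code{spatial_network}.
#' @param v a node id, or NULL for all nodes in canonical order.
#' @param theta nonnegative scalar, default 0.
#' @param mode path-length mode; see \code{\link{shortest_distance_matrix}}.
#' @return named numeric vector (or scalar for a single node).
#' @export
global_influence <- function(network, v = NULL, theta = 0,
                             mode = c("weight_sum", "inverse_weight_sum")) {
  stopifnot(theta >= 0)
  mode <- match.arg(mode)
  dw <- weighted_degree(network)
  d <- shortest_distance_matrix(network, mode)
  act <- network$active_nodes
  gi <- stats::setNames(numeric(length(network$all_nodes)), network$all_nodes)
  for (i in act) {
    j <- setdiff(act, i)
    contrib <- dw[j] / (d[i, j] + theta)
    gi[i] <- sum(contrib[is.finite(contrib)])
  }
  if (is.null(v)) return(gi)
  if (!v %in% network$all_nodes) stop("unknown node: ", v)
  gi[[v]]
}

#' Influence scores and ranking (W_LGI)
#'
#' Computes, for every node, the unweighted degree d, weighted degree dw,
#' local influence W_LI = dw/n, global influence W_GI (shortest-distance
#' weighted-degree sum) and the composite score W_LGI = W_LI x W_GI, then
#' ranks nodes by descending W_LGI. Excluded (isolated) nodes carry zero
#' scores and fill the bottom ranks. Ties break by descending dw, then
#' canonical node order, so output is deterministic.
#'
#' @param network a \code{spatial_network}.
#' @param theta adjustment parameter of the global term, default 0.
#' @param n_basis node count for W_LI: "active" (default; the nodes actually
#'   in the analyzed network) or "all".
#' @param mode path-length mode; see \code{\link{shortest_distance_matrix}}.
#' @return A data frame of class \code{influence_table} with columns
#'   \code{node}, \code{d}, \code{dw}, \code{W_LI}, \code{W_GI},
#'   \code{W_LGI}, \code{rank}, ordered by rank; attributes \code{theta},
#'   \code{n_basis}, \code{mode}, \code{n} echo the configuration.
#' @export
wlgi_scores <- function(network, theta = 0, n_basis = c("active", "all"),
                        mode = c("weight_sum", "inverse_weight_sum")) {
  n_basis <- match.arg(n_basis)
  mode <- match.arg(mode)
  if (nrow(network$edges) == 0L) stop("empty network")
  nodes <- network$all_nodes
  n <- if (n_basis == "active") length(network$active_nodes) else length(nodes)
  d <- igraph::degree(network$graph)[nodes]
  dw <- weighted_degree(network)
  wli <- local_influence(dw, n)
  wgi <- global_influence(network, theta = theta, mode = mode)
  wlgi <- wli * wgi
  ord <- order(-wlgi, -dw, seq_along(nodes))
  tab <- data.frame(node = nodes, d = as.integer(d), dw = dw, W_LI = wli,
                    W_GI = wgi, W_LGI = wlgi, stringsAsFactors = FALSE,
                    row.names = NULL)[ord, ]
  tab$rank <- seq_along(nodes)
  rownames(tab) <- NULL
  structure(tab, theta = theta, n_basis = n_basis, mode = mode, n = n,
            class = c("influence_table", "data.frame"))
}

#' Write an influence table as CSV and JSON
#'
#' The CSV mirrors the ranking-table layout (node, d, dw, W_LI, W_GI, W_LGI,
#' rank); the JSON variant echoes the configuration (theta, path mode, node
#' basis) alongside the rows.
#'
#' @param table an \code{influence_table}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_influence <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(table), file.path(dir, "influence.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(config = list(theta = attr(table, "theta"),
                                          n_basis = attr(table, "n_basis"),
                                          mode = attr(table, "mode"),
                                          n = attr(table, "n")),
                            nodes = as.data.frame(table)),
                       file.path(dir, "influence.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
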