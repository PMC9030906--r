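#' Pearson correlation matrix of a daily panel
#'
#' Computes the site-by-site Pearson correlation of the daily AQI series over
#' the full common date range. The matrix carries the mean off-diagonal
#' correlation as its \code{threshold} attribute, the default edge threshold
#' used by \code{\link{build_network}}.
#'
#' @param panel a complete daily \code{readings_panel} with at least 3 dates.
#' @return A symmetric matrix of class \code{correlation_matrix} with unit
#'   diagonal and attribute \code{threshold}.
#' @export
pearson_matrix <- function(panel) {
  stopifnot(inherits(panel, "readings_panel"))
  if (!panel_complete(panel)) stop("panel has missing cells; run impute_missing first")
  if (nrow(panel$values) < 3L) stop("need >= 3 dates for a correlation matrix")
  sds <- apply(panel$values, 2, stats::sd)
  flat <- colnames(panel$values)[sds == 0]
  if (length(flat))
    stop("site(s) with zero variance, correlation undefined: ",
         paste(flat, collapse = ", "))
  m <- stats::cor(panel$values)
  structure(m, threshold = mean_offdiag_threshold(m),
            class = c("correlation_matrix", class(m)))
}

#' Mean off-diagonal correlation threshold
#'
#' The arithmetic mean of all n(n-1) off-diagonal entries of a correlation
#' matrix (equivalently, of the n(n-1)/2 upper-triangle entries). Used as the
#' edge-inclusion threshold: keeping only above-average correlations yields a
#' network whose largest connected component is stable under small threshold
#' perturbations.
#'
#' @param corr square correlation matrix, n >= 2.
#' @return scalar threshold.
#' @export
mean_offdiag_threshold <- function(corr) {
  corr <- unclass(corr)
  if (nrow(corr) < 2L) stop("need >= 2 sites")
  mean(corr[row(corr) != col(corr)])
}

#' Geodesic distance between coordinates, in kilometres
#'
#' WGS-84 ellipsoid distance by default, with a spherical haversine
#' alternative. If the ellipsoid solver fails to return a finite value (nearly
#' antipodal points), the spherical value is used with a warning.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees; vectorized.
#' @param model "ellipsoid" (WGS-84) or "sphere" (haversine).
#' @return distance(s) in km.
#' @export
geodesic_distance_km <- function(lat1, lon1, lat2, lon2,
                                 model = c("ellipsoid", "sphere")) {
  model <- match.arg(model)
  p1 <- cbind(lon1, lat1)
  p2 <- cbind(lon2, lat2)
  if (model == "sphere") return(geosphere::distHaversine(p1, p2) / 1000)
  d <- tryCatch(geosphere::distGeo(p1, p2), error = function(e) NA_real_)
  bad <- !is.finite(d)
  if (any(bad)) {
    warning("ellipsoid distance did not converge for ", sum(bad),
            " pair(s); using spherical value")
    d[bad] <- geosphere::distHaversine(p1[bad, , drop = FALSE],
                                       p2[bad, , drop = FALSE])
  }
  d / 1000
}

#' Pairwise site distance matrix in kilometres
#' @param sites a \code{sites_table}.
#' @param model distance model passed to \code{\link{geodesic_distance_km}}.
#' @return symmetric n x n matrix with site ids as dimnames.
#' @export
site_distances <- function(sites, model = c("ellipsoid", "sphere")) {
  model <- match.arg(model)
  n <- nrow(sites)
  d <- matrix(0, n, n, dimnames = list(sites$site_id, sites$site_id))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    dij <- geodesic_distance_km(sites$latitude[i], sites$longitude[i],
                                sites$latitude[j], sites$longitude[j], model)
    d[i, j] <- dij
    d[j, i] <- dij
  }
  d
}

#' Normalized distance coefficients
#'
#' Removes the physical dimension of inter-site distance by a linear
#' proportional transformation: every pairwise distance is divided by the
#' maximum pairwise distance, giving coefficients in (0, 1] with the farthest
#' pair at exactly 1.
#'
#' @param dist_km symmetric pairwise distance matrix in km (zero diagonal).
#' @return An object of class \code{distance_model}: list with \code{km} and
#'   \code{coef} matrices.
#' @export
distance_coefficients <- function(dist_km) {
  dist_km <- as.matrix(dist_km)
  off <- dist_km[row(dist_km) != col(dist_km)]
  if (any(off <= 0)) {
    bad <- which(dist_km <= 0 & row(dist_km) != col(dist_km), arr.ind = TRUE)[1, ]
    stop("distinct sites with identical coordinates (zero distance): ",
         rownames(dist_km)[bad[1]], " / ", colnames(dist_km)[bad[2]])
  }
  structure(list(km = dist_km, coef = dist_km / max(off)),
            class = "distance_model")
}

#' Build the spatial correlation weighted network
#'
#' Sites are nodes. An edge joins sites i and j when their correlation
#' r_ij reaches the threshold (mean off-diagonal correlation by default;
#' comparison ">=" as in the worked experiments, ">" available). The raw edge
#' weight is r_ij divided by the normalized distance coefficient, so nearby
#' strongly correlated sites get heavy edges; raw weights are then rescaled by
#' their maximum so final weights lie in (0, 1] with the heaviest edge at
#' exactly 1. Nodes left without any edge are flagged excluded: they remain in
#' the node universe but take no part in path-based computations.
#'
#' @param corr a \code{correlation_matrix} (or plain symmetric matrix).
#' @param dist a \code{distance_model} over the same sites, in the same order.
#' @param comparison "ge" (default) or "gt": edge if r >= / > threshold.
#' @param threshold edge threshold; defaults to the mean off-diagonal
#'   correlation of \code{corr}.
#' @return A \code{spatial_network}: list with \code{graph} (igraph),
#'   \code{all_nodes}, \code{active_nodes}, \code{excluded}, \code{edges}
#'   data frame (source, target, weight, r, distance_km), \code{threshold},
#'   \code{comparison}, \code{normalizer}.
#' @export
build_network <- function(corr, dist, comparison = c("ge", "gt"),
                          threshold = NULL) {
  comparison <- match.arg(comparison)
  stopifnot(inherits(dist, "distance_model"))
  cm <- unclass(corr)
  nodes <- rownames(cm)
  if (is.null(nodes)) nodes <- rownames(dist$km)
  if (!identical(dim(cm), dim(dist$coef)) ||
      (!is.null(rownames(cm)) && !identical(rownames(cm), rownames(dist$km))))
    stop("correlation and distance matrices must share the same node universe")
  if (is.null(threshold)) {
    threshold <- attr(corr, "threshold")
    if (is.null(threshold)) threshold <- mean_offdiag_threshold(cm)
  }
  n <- nrow(cm)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[ut]
  keep <- if (comparison == "ge") r >= threshold else r > threshold
  if (!any(keep)) stop("empty network: no correlation passes the threshold ",
                       format(threshold))
  if (any(r[keep] <= 0))
    stop("threshold admits non-positive correlations; ",
         "edge weights must lie in (0, 1]")
  ii <- ut[keep, 1]; jj <- ut[keep, 2]
  pre <- r[keep] / dist$coef[cbind(ii, jj)]
  normalizer <- max(pre)
  edges <- data.frame(source = nodes[ii], target = nodes[jj],
                      weight = pre / normalizer, r = r[keep],
                      distance_km = dist$km[cbind(ii, jj)],
                      stringsAsFactors = FALSE)
  net <- spatial_network(edges, nodes)
  net$threshold <- threshold
  net$comparison <- comparison
  net$normalizer <- normalizer
  net
}

#' Assemble a spatial network from an edge list
#'
#' Lower-level constructor used by the builders, the artifact readers and
#' tests: wraps a weighted undirected edge list plus the full node universe
#' (including isolated nodes) into a \code{spatial_network}.
#'
#' @param edges data frame with columns \code{source}, \code{target},
#'   \code{weight} (positive); optional \code{r}, \code{distance_km}.
#' @param nodes character vector of all node ids (defaults to nodes seen in
#'   \code{edges}).
#' @return A \code{spatial_network}.
#' @export
spatial_network <- function(edges, nodes = NULL) {
  stopifnot(all(c("source", "target", "weight") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (is.null(nodes)) nodes <- unique(c(edges$source, edges$target))
  if (any(edges$source == edges$target)) stop("self-loops are not allowed")
  key <- paste(pmin(edges$source, edges$target), pmax(edges$source, edges$target))
  if (anyDuplicated(key)) stop("parallel edges are not allowed")
  if (any(!is.finite(edges$weight) | edges$weight <= 0))
    stop("edge weights must be positive and finite")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  active <- nodes[igraph::degree(g)[nodes] > 0]
  structure(list(graph = g, all_nodes = nodes, active_nodes = active,
                 excluded = setdiff(nodes, active), edges = edges,
                 threshold = NA_real_, comparison = NA_character_,
                 normalizer = NA_real_),
            class = "spatial_network")
}

#' @export
print.spatial_network <- function(x, ...) {
  cat(sprintf(
    "spatial_network: %d nodes (%d active), %d edges; threshold = %s\n",
    length(x$all_nodes), length(x$active_nodes), nrow(x$edges),
    if (is.na(x$threshold)) "n/a" else format(round(x$threshold, 4))))
  if (length(x$excluded))
    cat("  excluded (isolated):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Write network artifacts
#'
#' Writes three machine-readable artifacts into a directory: an edge-list CSV
#' (\code{edges.csv}: source, target, weight, r, distance_km), a GraphML file
#' (\code{network.graphml}, loadable by Gephi and igraph) and a JSON metadata
#' file (\code{network.json}: node universe, threshold, comparison rule,
#' weight normalizer, excluded nodes).
#'
#' @param network a \code{spatial_network}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ed <- network$edges
  for (col in c("r", "distance_km")) if (!col %in% names(ed)) ed[[col]] <- NA_real_
  utils::write.csv(ed[, c("source", "target", "weight", "r", "distance_km")],
                   file.path(dir, "edges.csv"), row.names = FALSE)
  igraph::write_graph(network$graph, file.path(dir, "network.graphml"),
                      format = "graphml")
  meta <- list(nodes = network$all_nodes, active_nodes = network$active_nodes,
               excluded = network$excluded, threshold = network$threshold,
               comparison = network$comparison, normalizer = network$normalizer)
  jsonlite::write_json(meta, file.path(dir, "network.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(dir)
}

#' Read network artifacts written by \code{\link{write_network}}
#' @param dir directory containing \code{edges.csv} and \code{network.json}.
#' @return A \code{spatial_network}.
#' @export
read_network <- function(dir) {
  edges <- utils::read.csv(file.path(dir, "edges.csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "network.json"), simplifyVector = TRUE)
  net <- spatial_network(edges, nodes = meta$nodes)
  net$threshold <- if (is.null(meta$threshold)) NA_real_ else meta$threshold
  net$comparison <- if (is.null(meta$comparison)) NA_character_ else meta$comparison
  net$normalizer <- if (is.null(meta$normalizer)) NA_real_ else meta$normalizer
  net
}

#' Write a correlation matrix as square CSV
#' @param corr a \code{correlation_matrix}.
#' @param path output CSV path (site ids as header and first column).
#' @return \code{path}, invisibly.
#' @export
write_correlation_matrix <- function(corr, path) {
  utils::write.csv(as.data.frame(unclass(corr)), path, row.names = TRUE)
  invisible(path)
}
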