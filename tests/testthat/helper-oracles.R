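# Independent brute-force oracles, kept deliberately naive: explicit-sum
# Pearson, exhaustive simple-path shortest distances, union-find spanning
# forests and transitive-closure components. They never call the package
# functions they are used to check.

brute_pearson <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n
  yb <- sum(y) / n
  num <- sum((x - xb) * (y - yb))
  num / sqrt(sum((x - xb)^2) * sum((y - yb)^2))
}

# shortest distance between every node pair by exhaustive simple-path
# enumeration; edge length = weight (or 1/weight)
brute_shortest <- function(edges, nodes, invert = FALSE) {
  n <- length(nodes)
  len <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    w <- if (invert) 1 / edges$weight[k] else edges$weight[k]
    i <- edges$source[k]; j <- edges$target[k]
    len[i, j] <- len[j, i] <- w
  }
  adj <- lapply(nodes, function(v) nodes[is.finite(len[v, ]) & nodes != v])
  names(adj) <- nodes
  best <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(best) <- 0
  dfs <- function(v, target, visited, acc) {
    if (acc >= best[start, target]) return(invisible(NULL))
    if (v == target) {
      best[start, target] <<- acc
      return(invisible(NULL))
    }
    for (u in adj[[v]]) {
      if (!(u %in% visited)) dfs(u, target, c(visited, u), acc + len[v, u])
    }
  }
  for (start in nodes) {
    for (target in setdiff(nodes, start)) {
      dfs(start, target, start, 0)
    }
  }
  best
}

# number of edges in a spanning forest, by union-find
brute_forest_edges <- function(edges, nodes) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(v) {
    while (parent[[v]] != v) v <- parent[[v]]
    v
  }
  cnt <- 0L
  for (k in seq_len(nrow(edges))) {
    a <- find(edges$source[k]); b <- find(edges$target[k])
    if (a != b) {
      parent[[a]] <- b
      cnt <- cnt + 1L
    }
  }
  cnt
}

# node partition by iterated transitive closure over the adjacency matrix
brute_components <- function(edges, nodes) {
  n <- length(nodes)
  adj <- diag(n) > 0
  dimnames(adj) <- list(nodes, nodes)
  for (k in seq_len(nrow(edges))) {
    adj[edges$source[k], edges$target[k]] <- TRUE
    adj[edges$target[k], edges$source[k]] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0 | adj
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[adj[i, ]] <- cur
    }
  }
  stats::setNames(comp, nodes)
}
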