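test_that("pearson_matrix matches hand values and flags degenerate sites", {
  p <- make_daily_panel(cbind(A = c(1, 2, 3, 4), B = c(3, 5, 7, 9)))
  expect_equal(unclass(pearson_matrix(p))["A", "B"], 1)

  p <- make_daily_panel(cbind(A = c(1, 2, 3), B = c(8, 7, 6)))
  expect_equal(unclass(pearson_matrix(p))["A", "B"], -1)

  p <- make_daily_panel(cbind(A = c(1, 2, 3, 4), B = c(1, 3, 2, 4)))
  expect_equal(unclass(pearson_matrix(p))["A", "B"], 0.8)

  flat <- make_daily_panel(cbind(A = c(1, 2, 3), B = c(5, 5, 5)))
  expect_error(pearson_matrix(flat), "zero variance.*B")
  holed <- make_daily_panel(cbind(A = c(1, NA, 3), B = c(1, 2, 3)))
  expect_error(pearson_matrix(holed), "missing")
})

test_that("pearson_matrix agrees with the explicit-sum formula", {
  set.seed(42)
  for (rep in 1:5) {
    vals <- matrix(runif(150, 20, 150), 30, 5,
                   dimnames = list(NULL, sprintf("S%d", 1:5)))
    m <- unclass(pearson_matrix(make_daily_panel(vals)))
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(m[i, j], brute_pearson(vals[, i], vals[, j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("mean_offdiag_threshold averages the off-diagonal entries", {
  m2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(mean_offdiag_threshold(m2), 0.5)
  m3 <- diag(3)
  m3[upper.tri(m3)] <- c(0.2, 0.4, 0.6)
  m3[lower.tri(m3)] <- t(m3)[lower.tri(m3)]
  expect_equal(mean_offdiag_threshold(m3), 0.4)
})

test_that("geodesic distances are symmetric and match reference arcs", {
  expect_equal(geodesic_distance_km(39.9, 116.4, 39.9, 116.4), 0)
  # one degree of latitude along the prime meridian on WGS-84
  expect_equal(geodesic_distance_km(0, 0, 1, 0), 110.57, tolerance = 0.1 / 110)
  set.seed(5)
  for (k in 1:10) {
    a <- c(runif(1, -80, 80), runif(1, -179, 179))
    b <- c(runif(1, -80, 80), runif(1, -179, 179))
    expect_equal(geodesic_distance_km(a[1], a[2], b[1], b[2]),
                 geodesic_distance_km(b[1], b[2], a[1], a[2]))
  }
  # the sphere model is close to but distinct from the ellipsoid
  d_e <- geodesic_distance_km(39.9, 116.4, 23.1, 113.3)
  d_s <- geodesic_distance_km(39.9, 116.4, 23.1, 113.3, model = "sphere")
  expect_equal(d_s, d_e, tolerance = 0.01)
  expect_false(identical(d_s, d_e))
})

test_that("distance coefficients scale by the maximum distance", {
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d["a", "b"] <- d["b", "a"] <- 10
  d["a", "c"] <- d["c", "a"] <- 20
  d["b", "c"] <- d["c", "b"] <- 40
  dm <- distance_coefficients(d)
  expect_equal(dm$coef["a", "b"], 0.25)
  expect_equal(dm$coef["a", "c"], 0.5)
  expect_equal(dm$coef["b", "c"], 1)

  d345 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d345["a", "b"] <- d345["b", "a"] <- 3
  d345["a", "c"] <- d345["c", "a"] <- 4
  d345["b", "c"] <- d345["c", "b"] <- 5
  expect_equal(sort(distance_coefficients(d345)$coef[upper.tri(d345)]),
               c(0.6, 0.8, 1.0))

  dz <- d
  dz["a", "b"] <- dz["b", "a"] <- 0
  expect_error(distance_coefficients(dz), "identical coordinates")
})

make_corr <- function(vals, nodes) {
  m <- diag(length(nodes))
  dimnames(m) <- list(nodes, nodes)
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

make_dist <- function(km, nodes) {
  m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  m[upper.tri(m)] <- km
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  distance_coefficients(m)
}

test_that("build_network applies threshold, ratio weights and renormalization", {
  # upper triangle order for 3 nodes: AB, AC, BC
  corr <- make_corr(c(0.9, 0.8, 0.4), c("A", "B", "C"))
  dist <- make_dist(c(5, 10, 8), c("A", "B", "C"))  # coefs 0.5, 1.0, 0.8
  net <- build_network(corr, dist)
  expect_equal(net$threshold, 0.7)  # mean of 0.9, 0.8, 0.4
  expect_equal(nrow(net$edges), 2L)
  ed <- net$edges[order(net$edges$target), ]
  # pre-normalization weights 1.8 (AB) and 0.8 (AC); normalizer 1.8
  expect_equal(ed$weight, c(1, 0.8 / 1.8))
  expect_equal(net$normalizer, 1.8)
  expect_equal(net$active_nodes, c("A", "B", "C"))
})

test_that("a single qualifying edge normalizes to weight 1", {
  corr <- make_corr(0.9, c("A", "B"))
  dist <- make_dist(50, c("A", "B"))
  net <- build_network(corr, dist, threshold = 0.9)
  expect_equal(net$edges$weight, 1)
})

test_that("nodes with no qualifying correlation are excluded but retained", {
  # C correlates weakly with everyone
  corr <- make_corr(c(0.9, 0.2, 0.3), c("A", "B", "C"))
  dist <- make_dist(c(5, 10, 8), c("A", "B", "C"))
  net <- build_network(corr, dist, threshold = 0.8)
  expect_equal(net$excluded, "C")
  expect_equal(net$all_nodes, c("A", "B", "C"))
  expect_equal(sort(net$active_nodes), c("A", "B"))
})

test_that("build_network errors on empty networks and negative-weight edges", {
  corr <- make_corr(c(0.9, 0.8, 0.4), c("A", "B", "C"))
  dist <- make_dist(c(5, 10, 8), c("A", "B", "C"))
  expect_error(build_network(corr, dist, threshold = 0.99), "empty network")
  neg <- make_corr(c(-0.5, 0.8, 0.4), c("A", "B", "C"))
  expect_error(build_network(neg, dist, threshold = -0.9), "0, 1")
})

test_that("ge admits threshold-equal correlations, gt does not", {
  corr <- make_corr(c(0.8, 0.9, 0.5), c("A", "B", "C"))
  dist <- make_dist(c(5, 10, 8), c("A", "B", "C"))
  expect_equal(nrow(build_network(corr, dist, "ge", threshold = 0.8)$edges), 2L)
  expect_equal(nrow(build_network(corr, dist, "gt", threshold = 0.8)$edges), 1L)
})

test_that("raising the threshold never adds edges", {
  set.seed(8)
  for (rep in 1:10) {
    n <- 6
    nodes <- sprintf("S%d", 1:n)
    corr <- make_corr(runif(n * (n - 1) / 2, 0.2, 0.99), nodes)
    dist <- make_dist(runif(n * (n - 1) / 2, 10, 500), nodes)
    edge_key <- function(net) paste(net$edges$source, net$edges$target)
    prev <- NULL
    for (th in c(0.3, 0.5, 0.7, 0.9)) {
      net <- tryCatch(build_network(corr, dist, threshold = th),
                      error = function(e) NULL)
      keys <- if (is.null(net)) character(0) else edge_key(net)
      if (!is.null(prev)) expect_true(all(keys %in% prev))
      prev <- keys
    }
  }
})

test_that("build_network commutes with node relabeling", {
  set.seed(21)
  cfg <- synth_config(n_sites = 8, n_days = 60, seed = 13)
  sites <- generate_sites(cfg)
  panel <- generate_panel(sites, cfg)
  corr <- pearson_matrix(panel)
  dist <- distance_coefficients(site_distances(sites))
  net <- build_network(corr, dist)

  perm <- sample(8)
  corr2 <- unclass(corr)[perm, perm]
  km2 <- dist$km[perm, perm]
  net2 <- build_network(structure(corr2, threshold = attr(corr, "threshold")),
                        distance_coefficients(km2))
  key <- function(e) sort(paste(pmin(e$source, e$target),
                                pmax(e$source, e$target), round(e$weight, 12)))
  expect_equal(key(net2$edges), key(net$edges))
})

test_that("network artifacts round-trip through write_network/read_network", {
  net <- rand_network(7, 10)
  net$threshold <- 0.6
  net$comparison <- "ge"
  net$normalizer <- 2.5
  dir <- withr::local_tempdir()
  write_network(net, dir)
  expect_true(all(file.exists(file.path(dir,
    c("edges.csv", "network.graphml", "network.json")))))
  back <- read_network(dir)
  expect_equal(back$all_nodes, net$all_nodes)
  expect_equal(back$edges$weight, net$edges$weight)
  expect_equal(back$threshold, 0.6)
  g <- igraph::read_graph(file.path(dir, "network.graphml"), format = "graphml")
  expect_equal(igraph::ecount(g), 10)
})
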