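complete_digraph <- function(n) {
  nodes <- paste0("v", seq_len(n))
  e <- expand.grid(regulator = nodes, target = nodes, stringsAsFactors = FALSE)
  e <- e[e$regulator != e$target, ]
  e$weight <- 1
  weighted_digraph(nodes, e)
}

test_that("the complete digraph attains its closed-form metrics", {
  m <- compute_metrics(complete_digraph(5))
  expect_equal(m$edge_density, 1)
  expect_equal(m$mean_betweenness, 0)
  expect_equal(m$degree_entropy, 0)
  expect_equal(m$mean_closeness, 1)
  expect_equal(m$mean_degree, 8)
  expect_setequal(m$hubs, paste0("v", 1:5))
})

test_that("a 23-node 13-edge digraph reproduces the sparse-network magnitudes", {
  set.seed(101)
  nodes <- sprintf("v%02d", 1:23)
  pairs <- expand.grid(regulator = nodes, target = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  e <- pairs[sample(nrow(pairs), 13), ]
  e$weight <- 1
  m <- compute_metrics(weighted_digraph(nodes, e))
  expect_equal(m$mean_degree, 26 / 23, tolerance = 1e-12)  # prints as 1.130
  expect_equal(m$edge_density, 13 / 506, tolerance = 1e-12)  # prints as 0.026
  expect_equal(round(m$mean_degree, 3), 1.130)
  expect_equal(round(m$edge_density, 3), 0.026)
})

test_that("the 7-node star has unit center betweenness and entropy ~0.410", {
  nodes <- c("hub", paste0("leaf", 1:6))
  e <- data.frame(regulator = "hub", target = paste0("leaf", 1:6), weight = 1,
                  stringsAsFactors = FALSE)
  g <- weighted_digraph(nodes, e)
  m <- compute_metrics(g)
  ig_btw <- c(1, rep(0, 6))
  expect_equal(m$mean_betweenness, mean(ig_btw), tolerance = 1e-12)
  expect_equal(m$hubs, "hub")
  expect_equal(m$degree_entropy,
               -(1 / 7) * log(1 / 7) - (6 / 7) * log(6 / 7), tolerance = 1e-12)
  # brute-force confirmation of the per-node path metrics
  adj <- matrix(0, 7, 7); adj[1, 2:7] <- 1
  expect_equal(m$mean_betweenness, mean(oracle_betweenness(adj) / 15),
               tolerance = 1e-12)
  expect_equal(m$mean_closeness, mean(oracle_closeness(adj)), tolerance = 1e-12)
})

test_that("closeness and betweenness match the brute-force oracle on random graphs", {
  for (s in 1:6) {
    rg <- random_digraph(sample(5:12, 1), runif(1, 0.1, 0.4), seed = 110 + s)
    n <- length(rg$g$nodes)
    m <- compute_metrics(rg$g)
    norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
    expect_equal(m$mean_betweenness, mean(oracle_betweenness(rg$adj) / norm),
                 tolerance = 1e-10)
    expect_equal(m$mean_closeness, mean(oracle_closeness(rg$adj)),
                 tolerance = 1e-10)
  }
})

test_that("metrics are invariant to node relabeling", {
  rg <- random_digraph(9, 0.3, seed = 130)
  g <- rg$g
  perm <- sample(seq_along(g$nodes))
  relab <- stats::setNames(paste0("x", seq_along(g$nodes)), g$nodes[perm])
  e2 <- data.frame(regulator = unname(relab[g$edges$regulator]),
                   target = unname(relab[g$edges$target]),
                   weight = g$edges$weight, stringsAsFactors = FALSE)
  g2 <- weighted_digraph(unname(relab), e2)
  m1 <- compute_metrics(g)
  m2 <- compute_metrics(g2)
  for (f in c("mean_degree", "edge_density", "mean_closeness",
              "mean_betweenness", "degree_entropy"))
    expect_equal(m1[[f]], m2[[f]], tolerance = 1e-10)
})

test_that("adding an edge never decreases density or mean degree", {
  rg <- random_digraph(8, 0.2, seed = 140)
  g <- rg$g
  m1 <- compute_metrics(g)
  free <- expand.grid(regulator = g$nodes, target = g$nodes,
                      stringsAsFactors = FALSE)
  free <- free[free$regulator != free$target, ]
  key <- paste(g$edges$regulator, g$edges$target)
  free <- free[!(paste(free$regulator, free$target) %in% key), ][1, ]
  free$weight <- 1
  g2 <- weighted_digraph(g$nodes, rbind(g$edges, free))
  m2 <- compute_metrics(g2)
  expect_gte(m2$edge_density, m1$edge_density)
  expect_gte(m2$mean_degree, m1$mean_degree)
})

test_that("degree entropy is zero exactly for degree-regular graphs", {
  # directed 4-cycle: all total degrees 2
  nodes <- paste0("c", 1:4)
  e <- data.frame(regulator = nodes, target = nodes[c(2, 3, 4, 1)], weight = 1,
                  stringsAsFactors = FALSE)
  m <- compute_metrics(weighted_digraph(nodes, e))
  expect_equal(m$degree_entropy, 0)
  expect_lte(compute_metrics(random_digraph(10, 0.3, seed = 150)$g)$degree_entropy,
             log(10))  # bounded by log(#distinct degrees) <= log(n)
  expect_error(compute_metrics(weighted_digraph("a")), "at least 2")
})

test_that("entropy base 2 rescales the natural-log entropy", {
  rg <- random_digraph(8, 0.3, seed = 160)
  me <- compute_metrics(rg$g, entropy_base = "e")
  m2 <- compute_metrics(rg$g, entropy_base = "2")
  expect_equal(m2$degree_entropy, me$degree_entropy / log(2), tolerance = 1e-12)
})
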