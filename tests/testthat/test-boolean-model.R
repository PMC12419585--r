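test_that("binarization splits separated clusters and flags constants", {
  m <- rbind(g1 = c(1, 1, 10, 10), g2 = c(5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  cm <- count_matrix(m, c("ND", "ND", "HFD", "HFD"))
  b <- binarize(cm, factors = rep(1, 4))
  expect_equal(unname(b["g1", ]), c(0, 0, 1, 1))
  expect_equal(unname(b["g2", ]), c(0, 0, 0, 0))
  expect_equal(attr(b, "degenerate"), "g2")
})

test_that("kmeans2 equals the exhaustive 1-D split minimizer and stats::kmeans", {
  set.seed(27)
  m <- matrix(rnbinom(30 * 10, mu = sample(c(15, 150), 300, TRUE), size = 8) + 1,
              30, 10, dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:10)))
  cm <- count_matrix(m, rep(c("ND", "HFD"), each = 5))
  b <- binarize(cm, factors = rep(1, 10))
  y <- log_normalized(cm, rep(1, 10))
  for (i in seq_len(nrow(y))) {
    v <- y[i, ]
    if (max(v) - min(v) < 1e-12) next
    # oracle: evaluate every split of the sorted values
    s <- sort(v)
    ss <- sapply(1:9, function(cut) {
      lo <- s[1:cut]; hi <- s[(cut + 1):10]
      sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    })
    thr <- (s[which.min(ss)] + s[which.min(ss) + 1]) / 2
    expect_equal(unname(b[i, ]), unname(as.integer(v > thr)))
    km <- kmeans(v, 2, nstart = 10)
    expect_equal(unname(b[i, ]),
                 unname(as.integer(km$cluster == which.max(km$centers))))
  }
})

test_that("single-parent rules are learned exactly", {
  st <- rbind(p = c(0, 1, 0, 1), y1 = c(0, 1, 0, 1), y2 = c(1, 0, 1, 0))
  expect_equal(as.integer(fit_boolean_rule("y1", "p", st)), c(0L, 1L))
  expect_equal(as.integer(fit_boolean_rule("y2", "p", st)), c(1L, 0L))
})

test_that("two-parent AND beats all 16 candidate functions in exhaustive scoring", {
  st <- rbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1), y = c(0, 0, 0, 1))
  fit <- fit_boolean_rule("y", c("a", "b"), st)
  expect_equal(as.integer(fit), c(0L, 0L, 0L, 1L))
  # oracle: score every 2-input truth table
  rows <- st["a", ] * 2 + st["b", ]
  errs <- sapply(0:15, function(code) {
    tab <- as.integer(intToBits(code))[4:1]
    sum(tab[rows + 1] != st["y", ])
  })
  expect_equal(attr(fit, "errors"), min(errs))
  expect_equal(errs[1 + 1], 0)  # AND is code 1 under MSB-first row order
})

test_that("best-fit never exceeds the better constant's error and ties break to 0", {
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(1:3, 1)
    n <- sample(4:12, 1)
    st <- matrix(rbinom((k + 1) * n, 1, 0.5), k + 1, n,
                 dimnames = list(c(paste0("p", 1:k), "y"), paste0("s", 1:n)))
    fit <- fit_boolean_rule("y", paste0("p", 1:k), st)
    const_err <- min(sum(st["y", ] == 1), sum(st["y", ] == 0))
    expect_lte(attr(fit, "errors"), const_err)
  }
  # a fully tied target gives the all-zero (lexicographically least) table
  st <- rbind(p = c(0, 0, 1, 1), y = c(0, 1, 0, 1))
  expect_equal(as.integer(fit_boolean_rule("y", "p", st)), c(0L, 0L))
})

test_that("noiseless data with all input rows observed recovers the true table", {
  set.seed(9)
  for (rep in 1:10) {
    k <- sample(1:3, 1)
    truth_tab <- sample(0:1, 2^k, replace = TRUE)
    rows <- 0:(2^k - 1)
    pm <- sapply(rows, function(r) as.integer(intToBits(r))[k:1])
    pm <- matrix(pm, nrow = k)
    st <- rbind(pm, truth_tab[rows + 1])
    rownames(st) <- c(paste0("p", 1:k), "y")
    colnames(st) <- paste0("s", seq_len(ncol(st)))
    fit <- fit_boolean_rule("y", paste0("p", 1:k), st)
    expect_equal(as.integer(fit), as.integer(truth_tab))
    expect_equal(attr(fit, "errors"), 0L)
  }
})

test_that("the in-degree cap is enforced", {
  st <- matrix(rbinom(50, 1, 0.5), 5, 10,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  expect_error(fit_boolean_rule("g1", paste0("g", 2:5), st), "cap")
})

test_that("rule files round-trip and compile as written", {
  net <- generate_network(10, 1.5, 3, seed = 41)
  f <- tempfile(fileext = ".txt")
  write_rules(net, f)
  back <- read_rules(f)
  expect_identical(back$genes, net$genes)
  expect_identical(back$tables, net$tables)
  expect_identical(back$parents, net$parents)
})

test_that("expressions compile to the truth table of their direct evaluation", {
  f <- tempfile()
  writeLines(c("targets, factors", "A, B & !C", "B, 1", "C, A | B"), f)
  net <- read_rules(f)
  expect_equal(net$parents$A, c("B", "C"))
  expect_equal(net$tables$A, c(0L, 0L, 1L, 0L))
  expect_equal(net$tables$B, 1L)
  expect_equal(net$parents$C, c("A", "B"))
  expect_equal(net$tables$C, c(0L, 1L, 1L, 1L))
  # exhaustive check of a nested expression against direct evaluation
  writeLines(c("targets, factors", "x, (y | !z) & !(y & w)",
               "y, 0", "z, 1", "w, 0"), f)
  net2 <- read_rules(f)
  pars <- net2$parents$x
  expect_equal(pars, c("y", "z", "w"))
  for (row in 0:7) {
    bits <- as.integer(intToBits(row))[3:1]
    names(bits) <- pars
    direct <- as.integer((bits["y"] | !bits["z"]) & !(bits["y"] & bits["w"]))
    expect_equal(net2$tables$x[row + 1], direct)
  }
})

test_that("malformed rule files fail with a line number", {
  f <- tempfile()
  writeLines(c("targets, factors", "A, B & !C", "B, A", "C, Z | A"), f)
  expect_error(read_rules(f), "line 4.*undefined gene 'Z'")
  writeLines(c("targets, factors", "A, B &"), f)
  expect_error(read_rules(f), "line 2")
  writeLines(c("no header", "A, 1"), f)
  expect_error(read_rules(f), "header")
})

test_that("JSON serialization round-trips clamped networks losslessly", {
  net <- generate_network(8, 1.5, 3, seed = 51)
  net <- boolean_network(net$genes, net$parents, net$tables,
                         clamped = c(g02 = 1L, g07 = 0L))
  f <- tempfile(fileext = ".json")
  network_to_json(net, f)
  back <- network_from_json(f)
  expect_identical(back$genes, net$genes)
  expect_identical(back$parents, net$parents)
  expect_identical(back$tables, net$tables)
  expect_identical(back$clamped, net$clamped)
})

test_that("build_boolean_model fits rules over the inferred regulators", {
  nodes <- c("a", "b", "c")
  e <- data.frame(regulator = c("a", "a", "b"), target = c("b", "c", "c"),
                  weight = c(1, 0.8, 0.6), stringsAsFactors = FALSE)
  g <- weighted_digraph(nodes, e)
  st <- rbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1), c = c(0, 0, 1, 1))
  colnames(st) <- paste0("s", 1:4)
  net <- build_boolean_model(g, st)
  expect_equal(net$parents$b, "a")
  expect_equal(net$tables$b, c(0L, 1L))
  expect_setequal(net$parents$c, c("a", "b"))
  expect_equal(net$parents$a, character(0))
  expect_equal(net$tables$a, 0L)  # tied constant -> 0
})
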