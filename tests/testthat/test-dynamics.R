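test_that("self-copy rules make every state a fixed point", {
  genes <- paste0("g", 1:4)
  net <- boolean_network(genes,
                         stats::setNames(as.list(genes), genes),
                         stats::setNames(rep(list(c(0L, 1L)), 4), genes))
  for (s in c(0, 5, 9, 15)) expect_equal(successor(net, s), s)
  att <- enumerate_attractors(net)
  expect_equal(length(att$attractors), 16)
  expect_true(all(vapply(att$attractors, `[[`, numeric(1), "basin") == 1))
  expect_true(all(vapply(att$attractors, function(a) length(a$states), numeric(1)) == 1))
})

test_that("all-constant rules give a single full-basin attractor", {
  genes <- paste0("g", 1:5)
  const <- c(1L, 0L, 1L, 1L, 0L)
  net <- boolean_network(genes,
                         stats::setNames(rep(list(character(0)), 5), genes),
                         stats::setNames(as.list(const), genes))
  target <- sum(const * 2^(0:4))
  for (s in c(0, 7, 31)) expect_equal(successor(net, s), target)
  att <- enumerate_attractors(net)
  expect_equal(length(att$attractors), 1)
  expect_equal(att$attractors[[1]]$states, target)
  expect_equal(att$attractors[[1]]$basin, 2^5)
})

test_that("a printed 3-gene rule file reproduces its hand-computed transition table", {
  f <- tempfile()
  writeLines(c("targets, factors",
               "a, b & c",
               "b, !a",
               "c, a | b"), f)
  net <- read_rules(f)
  # states packed with a at bit0, b at bit1, c at bit2; next state computed
  # by hand from the three rules
  hand <- c("000" = "010", "100" = "001", "010" = "011", "110" = "001",
            "001" = "010", "101" = "001", "011" = "111", "111" = "101")
  for (key in names(hand)) {
    bits <- as.integer(strsplit(key, "")[[1]])
    s <- sum(bits * 2^(0:2))
    exp_bits <- as.integer(strsplit(hand[[key]], "")[[1]])
    expect_equal(successor(net, s), sum(exp_bits * 2^(0:2)))
  }
})

test_that("optimized enumeration matches the naive walker on random networks", {
  for (s in 1:5) {
    net <- generate_network(10, 1.5, 3, seed = 60 + s)
    att <- enumerate_attractors(net)
    expect_true(same_attractors(att, oracle_attractors(net)))
    expect_equal(sum(vapply(att$attractors, `[[`, numeric(1), "basin")),
                 2^10)
  }
})

test_that("clamping all genes leaves exactly the clamped state", {
  net <- generate_network(6, 1.5, 3, seed = 71)
  vals <- c(g01 = 1L, g02 = 0L, g03 = 1L, g04 = 1L, g05 = 0L, g06 = 0L)
  att <- perturb(net, names(vals)[vals == 1], names(vals)[vals == 0])
  expect_equal(length(att$attractors), 1)
  expect_equal(att$attractors[[1]]$states, sum(vals * 2^(0:5)))
  expect_equal(att$attractors[[1]]$basin, 1)
})

test_that("clamping nothing reproduces the baseline attractors", {
  net <- generate_network(9, 1.5, 3, seed = 72)
  base <- enumerate_attractors(net)
  none <- perturb(net, character(0), character(0))
  expect_equal(none$attractors, base$attractors)
})

test_that("clamped-gene enumeration equals the oracle on the reduced system", {
  net <- generate_network(8, 1.5, 3, seed = 73)
  att <- perturb(net, character(0), "g03")
  net_cl <- boolean_network(net$genes, net$parents, net$tables, c(g03 = 0L))
  expect_true(same_attractors(att, oracle_attractors(net_cl)))
  # every attractor state carries the clamped value
  for (a in att$attractors)
    for (s in a$states)
      expect_equal((s %/% 4) %% 2, 0)  # g03 is bit 2
  expect_equal(att$total_states, 2^7)
})

test_that("initial-state perturbation restricts starts but not the dynamics", {
  # two-gene toggle: a <- b, b <- a; starting from states with a = b gives
  # only the matching fixed points, while a != b starts the 2-cycle
  f <- tempfile()
  writeLines(c("targets, factors", "a, b", "b, a"), f)
  net <- read_rules(f)
  fixed1 <- perturb(net, up_genes = "a", mode = "initial_state")
  sigs <- vapply(fixed1$attractors, function(a) canon_cycle(a$states), character(1))
  expect_setequal(sigs, c("3", "1,2"))   # a=1,b=1 fixed point and the 2-cycle
  expect_equal(fixed1$total_states, 2)
  # clamp mode instead collapses to a single fixed point
  clamped <- perturb(net, up_genes = "a", mode = "clamp")
  expect_equal(length(clamped$attractors), 1)
  expect_equal(clamped$attractors[[1]]$states, 3)
})

test_that("perturbation preconditions are checked", {
  net <- generate_network(5, 1, 2, seed = 74)
  expect_error(perturb(net, "g01", "g01"), "disjoint")
  expect_error(perturb(net, "zz"), "belong")
})

test_that("exhaustive capacity limits are explicit", {
  net <- generate_network(12, 1, 2, seed = 75)
  expect_error(enumerate_attractors(net, max_exhaustive_genes = 10), "sampled")
  expect_error(enumerate_attractors(net, max_exhaustive_genes = 30), "25")
})

test_that("sampled mode finds a subset of the exhaustive attractors", {
  for (s in 1:3) {
    net <- generate_network(10, 1.5, 3, seed = 80 + s)
    ex <- enumerate_attractors(net)
    sm <- enumerate_attractors(net, mode = "sampled", n_samples = 200, seed = s)
    expect_true(sm$estimated)
    sig_ex <- vapply(ex$attractors, function(a) canon_cycle(a$states), character(1))
    sig_sm <- vapply(sm$attractors, function(a) canon_cycle(a$states), character(1))
    expect_true(all(sig_sm %in% sig_ex))
    expect_equal(sum(vapply(sm$attractors, `[[`, numeric(1), "basin")), 200)
  }
})

test_that("cycle reports list oscillating genes as the XOR of cycle states", {
  # planted 2-cycle: a and c toggle, b is constant 1
  f <- tempfile()
  writeLines(c("targets, factors", "a, !a", "b, 1", "c, !c"), f)
  net <- read_rules(f)
  att <- enumerate_attractors(net)
  rep_ <- report_cycles(att)
  expect_true(all(rep_$length[rep_$oscillating == ""] == 1))
  osc <- rep_$oscillating[rep_$length == 2]
  expect_true(all(osc == "a,c"))
  # XOR oracle on the cycle states
  for (a in att$attractors) {
    if (length(a$states) != 2) next
    x <- bitwXor(as.integer(a$states[1]), as.integer(a$states[2]))
    expect_equal(x, 1 + 4)  # bits of a and c
  }
  # fixed points report empty sets
  fp <- boolean_network("g1", list(g1 = character(0)), list(g1 = 1L))
  rp <- report_cycles(enumerate_attractors(fp))
  expect_equal(rp$length, 1)
  expect_equal(rp$oscillating, "")
})

test_that("attractor sets serialize to JSON with gene-order bitstrings", {
  net <- generate_network(5, 1.5, 2, seed = 90)
  att <- enumerate_attractors(net)
  f <- tempfile(fileext = ".json")
  attractors_to_json(att, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$total_states, 32)
  s1 <- obj$attractors$states[[1]][1]
  expect_equal(nchar(s1), 5)
  bits <- as.integer(strsplit(s1, "")[[1]])
  expect_equal(sum(bits * 2^(0:4)), att$attractors[[1]]$states[1])
})
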