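test_that("hand-derived scores on canonical small graphs", {
  p3 <- path_net(c("A", "B", "C"))
  expect_equal(compute_measure(p3, "betweenness"), c(A = 0, B = 1, C = 0))
  expect_equal(compute_measure(p3, "eccentricity"), c(A = 0.5, B = 1, C = 0.5))

  k4 <- complete_net(LETTERS[1:4])
  expect_equal(compute_measure(k4, "mcc"), setNames(rep(6, 4), LETTERS[1:4]))
  expect_equal(compute_measure(k4, "mnc"), setNames(rep(3, 4), LETTERS[1:4]))
  expect_equal(compute_measure(k4, "dmnc"),
               setNames(rep(3 / 3^1.7, 4), LETTERS[1:4]))

  st <- star_net("C0", c("L1", "L2", "L3"))
  bn <- compute_measure(st, "bottleneck")
  expect_equal(bn[["C0"]], 3)  # every leaf-rooted tree routes 3 > 4/4 nodes
  expect_equal(unname(bn[c("L1", "L2", "L3")]), c(0, 0, 0))
  expect_equal(compute_measure(st, "mcc")[["C0"]], 3)  # = degree, leaves non-adjacent
})

test_that("EPC matches the analytic expectation on a single edge", {
  e1 <- make_net(rbind(c("A", "B")))
  # E[size of A's component] = 1.5 at retention 0.5; 3-sigma band at 2e4 draws
  params <- centrality_params(epc_retention = 0.5, epc_realizations = 2e4,
                              rng_seed = 99)
  got <- compute_measure(e1, "epc", params)
  sigma <- 0.5 / sqrt(2e4)
  expect_lt(abs(got[["A"]] - 1.5), 3 * sigma)
  # retention 1 gives the component size exactly
  p1 <- centrality_params(epc_retention = 1, epc_realizations = 3)
  expect_equal(compute_measure(e1, "epc", p1), c(A = 2, B = 2))
})

test_that("every measure matches its brute-force oracle on assorted graphs", {
  nets <- c(
    all_connected_graphs(LETTERS[1:4]),
    list(path_net(LETTERS[1:6]),
         star_net("HUB", sprintf("L%d", 1:5)),
         complete_net(LETTERS[1:5]),
         # disconnected: triangle plus an edge plus an isolated vertex
         make_net(rbind(c("A", "B"), c("B", "C"), c("A", "C"), c("D", "E")),
                  nodes = LETTERS[1:6])),
    lapply(1:6, function(s) random_connected_net(7, p = 0.35, seed = s))
  )
  for (net in nets) expect_measures_match_oracle(net)
})

test_that("tree leaves carry zero betweenness/stress and MCC = degree", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    # random labelled tree: attach each vertex to a previous one
    syms <- sprintf("T%02d", 1:n)
    pairs <- cbind(syms[vapply(2:n, function(i) sample(i - 1, 1), numeric(1))],
                   syms[2:n])
    net <- make_net(pairs)
    deg <- compute_measure(net, "degree")
    leaves <- names(deg)[deg == 1]
    expect_true(all(compute_measure(net, "betweenness")[leaves] == 0))
    expect_true(all(compute_measure(net, "stress")[leaves] == 0))
    # tree neighbourhoods are edgeless, so MCC falls back to the degree
    expect_equal(compute_measure(net, "mcc"), deg)
    # EPC at retention 1 equals component size (= n on a tree)
    p1 <- centrality_params(epc_retention = 1, epc_realizations = 1)
    expect_equal(unname(compute_measure(net, "epc", p1)), rep(n, n))
  }
})

test_that("rank table ranks are a permutation with symbol tie-breaks", {
  k5 <- complete_net(LETTERS[1:5])
  # retention 1 makes EPC symmetric too, so every measure ties on K5
  sym <- centrality_params(rng_seed = 5, epc_retention = 1)
  rt <- compute_all(k5, sym)
  for (m in hub_measures()) {
    sub <- dplyr::filter(rt, measure == m)
    expect_equal(sort(sub$rank), 1:5)
    expect_equal(sub$gene[order(sub$rank)], LETTERS[1:5])
  }
  # determinism including the stochastic EPC at partial retention
  rt1 <- compute_all(k5, centrality_params(rng_seed = 5))
  rt2 <- compute_all(k5, centrality_params(rng_seed = 5))
  expect_equal(tidy(rt1), tidy(rt2))
})

test_that("a dominant node ranks first on the measures that reward it", {
  # hub wired to everyone; others sparse
  net <- make_net(rbind(cbind("HUB", sprintf("V%d", 1:6)), c("V1", "V2")))
  rt <- compute_all(net)
  for (m in c("degree", "closeness", "mcc", "betweenness")) {
    expect_equal(top_k(rt, m, 1), "HUB")
  }
  expect_equal(top_k(rt, "degree", 10), c("HUB", sprintf("V%d", 1:6)))
  expect_length(top_k(rt, "degree", 3), 3)
})

test_that("adding an edge never decreases endpoint degree", {
  net <- make_net(rbind(c("A", "B"), c("B", "C")))
  net2 <- make_net(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  d1 <- compute_measure(net, "degree")
  d2 <- compute_measure(net2, "degree")
  expect_true(all(d2[c("A", "C")] >= d1[c("A", "C")]))
})

test_that("degenerate inputs are handled", {
  expect_error(compute_measure(make_net(rbind(c("A", "B"))), "pagerank"))
  lone <- ppi_network(data.frame(node1 = character(0), node2 = character(0),
                                 score = numeric(0)),
                      keep_isolated = TRUE, query_nodes = "A")
  for (m in setdiff(hub_measures(), "epc")) {
    expect_equal(unname(compute_measure(lone, m)), 0)
  }
})
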