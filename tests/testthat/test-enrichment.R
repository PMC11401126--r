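# exhaustive hypergeometric upper tail by direct summation
tail_sum <- function(k, m, n, N) {
  if (k <= max(0, n + m - N)) return(1)
  i <- k:min(m, n)
  sum(choose(m, i) * choose(N - m, n - i)) / choose(N, n)
}

test_that("hypergeometric tail matches exhaustive summation", {
  expect_equal(hyper_tail_p(5, 5, 5, 20), 1 / choose(20, 5))
  expect_equal(hyper_tail_p(0, 5, 5, 20), 1)
  for (N in c(5, 9, 13)) {
    for (m in 1:N) for (n in 1:N) {
      for (k in max(0, n + m - N):min(m, n)) {
        expect_equal(hyper_tail_p(k, m, n, N), tail_sum(k, m, n, N),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("GMT round-trips with descriptions and validates members", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tfirst set\tTP53\tEGFR\tMYC",
               "SET_B\tsecond set\tJUN\tFOS"), f)
  coll <- read_gmt(f)
  expect_equal(names(coll$terms), c("SET_A", "SET_B"))
  expect_equal(coll$terms$SET_B, c("JUN", "FOS"))
  expect_equal(unname(coll$descriptions["SET_A"]), "first set")
  expect_equal(coll$universe, sort(c("TP53", "EGFR", "MYC", "JUN", "FOS")))
  expect_error(read_gmt(tempfile()), "not found")
  f2 <- tempfile(fileext = ".gmt")
  writeLines("ONLY_NAME\tdesc", f2)
  expect_error(read_gmt(f2), "malformed")
  expect_error(geneset_collection(list(S = c("A", "B")), universe = "A"),
               "outside")
})

test_that("fisher_enrich orders records and flags significance", {
  universe <- sprintf("U%03d", 1:40)
  coll <- geneset_collection(
    list(HIT = universe[1:6], MISS = universe[21:30]),
    universe = universe)
  er <- fisher_enrich(universe[1:6], coll, alpha = 0.05)
  expect_equal(er$term, c("HIT", "MISS"))
  expect_equal(er$overlap_k, c(6L, 0L))
  expect_equal(er$p_value[1], 1 / choose(40, 6))
  expect_equal(er$p_value[2], 1)
  expect_true(er$significant[1] && !er$significant[2])
  expect_true(all(er$q_value >= er$p_value))
  # out-of-universe query genes are dropped with a warning
  expect_warning(fisher_enrich(c(universe[1:3], "NOT_THERE"), coll), "dropped")
  expect_error(suppressWarnings(fisher_enrich("NOT_THERE", coll)), "empty query")
})

test_that("BH adjustment matches hand-computed step-up vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(c(0.03, 0.005)), c(0.03, 0.01))  # order preserved
  set.seed(31)
  p <- runif(25)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))  # monotone in p-rank
  # permutation-consistent
  perm <- sample(25)
  expect_equal(bh_adjust(p[perm]), q[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("planted terms are recovered while decoys stay mostly null", {
  n_false <- 0L
  n_decoy <- 0L
  for (seed in 1:5) {
    spec <- synthetic_spec(rng_seed = seed)
    core <- gen_gene_lists(spec)$truth$core
    gen <- gen_gene_set_collection(spec, query = core)
    er <- fisher_enrich(core, gen$collection, alpha = 0.05)
    sig <- er$term[er$significant]
    expect_true(all(gen$truth$planted_terms %in% sig))
    n_false <- n_false + length(setdiff(sig, gen$truth$planted_terms))
    n_decoy <- n_decoy + length(gen$truth$decoy_terms)
  }
  expect_lte(n_false / n_decoy, 0.05)
})

test_that("kappa grouping merges redundant terms and splits disjoint ones", {
  universe <- sprintf("U%03d", 1:100)
  q <- universe[1:8]
  coll <- geneset_collection(
    list(T_LEFT = universe[1:4], T_LEFT2 = universe[1:4],
         T_RIGHT = universe[5:8]),
    universe = universe)
  er <- fisher_enrich(q, coll, alpha = 0.05)
  expect_true(all(er$significant))
  g <- kappa_group(er, kappa_threshold = 0.4)
  # identical membership -> kappa 1 -> one group; disjoint halves -> kappa -1
  expect_equal(nrow(g), 2L)
  expect_true(any(vapply(g$terms, function(t) setequal(t, c("T_LEFT", "T_LEFT2")),
                         logical(1))))
  # threshold above 1 isolates every term
  g2 <- kappa_group(er, kappa_threshold = 1.01)
  expect_equal(nrow(g2), 3L)
  # representative is the most significant member
  expect_true(all(mapply(function(rep, t) rep %in% t, g$representative, g$terms)))
})

test_that("kappa is symmetric and 1 on identical memberships", {
  k <- metahubr:::cohen_kappa
  x <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  y <- c(TRUE, FALSE, FALSE, TRUE, TRUE)
  expect_equal(k(x, y), k(y, x))
  expect_equal(k(x, x), 1)
  # disjoint halves: hand 2x2 gives kappa = -1
  expect_equal(k(c(TRUE, TRUE, FALSE, FALSE), c(FALSE, FALSE, TRUE, TRUE)), -1)
})
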