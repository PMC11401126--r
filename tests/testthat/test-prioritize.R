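# minimal hand-built inputs for ledger tests
ledger_fixture <- function() {
  hub <- c("AKT1", "STAT3", "MMP9", "EGFR", "CD44", "TP53", "JUN", "MYC",
           "FOS", "IL6")
  clus <- c("AKT1", "STAT3", "MMP9", "NFKB1", "CTNNB1", "MMP1", "IFNG",
            "ESR1", "KDR", "AR")
  merged <- merge_hub_cluster(hub, clus)
  gl <- new_gene_lists(list(
    d1 = c(rep("AKT1", 5), merged$union_list),
    d2 = merged$union_list,
    d3 = c("AKT1", "STAT3")
  ))
  red <- redundancy_counts(gl, merged$union_list)
  rt <- dplyr::bind_rows(lapply(sprintf("m%d", 1:3), function(m) {
    tibble::tibble(measure = m, gene = hub, score = rev(seq_along(hub)),
                   rank = seq_along(hub))
  }))
  class(rt) <- c("rank_table", class(rt))
  cons <- consensus_rank(rt, k = 10)
  list(merged = merged, red = red, cons = cons, cluster_top = clus)
}

test_that("ledger assembles all seven parameters over the merged list", {
  fx <- ledger_fixture()
  db <- tibble::tibble(gene = rep(c("NFKB1", "MMP9"), each = 2),
                       disease = rep(c("d1", "d2"), 2),
                       direction = c("up", "up", "up", "down"),
                       source = "database")
  ledger <- suppressWarnings(build_ledger(fx$merged, fx$red, fx$cons,
                                          fx$cluster_top, db_expression = db))
  expect_equal(ledger$genes, fx$merged$union_list)
  expect_equal(unname(ledger$redundancy[["AKT1"]]), 8L)  # 5 dups + 3 list entries
  expect_equal(unname(ledger$consensus_rank[["AKT1"]]), 1L)
  expect_equal(unname(ledger$cluster_rank[["NFKB1"]]), 4L)
  expect_true(all(ledger$db_expression[setdiff(ledger$genes, c("NFKB1", "MMP9")), ] == "unknown"))
  expect_warning(build_ledger(fx$merged, fx$red, fx$cons, fx$cluster_top,
                              db_expression = db),
                 "missing")
})

test_that("the selection policy picks winners, overlap and concordant genes", {
  fx <- ledger_fixture()
  # database: NFKB1 concordant up/up; MMP9 discordant
  db <- tibble::tibble(gene = rep(c("NFKB1", "MMP9"), each = 2),
                       disease = rep(c("d1", "d2"), 2),
                       direction = c("up", "up", "up", "down"),
                       source = "database")
  # literature: NFKB1 and CTNNB1 concordant
  lit <- tibble::tibble(gene = rep(c("NFKB1", "CTNNB1"), each = 2),
                        disease = rep(c("d1", "d2"), 2),
                        direction = c("down", "down", "up", "up"),
                        source = "literature")
  ledger <- suppressWarnings(build_ledger(fx$merged, fx$red, fx$cons,
                                          fx$cluster_top,
                                          db_expression = db,
                                          lit_expression = lit))
  ps <- shortlist(ledger)
  # AKT1 wins redundancy, hub rank and cluster rank; overlap adds STAT3, MMP9;
  # expression adds NFKB1 (db+lit) and CTNNB1 (lit)
  expect_equal(ps$shortlist, sort(c("AKT1", "STAT3", "MMP9", "NFKB1", "CTNNB1")))
  expect_setequal(ps$provenance$AKT1,
                  c("1_redundancy", "2_hub_rank", "3_cluster_rank", "4_overlap"))
  expect_setequal(ps$provenance$NFKB1,
                  c("6_db_expression", "7_lit_expression"))
  expect_equal(ps$provenance$CTNNB1, "7_lit_expression")
  expect_true(all(ps$shortlist %in% fx$merged$union_list))
})

test_that("a nine-way fixture shortlists exactly nine candidates", {
  # distinct winners for params 1-3 and 5, a 3-gene overlap, and two extra
  # concordant genes alongside one overlap gene -> union of size 9
  hub <- c("W2", "OV1", "OV2", "OV3", "W1", "W5", "X1", "X2", "X3", "X4")
  clus <- c("W3", "OV1", "OV2", "OV3", "Y1", "Y2", "Y3", "Y4", "Y5", "Y6")
  merged <- merge_hub_cluster(hub, clus)
  gl <- new_gene_lists(list(d1 = c(rep("W1", 4), merged$union_list)))
  red <- redundancy_counts(gl, merged$union_list)
  rt <- tibble::tibble(measure = "m1", gene = hub,
                       score = rev(seq_along(hub)), rank = seq_along(hub))
  class(rt) <- c("rank_table", class(rt))
  cons <- consensus_rank(rt, k = 10)
  universe <- c(merged$union_list, sprintf("U%02d", 1:50))
  coll <- geneset_collection(list(T1 = "W5", T2 = c("W5", "U01")),
                             universe = universe)
  er <- fisher_enrich(merged$union_list, coll, alpha = 0.5)
  expect_true(all(er$significant))
  dirs <- function(genes) {
    tibble::tibble(gene = rep(genes, each = 2), disease = rep(c("d1", "d2"),
                   length(genes)), direction = "up", source = "database")
  }
  ledger2 <- suppressWarnings(build_ledger(
    merged, red, cons, clus, enrichment = er,
    db_expression = dirs("Y1"), lit_expression = dirs(c("Y2", "OV1"))))
  ps <- shortlist(ledger2)
  # winners: W1 (redundancy), W2 (hub rank), W3 (cluster rank), W5
  # (enrichment), OV1-3 (overlap), Y1, Y2 (concordant; OV1 already in)
  expect_length(ps$shortlist, 9L)
  expect_setequal(ps$shortlist,
                  c("W1", "W2", "W3", "W5", "OV1", "OV2", "OV3", "Y1", "Y2"))
})

test_that("shortlist shrinks monotonically as parameters are removed", {
  fx <- ledger_fixture()
  db <- tibble::tibble(gene = rep("NFKB1", 2), disease = c("d1", "d2"),
                       direction = "up", source = "database")
  full <- suppressWarnings(build_ledger(fx$merged, fx$red, fx$cons,
                                        fx$cluster_top, db_expression = db))
  no_db <- suppressWarnings(build_ledger(fx$merged, fx$red, fx$cons,
                                         fx$cluster_top))
  s_full <- shortlist(full)$shortlist
  s_less <- shortlist(no_db)$shortlist
  expect_true(all(s_less %in% s_full))
})

test_that("generated concordant subsets are recovered exactly", {
  spec <- synthetic_spec(rng_seed = 11, n_concordant = 4)
  genes <- sprintf("G%03d", 1:15)
  gen <- gen_expression_annotations(spec, genes, source = "database")
  m <- metahubr:::expression_matrix(gen$annotation, genes)
  expect_equal(metahubr:::concordant_genes(m), gen$truth$concordant)
  # all-unknown table -> empty concordant set
  unk <- dplyr::mutate(gen$annotation, direction = "unknown")
  expect_equal(metahubr:::concordant_genes(
    metahubr:::expression_matrix(unk, genes)), character(0))
  # a single disease makes every known-direction gene concordant
  spec1 <- synthetic_spec(rng_seed = 2, diseases = "only", n_concordant = 2)
  gen1 <- gen_expression_annotations(spec1, genes)
  m1 <- metahubr:::expression_matrix(gen1$annotation, genes)
  known <- rownames(m1)[m1[, 1] != "unknown"]
  expect_equal(metahubr:::concordant_genes(m1), sort(known))
})
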