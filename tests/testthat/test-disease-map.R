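test_that("the shipped three-disease core map loads with the printed wiring", {
  f <- system.file("extdata", "three_disease_map.tsv", package = "metahubr")
  maps <- read_disease_map(f, isolated = "IFNG")
  expect_equal(nrow(maps$edges), 27L)  # 9 shared edges x 3 diseases
  per_disease <- dplyr::count(maps$edges, disease)
  expect_equal(per_disease$n, rep(9L, 3))
  expect_length(map_nodes(maps), 9L)
  builtin <- three_disease_core_map()
  expect_equal(as.data.frame(maps$edges), as.data.frame(builtin$edges))
  expect_equal(maps$isolated, builtin$isolated)

  # rejected inputs
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\teffect\tdisease", "A\tB\tphosphorylates\td1"), bad)
  expect_error(read_disease_map(bad), "effect")
  loop <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\teffect\tdisease", "A\tA\tactivate\td1"), loop)
  expect_error(read_disease_map(loop), "self-edge at row 1")
  empty <- tempfile(fileext = ".tsv")
  writeLines("source\ttarget\teffect\tdisease", empty)
  expect_warning(m0 <- read_disease_map(empty), "empty")
  expect_equal(nrow(m0$edges), 0L)
})

test_that("superimposition keeps pairs by support and resolves conflicts", {
  base <- tibble::tibble(source = c("A", "B"), target = c("B", "C"),
                         effect = "activate")
  maps <- disease_maps(dplyr::bind_rows(
    dplyr::mutate(base, disease = "d1"),
    dplyr::mutate(base, disease = "d2"),
    dplyr::mutate(base[1, ], disease = "d3")
  ))
  sup_all <- superimpose(maps)  # min_support defaults to all three
  expect_equal(nrow(sup_all$edges), 1L)
  expect_equal(sup_all$edges$support, 3L)
  sup2 <- superimpose(maps, min_support = 2)
  expect_equal(nrow(sup2$edges), 2L)
  expect_error(superimpose(maps, min_support = 4), "exceeds")
  expect_error(superimpose(disease_maps(dplyr::mutate(base, disease = "d1"))),
               "at least 2")

  # conflicting effects collapse to regulate
  confl <- disease_maps(tibble::tibble(
    source = "A", target = "B", effect = c("activate", "inhibit"),
    disease = c("d1", "d2")))
  expect_warning(supc <- superimpose(confl, min_support = 2), "regulate")
  expect_equal(supc$edges$effect, "regulate")

  # three identical maps reproduce the map with support 3 everywhere
  ident <- three_disease_core_map()
  sup <- superimpose(ident)
  expect_equal(nrow(sup$edges), 9L)
  expect_true(all(sup$edges$support == 3L))
})

test_that("superimpose is union at support 1 and intersection at full support", {
  set.seed(23)
  for (i in 1:5) {
    nodes <- sprintf("N%02d", 1:8)
    mk <- function(d) {
      pairs <- expand.grid(source = nodes, target = nodes,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$source != pairs$target, ]
      pick <- pairs[sample(nrow(pairs), 10), ]
      dplyr::mutate(pick, effect = "regulate", disease = d)
    }
    edges <- dplyr::bind_rows(mk("d1"), mk("d2"), mk("d3"))
    maps <- disease_maps(edges)
    key <- function(df) sort(paste(df$source, df$target))
    per_d <- lapply(split(edges, edges$disease), key)
    sup1 <- suppressWarnings(superimpose(maps, min_support = 1))
    expect_equal(key(sup1$edges), sort(Reduce(union, per_d)))
    sup3 <- suppressWarnings(superimpose(maps, min_support = 3))
    expect_equal(key(sup3$edges), sort(Reduce(intersect, per_d)))
  }
})

test_that("the hub of hubs maximizes two-way reachability", {
  sup <- superimpose(three_disease_core_map())
  hub <- hub_of_hubs(sup)
  expect_equal(hub$gene, "AKT1")
  expect_equal(hub$connectivity, 6L)  # EGFR, CD44 upstream; NFKB1, STAT3, MMP9, MMP1 downstream
  expect_lte(hub$connectivity, length(map_nodes(sup)) - 1L)

  single <- disease_maps(tibble::tibble(source = "A", target = "B",
                                        effect = "activate",
                                        disease = c("d1", "d2")))
  h1 <- hub_of_hubs(superimpose(single, min_support = 2))
  expect_equal(h1$gene, "A")  # ties with B on count 1; symbol breaks the tie
  expect_equal(h1$connectivity, 1L)

  star <- disease_maps(tibble::tibble(source = "HUB",
                                      target = rep(sprintf("L%d", 1:4), 2),
                                      effect = "activate",
                                      disease = rep(c("d1", "d2"), each = 4)))
  hs <- hub_of_hubs(superimpose(star, min_support = 2))
  expect_equal(hs$gene, "HUB")
  expect_equal(hs$connectivity, 4L)
})

test_that("the core equation collects direct neighbours of the hub", {
  sup <- superimpose(three_disease_core_map())
  eq <- core_equation(sup, "AKT1")
  expect_equal(eq$inputs, c("CD44", "EGFR"))
  expect_equal(eq$outputs, c("MMP9", "NFKB1", "STAT3"))
  expect_equal(eq$n_nodes, 6L)
  expect_equal(eq$n_nodes, length(eq$inputs) + 1L + length(eq$outputs))
  expect_error(core_equation(sup, "NOT_THERE"), "absent")
  # isolated hub: empty equation
  eq_iso <- core_equation(sup, "IFNG")
  expect_equal(eq_iso$n_nodes, 1L)
})

test_that("the printed counts are invariant to the ambiguous MMP wiring", {
  # swap which of NFKB1/STAT3 feeds MMP1 vs MMP9: hub, equation size and
  # participant count must not change
  alt <- tibble::tibble(
    source = c("EGFR", "CD44", "AKT1", "AKT1", "AKT1", "NFKB1", "STAT3",
               "CTNNB1", "CTNNB1"),
    target = c("AKT1", "AKT1", "NFKB1", "STAT3", "MMP9", "MMP1", "MMP9",
               "MMP1", "MMP9"),
    effect = "activate")
  maps <- disease_maps(dplyr::bind_rows(lapply(c("d1", "d2", "d3"), function(d) {
    dplyr::mutate(alt, disease = d)
  })), isolated = "IFNG")
  sup <- superimpose(maps)
  expect_equal(hub_of_hubs(sup)$gene, "AKT1")
  expect_equal(core_equation(sup, "AKT1")$n_nodes, 6L)
  expect_length(participating_genes(sup, candidate_meta_hubs()), 8L)
})

test_that("participating candidates are those touching a superimposed edge", {
  sup <- superimpose(three_disease_core_map())
  part <- participating_genes(sup, candidate_meta_hubs())
  expect_length(part, 8L)
  expect_false("IFNG" %in% part)
  expect_equal(participating_genes(sup, c("ZZZ1", "ZZZ2")), character(0))
  all_nodes <- map_nodes(sup)
  expect_equal(participating_genes(sup, all_nodes), setdiff(all_nodes, "IFNG"))
})

test_that("planted shared map cores are recovered exactly", {
  for (seed in c(4, 9, 14)) {
    spec <- synthetic_spec(rng_seed = seed)
    gen <- gen_disease_maps(spec)
    sup <- suppressWarnings(superimpose(gen$maps))
    got <- dplyr::arrange(dplyr::select(sup$edges, source, target, effect),
                          source, target)
    expect_equal(got, gen$truth$core_edges)
  }
})
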