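#' Specification for the synthetic study generators
#'
#' The defaults emulate the study conditions the pipeline was designed
#' for: three diseases whose text-mined gene lists (376, 567 and 360
#' genes) share a planted 31-gene core inside a 2000-gene universe; a
#' sparse interactome with one planted dense module; a gene-set collection
#' with a handful of genuinely enriched terms among decoys; expression
#' annotations with a small concordant subset; and three directed disease
#' maps sharing a planted signalling core.
#'
#' @param rng_seed integer seed; every generator is a pure function of the
#'   spec, so equal seeds give byte-identical outputs.
#' @param universe_size size of the gene universe.
#' @param list_sizes named integer vector of per-disease list sizes.
#' @param core_size number of genes planted in every disease list.
#' @param dup_rate fraction of extra duplicate occurrences injected into
#'   each list (emulating multi-article mentions); 0 disables.
#' @param module_size,p_in,p_out,background_n planted-module network:
#'   `module_size` vertices wired with probability `p_in`, remaining
#'   `background_n - module_size` background vertices (and cross pairs)
#'   wired with probability `p_out`.
#' @param planted_hub also wire one designated hub vertex to every node?
#' @param n_terms,n_planted_terms,term_size,planted_fraction gene-set
#'   collection: `n_planted_terms` terms each containing
#'   `ceiling(planted_fraction * |query|)` query genes, the rest decoys of
#'   `term_size` random universe genes.
#' @param diseases disease labels.
#' @param n_concordant number of genes planted with a concordant
#'   expression direction across all diseases.
#' @param map_pool_size,map_core_edges,map_noise_edges disease maps: node
#'   pool size, shared core edge count, per-disease noise edge count.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(rng_seed = 1L,
                           universe_size = 2000L,
                           list_sizes = c(T2DM = 376L, OA = 567L, TNBC = 360L),
                           core_size = 31L,
                           dup_rate = 0.1,
                           module_size = 8L, p_in = 1.0, p_out = 0.05,
                           background_n = 40L, planted_hub = FALSE,
                           n_terms = 25L, n_planted_terms = 5L,
                           term_size = 40L, planted_fraction = 0.8,
                           diseases = c("T2DM", "OA", "TNBC"),
                           n_concordant = 3L,
                           map_pool_size = 20L, map_core_edges = 9L,
                           map_noise_edges = 6L) {
  if (core_size > universe_size) abort("core_size exceeds universe")
  if (core_size > min(list_sizes)) abort("core_size exceeds the smallest list")
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1)) abort("need 0 <= p_out <= p_in <= 1")
  if (module_size < 3 || background_n < module_size) abort("need module_size >= 3 and background_n >= module_size")
  if (planted_fraction <= 0 || planted_fraction > 1) abort("planted_fraction must be in (0, 1]")
  structure(as.list(environment()), class = "synthetic_spec")
}

syn_universe <- function(spec) sprintf("G%04d", seq_len(spec$universe_size))

#' Generate disease gene lists with a planted common core
#'
#' Each disease list is the planted core plus a disease-specific draw
#' without replacement from the universe; a repair pass removes any gene
#' that accidentally lands in every list, so the all-list intersection
#' equals the planted core exactly. Duplicate occurrences are then
#' injected at `dup_rate` and recorded.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional directory; when given, one `<disease>.txt` file
#'   (one symbol per line) is written per disease.
#' @return a list with `collection` (a `gene_lists` object), `truth`
#'   (list: `core`, `multiplicity` tibble) and `paths` (when written).
#' @export
gen_gene_lists <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  universe <- syn_universe(spec)
  with_seed(spec$rng_seed, {
    core <- sort(sample(universe, spec$core_size))
    pool <- setdiff(universe, core)
    sizes <- pmin(spec$list_sizes, spec$universe_size)
    extras <- lapply(sizes, function(sz) sample(pool, sz - spec$core_size))
    # repair: no non-core gene may sit in every list
    repeat {
      accidental <- Reduce(intersect, extras)
      if (!length(accidental)) break
      for (g in accidental) {
        i <- which.max(vapply(extras, length, integer(1)))
        in_all_others <- Reduce(intersect, extras[-i])
        candidates <- setdiff(pool, c(extras[[i]], in_all_others))
        extras[[i]] <- setdiff(extras[[i]], g)
        if (length(candidates)) {
          extras[[i]] <- c(extras[[i]], sample(candidates, 1))
        }
      }
    }
    lists <- lapply(extras, function(e) sample(c(core, e)))
    names(lists) <- names(spec$list_sizes)
    if (spec$dup_rate > 0) {
      lists <- lapply(lists, function(l) {
        n_dup <- floor(spec$dup_rate * length(l))
        if (n_dup > 0) l <- sample(c(l, sample(l, n_dup, replace = TRUE)))
        l
      })
    }
    multiplicity <- tibble(gene = unlist(lists, use.names = FALSE)) |>
      dplyr::count(.data$gene, name = "n_occurrences") |>
      dplyr::arrange(.data$gene)
    collection <- new_gene_lists(lists, universe = universe)
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- vapply(names(lists), function(nm) {
        p <- file.path(dir, paste0(nm, ".txt"))
        writeLines(lists[[nm]], p)
        p
      }, character(1))
    }
    list(collection = collection,
         truth = list(core = core, multiplicity = multiplicity),
         paths = paths)
  })
}

#' Generate a planted-module interaction network
#'
#' `background_n` vertices; the first `module_size` form the planted
#' module, wired with probability `p_in`; every other pair is wired with
#' probability `p_out`. When `planted_hub` is set an extra vertex `HUB` is
#' wired to every node. Confidence scores are uniform on `(0.4, 1)`, so
#' the default 0.4 load threshold is non-trivial but lossless.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional directory; writes `network.tsv`.
#' @param node_names optional character vector of `background_n` symbols to
#'   use as node names (the first `module_size` become the module); when a
#'   simulated study is assembled end-to-end these are core genes, so the
#'   network stage is coherent with the gene-list stage.
#' @return a list with `network` (a `ppi_network`), `truth` (list:
#'   `module`, `hub`, `nodes`, `n_edges`) and `paths`.
#' @export
gen_planted_network <- function(spec, dir = NULL, node_names = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  m <- spec$module_size
  n <- spec$background_n
  nodes <- if (!is.null(node_names)) {
    if (length(node_names) != n) abort("node_names must have background_n entries")
    normalize_symbols(node_names)
  } else {
    c(sprintf("M%02d", seq_len(m)), sprintf("B%02d", seq_len(n - m)))
  }
  with_seed(spec$rng_seed + 1L, {
    pairs <- combn(nodes, 2, simplify = FALSE)
    keep <- vapply(pairs, function(p) {
      p_edge <- if (all(p %in% nodes[seq_len(m)])) spec$p_in else spec$p_out
      runif(1) < p_edge
    }, logical(1))
    el <- pairs[keep]
    hub <- NULL
    if (spec$planted_hub) {
      hub <- "AHUB"  # lexicographically early so rank ties favour the hub
      el <- c(el, lapply(nodes, function(v) c(hub, v)))
      nodes <- c(hub, nodes)
    }
    edges <- tibble(
      node1 = vapply(el, `[[`, character(1), 1L),
      node2 = vapply(el, `[[`, character(1), 2L),
      score = runif(length(el), 0.4, 1.0)
    )
    net <- ppi_network(edges, min_score = 0.4, keep_isolated = TRUE,
                       query_nodes = nodes)
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- file.path(dir, "network.tsv")
      readr::write_tsv(dplyr::rename(net$edges, score = "weight"), paths)
    }
    list(network = net,
         truth = list(module = nodes[seq_len(m) + as.integer(spec$planted_hub)],
                      hub = hub, nodes = sort(nodes), n_edges = nrow(net$edges)),
         paths = paths)
  })
}

#' Generate a gene-set collection with planted enriched terms
#'
#' Planted terms contain `ceiling(planted_fraction * |query|)` query genes
#' topped up to `term_size` with background genes; decoy terms are uniform
#' draws from the universe.
#'
#' @param spec a [synthetic_spec()].
#' @param query character vector of query genes (added to the universe if
#'   absent).
#' @param dir optional directory; writes `collection.gmt`.
#' @return a list with `collection` (a `geneset_collection`), `truth`
#'   (list: `planted_terms`, `decoy_terms`) and `paths`.
#' @export
gen_gene_set_collection <- function(spec, query, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  query <- unique(normalize_symbols(query))
  universe <- sort(unique(c(syn_universe(spec), query)))
  n_from_query <- ceiling(spec$planted_fraction * length(query))
  if (n_from_query > spec$term_size) {
    abort("planted_fraction * |query| exceeds term_size")
  }
  with_seed(spec$rng_seed + 2L, {
    terms <- list()
    planted <- sprintf("PLANTED_%02d", seq_len(spec$n_planted_terms))
    for (t in planted) {
      members <- sample(query, n_from_query)
      filler <- sample(setdiff(universe, query), spec$term_size - n_from_query)
      terms[[t]] <- sample(c(members, filler))
    }
    decoys <- sprintf("DECOY_%02d", seq_len(spec$n_terms - spec$n_planted_terms))
    for (t in decoys) terms[[t]] <- sample(universe, spec$term_size)
    collection <- geneset_collection(terms, universe = universe)
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- file.path(dir, "collection.gmt")
      writeLines(vapply(names(terms), function(t) {
        paste(c(t, "synthetic gene set", terms[[t]]), collapse = "\t")
      }, character(1)), paths)
    }
    list(collection = collection,
         truth = list(planted_terms = planted, decoy_terms = decoys),
         paths = paths)
  })
}

#' Generate expression-direction annotations
#'
#' A designated subset of genes is concordant (same known direction across
#' all diseases); every other gene is forced discordant or unknown
#' somewhere, so the concordant set is exactly recoverable.
#'
#' @param spec a [synthetic_spec()].
#' @param genes character vector of genes to annotate.
#' @param source annotation provenance label.
#' @param dir optional directory; writes `expression_<source>.tsv`.
#' @return a list with `annotation` (tibble `gene`, `disease`,
#'   `direction`, `source`), `truth` (list: `concordant`) and `paths`.
#' @export
gen_expression_annotations <- function(spec, genes, source = "database",
                                       dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- unique(normalize_symbols(genes))
  D <- spec$diseases
  n_conc <- min(spec$n_concordant, length(genes))
  with_seed(spec$rng_seed + 3L + (source == "literature"), {
    concordant <- sort(sample(genes, n_conc))
    rows <- lapply(genes, function(g) {
      if (g %in% concordant) {
        dirn <- rep(sample(c("up", "down"), 1), length(D))
      } else {
        dirn <- sample(c("up", "down", "unknown"), length(D), replace = TRUE)
        if (length(unique(dirn)) == 1L && dirn[1] != "unknown") {
          flip <- sample(length(D), 1)
          dirn[flip] <- if (dirn[flip] == "up") "down" else "up"
          if (length(D) == 1L) dirn[1] <- "unknown"
        }
      }
      tibble(gene = g, disease = D, direction = dirn, source = source)
    })
    annotation <- dplyr::bind_rows(rows)
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- file.path(dir, paste0("expression_", source, ".tsv"))
      readr::write_tsv(annotation, paths)
    }
    list(annotation = annotation, truth = list(concordant = concordant),
         paths = paths)
  })
}

#' Generate directed disease maps with a planted shared core
#'
#' The same `map_core_edges` directed edges (with shared effects) are
#' placed in every disease map; per-disease noise edges use pairs drawn
#' disjointly across diseases, so superimposition at full support returns
#' exactly the planted core.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional directory; writes `disease_maps.tsv`.
#' @return a list with `maps` (a `disease_maps` object), `truth` (list:
#'   `core_edges` tibble) and `paths`.
#' @export
gen_disease_maps <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nodes <- sprintf("N%02d", seq_len(spec$map_pool_size))
  D <- spec$diseases
  with_seed(spec$rng_seed + 5L, {
    all_pairs <- expand.grid(source = nodes, target = nodes,
                             stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$source != all_pairs$target, ]
    need <- spec$map_core_edges + length(D) * spec$map_noise_edges
    if (need > nrow(all_pairs)) abort("not enough node pairs for requested edges")
    idx <- sample(nrow(all_pairs), need)
    core <- tibble(source = all_pairs$source[idx[seq_len(spec$map_core_edges)]],
                   target = all_pairs$target[idx[seq_len(spec$map_core_edges)]])
    core$effect <- sample(c("activate", "inhibit", "regulate"),
                          nrow(core), replace = TRUE)
    noise_idx <- idx[-seq_len(spec$map_core_edges)]
    rows <- list()
    for (d in seq_along(D)) {
      take <- noise_idx[seq.int((d - 1) * spec$map_noise_edges + 1,
                                d * spec$map_noise_edges)]
      noise <- tibble(source = all_pairs$source[take],
                      target = all_pairs$target[take])
      if (nrow(noise)) {
        noise$effect <- sample(c("activate", "inhibit", "regulate"),
                               nrow(noise), replace = TRUE)
      }
      both <- rbind(core, noise)
      both$disease <- D[d]
      rows[[d]] <- both
    }
    edges <- dplyr::bind_rows(rows)
    maps <- disease_maps(edges)
    core_tbl <- dplyr::arrange(as_tibble(core), .data$source, .data$target)
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- file.path(dir, "disease_maps.tsv")
      readr::write_tsv(maps$edges, paths)
    }
    list(maps = maps, truth = list(core_edges = core_tbl), paths = paths)
  })
}

#' Write every synthetic input plus its ground truth
#'
#' Runs all five generators into one directory and records the combined
#' ground truth as `ground_truth.json`.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created).
#' @return invisibly, a list with all generator outputs plus `truth_path`.
#' @export
simulate_all <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gl <- gen_gene_lists(spec, dir)
  nn <- if (spec$background_n <= spec$core_size) {
    gl$truth$core[seq_len(spec$background_n)]
  } else {
    extra <- with_seed(spec$rng_seed + 7L,
                       sample(setdiff(syn_universe(spec), gl$truth$core),
                              spec$background_n - spec$core_size))
    c(gl$truth$core, extra)
  }
  net <- gen_planted_network(spec, dir, node_names = nn)
  gmt <- gen_gene_set_collection(spec, query = gl$truth$core, dir = dir)
  db <- gen_expression_annotations(spec, gl$truth$core, "database", dir)
  lit <- gen_expression_annotations(spec, gl$truth$core, "literature", dir)
  maps <- gen_disease_maps(spec, dir)
  truth <- list(
    core = gl$truth$core,
    multiplicity = gl$truth$multiplicity,
    module = net$truth$module,
    hub = net$truth$hub,
    planted_terms = gmt$truth$planted_terms,
    concordant_db = db$truth$concordant,
    concordant_lit = lit$truth$concordant,
    map_core_edges = maps$truth$core_edges
  )
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(gene_lists = gl, network = net, collection = gmt,
                 expression_db = db, expression_lit = lit, maps = maps,
                 truth = truth, truth_path = truth_path))
}
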