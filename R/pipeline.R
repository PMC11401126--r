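#' Pipeline configuration
#'
#' Collects input paths and per-stage parameters for [run_pipeline()].
#' Any input path may be `NULL`; the corresponding stage (and stages that
#' depend only on it) are skipped and marked so in the manifest.
#'
#' @param gene_lists named character vector of per-disease gene-list paths.
#' @param gene_list_dialect dialect for [read_gene_lists()].
#' @param network path to the weighted edge-list TSV.
#' @param gmt path to a GMT collection.
#' @param db_expression,lit_expression expression annotation TSV paths.
#' @param disease_maps path to a directed disease-map TSV.
#' @param out_dir output directory for stage artifacts.
#' @param min_score network confidence threshold.
#' @param centrality a [centrality_params()] list.
#' @param mcode an [mcode_params()] list.
#' @param alpha enrichment significance threshold.
#' @param kappa_threshold term-grouping threshold.
#' @param k consensus top-list depth.
#' @param min_support disease-map superimposition support (`NULL` = all).
#' @param rng_seed seed forwarded to the stochastic EPC measure.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(gene_lists = NULL,
                            gene_list_dialect = "one-per-line",
                            network = NULL, gmt = NULL,
                            db_expression = NULL, lit_expression = NULL,
                            disease_maps = NULL,
                            out_dir = tempfile("metahub_run_"),
                            min_score = 0.4,
                            centrality = centrality_params(),
                            mcode = mcode_params(),
                            alpha = 0.05, kappa_threshold = 0.4,
                            k = 10, min_support = NULL, rng_seed = 1L) {
  cfg <- as.list(environment())
  for (p in c(cfg$gene_lists, cfg$network, cfg$gmt, cfg$db_expression,
              cfg$lit_expression, cfg$disease_maps)) {
    if (!is.null(p) && !file.exists(p)) abort(paste0("input not found: ", p))
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] arguments; nested `centrality` and
#' `mcode` blocks override individual parameter defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cent <- do.call(centrality_params, raw$centrality %||% list())
  mc <- do.call(mcode_params, raw$mcode %||% list())
  raw$centrality <- cent
  raw$mcode <- mc
  if (!is.null(raw$gene_lists)) raw$gene_lists <- unlist(raw$gene_lists)
  do.call(pipeline_config, raw)
}

#' Run the full meta-hub discovery pipeline
#'
#' Stage sequence: gene-list intersection (Venn) -> network summary ->
#' 11-measure hub ranking -> MCODE clustering -> consensus + hub/cluster
#' merge -> enrichment (with kappa grouping) -> seven-parameter
#' prioritization -> disease-map superimposition and core equation. Each
#' stage writes its artifact under `out_dir` and is recorded in the
#' manifest with parameters and input digests; stages whose inputs are
#' absent are marked `skipped` and downstream stages degrade explicitly
#' (the prioritization ledger fills missing signals with zeros/unknown).
#' Progress is logged to standard error.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return a list of class `pipeline_result`: per-stage results plus
#'   `manifest` (tibble `stage`, `status`, `artifact`) written alongside
#'   the artifacts as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifest <- list()
  t0 <- Sys.time()
  log_stage <- function(stage, status, artifact = NA_character_) {
    message(sprintf("[%5.1fs] %-14s %s", as.numeric(Sys.time() - t0, units = "secs"),
                    stage, status))
    manifest[[length(manifest) + 1L]] <<- tibble(stage = stage, status = status,
                                                 artifact = artifact)
  }
  run_stage <- function(stage, enabled, fn) {
    if (!enabled) {
      log_stage(stage, "skipped")
      return(NULL)
    }
    out <- tryCatch(fn(), error = function(e) {
      log_stage(stage, paste0("failed: ", conditionMessage(e)))
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
    log_stage(stage, "completed", out$artifact %||% NA_character_)
    out$value
  }
  art <- function(name) file.path(config$out_dir, name)

  res$venn <- run_stage("venn", !is.null(config$gene_lists), function() {
    gl <- read_gene_lists(config$gene_lists, dialect = config$gene_list_dialect)
    v <- intersect_all(gl)
    write_venn(v, art("venn.tsv"), art("venn.json"))
    list(value = list(collection = gl, venn = v), artifact = "venn.tsv")
  })

  net_ok <- !is.null(config$network)
  res$network <- run_stage("net_summary", net_ok, function() {
    net <- read_network(config$network, min_score = config$min_score)
    s <- network_summary(net)
    jsonlite::write_json(as.list(s), art("network_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(value = list(network = net, summary = s), artifact = "network_summary.json")
  })

  res$ranks <- run_stage("hub_ranking", net_ok, function() {
    params <- config$centrality
    params$rng_seed <- config$rng_seed
    rt <- compute_all(res$network$network, params)
    readr::write_tsv(tidy(rt), art("rank_table.tsv"))
    list(value = rt, artifact = "rank_table.tsv")
  })

  res$mcode <- run_stage("mcode", net_ok, function() {
    mc <- find_clusters(res$network$network, config$mcode)
    write_clusters(mc, art("clusters.json"))
    list(value = mc, artifact = "clusters.json")
  })

  res$merge <- run_stage("consensus_merge", net_ok, function() {
    cons <- consensus_rank(res$ranks, k = config$k)
    readr::write_tsv(tidy(cons), art("consensus.tsv"))
    if (!length(res$mcode$clusters)) abort("no cluster to merge with")
    cl_top <- top_cluster_genes(res$mcode$clusters[[1]], k = config$k)
    merged <- merge_hub_cluster(cons$meta_hubs, cl_top)
    readr::write_tsv(tidy(merged), art("merged.tsv"))
    list(value = list(consensus = cons, cluster_top = cl_top, merged = merged),
         artifact = "merged.tsv")
  })

  enrich_ok <- !is.null(config$gmt) && !is.null(res$merge)
  res$enrichment <- run_stage("enrichment", enrich_ok, function() {
    coll <- read_gmt(config$gmt)
    er <- fisher_enrich(res$merge$merged$union_list, coll, alpha = config$alpha)
    write_enrichment(er, art("enrichment.tsv"))
    groups <- if (any(er$significant)) {
      kappa_group(er, kappa_threshold = config$kappa_threshold)
    } else NULL
    if (!is.null(groups)) {
      readr::write_tsv(dplyr::mutate(groups, terms = vapply(.data$terms, paste,
                       character(1), collapse = ";")), art("term_groups.tsv"))
    }
    list(value = list(records = er, groups = groups), artifact = "enrichment.tsv")
  })

  prio_ok <- !is.null(res$merge)
  res$prioritized <- run_stage("prioritize", prio_ok, function() {
    merged <- res$merge$merged
    red <- if (!is.null(res$venn)) {
      redundancy_counts(res$venn$collection, merged$union_list)
    } else tibble(gene = merged$union_list, n_occurrences = 0L)
    db <- if (!is.null(config$db_expression)) read_expression_annotation(config$db_expression, "database")
    lit <- if (!is.null(config$lit_expression)) read_expression_annotation(config$lit_expression, "literature")
    ledger <- build_ledger(merged, red, res$merge$consensus, res$merge$cluster_top,
                           enrichment = res$enrichment$records,
                           db_expression = db, lit_expression = lit)
    ps <- shortlist(ledger)
    write_shortlist(ps, art("shortlist.json"))
    list(value = ps, artifact = "shortlist.json")
  })

  map_ok <- !is.null(config$disease_maps)
  res$map <- run_stage("disease_map", map_ok, function() {
    maps <- read_disease_map(config$disease_maps)
    sup <- superimpose(maps, min_support = config$min_support)
    write_sif(sup, art("superimposed.sif"))
    hub <- hub_of_hubs(sup)
    eq <- core_equation(sup, hub$gene)
    jsonlite::write_json(list(hub = hub$gene, connectivity = hub$connectivity,
                              inputs = eq$inputs, outputs = eq$outputs,
                              n_nodes = eq$n_nodes),
                         art("core_equation.json"), auto_unbox = TRUE, digits = NA)
    list(value = list(superimposed = sup, hub = hub, equation = eq),
         artifact = "core_equation.json")
  })

  manifest <- dplyr::bind_rows(manifest)
  inputs <- purrr::compact(list(gene_lists = config$gene_lists,
                                network = config$network, gmt = config$gmt,
                                db_expression = config$db_expression,
                                lit_expression = config$lit_expression,
                                disease_maps = config$disease_maps))
  digests <- lapply(inputs, function(p) unname(tools::md5sum(p)))
  params <- list(min_score = config$min_score,
                 centrality = unclass(config$centrality),
                 mcode = unclass(config$mcode),
                 alpha = config$alpha, kappa_threshold = config$kappa_threshold,
                 k = config$k, min_support = config$min_support,
                 rng_seed = config$rng_seed)
  jsonlite::write_json(list(stages = manifest, parameters = params,
                            input_digests = digests),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(c(res, list(manifest = manifest, out_dir = config$out_dir)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> in ", x$out_dir, "\n", sep = "")
  print(x$manifest)
  invisible(x)
}
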