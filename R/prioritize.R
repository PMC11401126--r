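#' Read an expression-direction annotation table
#'
#' TSV with columns `gene`, `disease`, `direction` (`up`, `down` or
#' `unknown`) and optionally `source` (`database` or `literature`).
#'
#' @param path TSV path.
#' @param source annotation provenance recorded when the file has no
#'   `source` column.
#' @return a tibble `gene`, `disease`, `direction`, `source`.
#' @export
read_expression_annotation <- function(path, source = "database") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene", "disease", "direction") %in% names(df))) {
    abort("annotation needs columns gene, disease, direction")
  }
  bad <- setdiff(unique(df$direction), c("up", "down", "unknown"))
  if (length(bad)) abort(paste0("unknown direction token: ", bad[1]))
  if (!"source" %in% names(df)) df$source <- source
  dplyr::mutate(as_tibble(df), gene = normalize_symbols_keep(.data$gene))
}

#' Assemble the seven-parameter prioritization ledger
#'
#' The ledger gathers, restricted to the merged meta-hub list, the seven
#' prioritization signals: (1) redundancy in the parent text-mining lists;
#' (2) consensus hub rank; (3) cluster weight rank; (4) membership in the
#' hub/cluster overlap; (5) number of significant enriched terms containing
#' the gene; (6) database and (7) literature expression direction across
#' the configured diseases. Missing entries default to 0 / `unknown` with a
#' warning.
#'
#' @param merged a [merge_hub_cluster()] result.
#' @param redundancy tibble `gene`, `n_occurrences` (see
#'   [redundancy_counts()]).
#' @param consensus a [consensus_rank()] result.
#' @param cluster_top ordered character vector from [top_cluster_genes()].
#' @param enrichment an `enrichment_result` from [fisher_enrich()], used
#'   for per-gene significant-term counts.
#' @param db_expression,lit_expression annotation tibbles (see
#'   [read_expression_annotation()]); `NULL` entries are treated as
#'   all-unknown.
#' @param diseases character vector of disease labels the expression
#'   concordance is judged over; defaults to the labels present in the
#'   annotations.
#' @return a list of class `priority_ledger`.
#' @export
build_ledger <- function(merged, redundancy, consensus, cluster_top,
                         enrichment = NULL, db_expression = NULL,
                         lit_expression = NULL, diseases = NULL) {
  stopifnot(inherits(merged, "merge_result"),
            inherits(consensus, "consensus_result"))
  genes <- merged$union_list

  red <- setNames(rep(0L, length(genes)), genes)
  hit <- intersect(genes, redundancy$gene)
  red[hit] <- redundancy$n_occurrences[match(hit, redundancy$gene)]
  if (length(setdiff(genes, redundancy$gene))) {
    warn("redundancy missing for some merged genes; defaulting to 0")
  }

  cons_rank <- setNames(rep(NA_integer_, length(genes)), genes)
  rk <- consensus$ranking
  hit <- intersect(genes, rk$gene)
  cons_rank[hit] <- match(hit, rk$gene)

  clus_rank <- setNames(rep(NA_integer_, length(genes)), genes)
  hit <- intersect(genes, cluster_top)
  clus_rank[hit] <- match(hit, cluster_top)

  enrich_freq <- setNames(rep(0L, length(genes)), genes)
  if (!is.null(enrichment)) {
    stopifnot(inherits(enrichment, "enrichment_result"))
    sig <- dplyr::filter(as_tibble(enrichment), .data$significant)
    counts <- table(factor(unlist(sig$genes), levels = genes))
    enrich_freq[] <- as.integer(counts[genes])
  }

  db_dir <- expression_matrix(db_expression, genes, diseases)
  lit_dir <- expression_matrix(lit_expression, genes, diseases)
  if (!is.null(db_expression) && !is.null(lit_expression)) {
    d1 <- sort(unique(db_expression$disease))
    d2 <- sort(unique(lit_expression$disease))
    if (is.null(diseases) && !identical(d1, d2)) {
      abort("disease labels differ between database and literature annotations")
    }
  }

  structure(list(
    genes = genes,
    overlap = merged$overlap,
    redundancy = red,
    consensus_rank = cons_rank,
    cluster_rank = clus_rank,
    enrich_freq = enrich_freq,
    db_expression = db_dir,
    lit_expression = lit_dir
  ), class = "priority_ledger")
}

# gene x disease direction matrix, "unknown" filled
expression_matrix <- function(ann, genes, diseases = NULL) {
  if (is.null(ann)) {
    diseases <- diseases %||% character(0)
    m <- matrix("unknown", nrow = length(genes), ncol = length(diseases),
                dimnames = list(genes, diseases))
    return(m)
  }
  diseases <- diseases %||% sort(unique(ann$disease))
  m <- matrix("unknown", nrow = length(genes), ncol = length(diseases),
              dimnames = list(genes, diseases))
  ann <- dplyr::filter(ann, .data$gene %in% genes, .data$disease %in% diseases)
  if (nrow(ann)) m[cbind(ann$gene, ann$disease)] <- ann$direction
  missing <- length(genes) * length(diseases) - nrow(dplyr::distinct(ann, .data$gene, .data$disease))
  if (missing > 0) warn(paste0(missing, " expression entries missing; treated as unknown"))
  m
}

#' Shortlist candidate meta-hub genes
#'
#' Selection policy per parameter: (1), (5) the single maximum (redundancy,
#' enrichment frequency); (2), (3) the single best (smallest) rank; ties
#' broken by symbol. (4) admits every member of the hub/cluster overlap.
#' (6), (7) admit every gene whose direction is identical — and not
#' `unknown` — across all configured diseases. The shortlist is the union,
#' with per-gene provenance recording which parameters selected it.
#'
#' @param ledger a [build_ledger()] result.
#' @return an object of class `prioritized_set`: list with `shortlist`
#'   (sorted character) and `provenance` (named list gene -> parameter
#'   labels).
#' @export
shortlist <- function(ledger) {
  stopifnot(inherits(ledger, "priority_ledger"))
  if (!length(ledger$genes)) abort("empty ledger")
  sel <- list()
  pick_max <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x) || all(x <= 0)) return(character(0))
    best <- names(x)[x == max(x)]
    sort(best)[1]
  }
  pick_min_rank <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(character(0))
    best <- names(x)[x == min(x)]
    sort(best)[1]
  }
  sel[["1_redundancy"]] <- pick_max(ledger$redundancy)
  sel[["2_hub_rank"]] <- pick_min_rank(ledger$consensus_rank)
  sel[["3_cluster_rank"]] <- pick_min_rank(ledger$cluster_rank)
  sel[["4_overlap"]] <- ledger$overlap
  sel[["5_enrichment"]] <- pick_max(ledger$enrich_freq)
  sel[["6_db_expression"]] <- concordant_genes(ledger$db_expression)
  sel[["7_lit_expression"]] <- concordant_genes(ledger$lit_expression)
  genes <- sort(unique(unlist(sel)))
  provenance <- lapply(setNames(genes, genes), function(g) {
    names(sel)[vapply(sel, function(s) g %in% s, logical(1))]
  })
  structure(list(shortlist = genes, provenance = provenance, selections = sel),
            class = "prioritized_set")
}

# genes whose direction agrees (and is known) across every disease column
concordant_genes <- function(m) {
  if (is.null(m) || ncol(m) == 0) return(character(0))
  keep <- apply(m, 1L, function(row) {
    length(unique(row)) == 1L && row[1] != "unknown"
  })
  sort(rownames(m)[keep])
}

#' @export
print.prioritized_set <- function(x, ...) {
  cat("<prioritized_set> ", length(x$shortlist), " candidate(s): ",
      paste(x$shortlist, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname shortlist
#' @param x a `prioritized_set`.
#' @param ... unused.
#' @export
tidy.prioritized_set <- function(x, ...) {
  tibble(gene = x$shortlist,
         n_parameters = vapply(x$provenance[x$shortlist], length, integer(1)),
         parameters = vapply(x$provenance[x$shortlist], paste,
                             character(1), collapse = ";"))
}

#' Write a prioritized shortlist to JSON
#'
#' @param set a `prioritized_set`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_shortlist <- function(set, path) {
  stopifnot(inherits(set, "prioritized_set"))
  jsonlite::write_json(list(shortlist = set$shortlist, provenance = set$provenance),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
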