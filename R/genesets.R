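#' Read disease gene lists
#'
#' Reads one or more per-disease gene lists into a gene-list collection.
#' Three dialects are supported: `"one-per-line"` (one symbol per line),
#' `"semicolon"` (a single `;`-separated string, possibly spanning lines),
#' and `"tsv-column"` (first column of a TSV, header auto-skipped when it is
#' not a plausible symbol line). Duplicates are preserved in the stored
#' sequence — they carry the number of source articles mentioning a gene —
#' and reported via a message; set operations downstream use distinct
#' symbols only.
#'
#' @param paths named character vector of file paths; names are disease
#'   labels (unnamed paths get their base name).
#' @param dialect one of `"one-per-line"`, `"semicolon"`, `"tsv-column"`.
#' @param universe optional character vector restricting the gene universe.
#' @return an object of class `gene_lists`: a list with elements `lists`
#'   (named list of normalized symbol sequences, duplicates kept) and
#'   `universe` (character or `NULL`).
#' @examples
#' f <- tempfile()
#' writeLines("LCK; STAT1; IFNG", f)
#' gl <- read_gene_lists(c(demo = f), dialect = "semicolon")
#' gene_list_sizes(gl)
#' @export
read_gene_lists <- function(paths, dialect = c("one-per-line", "semicolon", "tsv-column"),
                            universe = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    nm <- names(paths) %||% rep("", length(paths))
    nm[!nzchar(nm)] <- tools::file_path_sans_ext(basename(paths[!nzchar(nm)]))
    names(paths) <- nm
  }
  if (anyDuplicated(names(paths))) abort("disease labels must be unique")
  lists <- lapply(paths, function(p) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
    lines <- readLines(p, warn = FALSE)
    toks <- switch(dialect,
      "one-per-line" = lines,
      "semicolon"    = unlist(strsplit(paste(lines, collapse = ";"), ";", fixed = TRUE)),
      "tsv-column"   = {
        x <- vapply(strsplit(lines, "\t", fixed = TRUE),
                    function(f) if (length(f)) f[[1]] else "", character(1))
        # drop a header row that is clearly not a symbol
        if (length(x) && grepl("^(gene|symbol|name)s?$", x[[1]], ignore.case = TRUE)) x <- x[-1]
        x
      })
    syms <- normalize_symbols(toks)
    if (!length(syms)) abort(paste0("no genes parsed from ", p))
    dup <- sum(duplicated(syms))
    if (dup > 0) {
      inform(paste0(basename(p), ": ", length(syms), " symbols, ",
                    dup, " duplicate occurrence(s) retained in sequence"))
    }
    syms
  })
  new_gene_lists(lists, universe)
}

#' Construct a gene-list collection from in-memory vectors
#'
#' @param lists named list of character vectors (duplicates permitted).
#' @param universe optional character vector of the gene universe.
#' @return a `gene_lists` object.
#' @export
new_gene_lists <- function(lists, universe = NULL) {
  if (is.null(names(lists)) || anyDuplicated(names(lists))) {
    abort("lists must be uniquely named by disease label")
  }
  lists <- lapply(lists, normalize_symbols)
  if (!is.null(universe)) universe <- unique(normalize_symbols(universe))
  structure(list(lists = lists, universe = universe), class = "gene_lists")
}

#' @export
print.gene_lists <- function(x, ...) {
  cat("<gene_lists> ", length(x$lists), " list(s)\n", sep = "")
  for (nm in names(x$lists)) {
    cat("  ", nm, ": ", length(x$lists[[nm]]), " symbols (",
        length(unique(x$lists[[nm]])), " distinct)\n", sep = "")
  }
  invisible(x)
}

#' Per-list sequence and distinct sizes
#'
#' @param collection a `gene_lists` object.
#' @return a tibble with columns `disease`, `n_total`, `n_distinct`.
#' @export
gene_list_sizes <- function(collection) {
  stopifnot(inherits(collection, "gene_lists"))
  tibble(
    disease    = names(collection$lists),
    n_total    = unname(vapply(collection$lists, length, integer(1))),
    n_distinct = unname(vapply(collection$lists, function(x) length(unique(x)),
                               integer(1)))
  )
}

#' Venn intersection of all disease lists
#'
#' Computes, with distinct-symbol semantics, the exclusive Venn region of
#' every non-empty subset of disease labels, plus the common core (genes
#' present in every list).
#'
#' @param collection a `gene_lists` object with at least two lists.
#' @return an object of class `venn_result`: list with `regions` (tibble:
#'   `labels` — `"+"`-joined label subset, `n`, `genes` list-column) and
#'   `core` (sorted character vector of genes common to all lists).
#' @examples
#' gl <- new_gene_lists(list(a = c("A", "B", "C"), b = c("B", "C", "D"), c = c("C", "E")))
#' intersect_all(gl)$core
#' @export
intersect_all <- function(collection) {
  stopifnot(inherits(collection, "gene_lists"))
  if (length(collection$lists) < 2) abort("need at least 2 lists to intersect")
  labs <- names(collection$lists)
  sets <- lapply(collection$lists, unique)
  all_genes <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1L) membership <- matrix(membership, nrow = 1, dimnames = list(NULL, labs))
  key <- apply(membership, 1L, function(row) paste(labs[row], collapse = "+"))
  subsets <- unlist(lapply(seq_along(labs), function(k) {
    combn(labs, k, FUN = paste, collapse = "+", simplify = FALSE)
  }))
  genes_by_region <- split(all_genes, factor(key, levels = subsets))
  regions <- tibble(
    labels = subsets,
    n      = vapply(genes_by_region, length, integer(1)),
    genes  = lapply(genes_by_region, sort)
  )
  core <- sort(Reduce(intersect, sets))
  structure(list(regions = regions, core = core, labels = labs),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat("<venn_result> core of ", length(x$core), " gene(s) across ",
      length(x$labels), " lists\n", sep = "")
  print(dplyr::select(x$regions, "labels", "n"))
  invisible(x)
}

#' @rdname intersect_all
#' @param x a `venn_result`.
#' @param ... unused.
#' @export
tidy.venn_result <- function(x, ...) {
  tidyr::unnest(dplyr::rename(x$regions, gene = "genes"), "gene")
}

#' Overlap a core signature with an annotation gene set
#'
#' @param core non-empty character vector (e.g. a Venn core).
#' @param annotation non-empty character vector of annotation genes.
#' @return a list with `n` (overlap count) and `genes` (sorted overlap).
#' @export
overlap_with_annotation <- function(core, annotation) {
  core <- unique(normalize_symbols(core))
  annotation <- unique(normalize_symbols(annotation))
  if (!length(core)) abort("core gene set is empty")
  if (!length(annotation)) abort("annotation gene set is empty")
  genes <- sort(intersect(core, annotation))
  list(n = length(genes), genes = genes)
}

#' Occurrence counts across raw list sequences
#'
#' Counts total appearances of each gene across all stored sequences,
#' duplicates included — the "redundancy within the parent list" signal used
#' by the prioritization ledger. Genes absent everywhere map to 0.
#'
#' @param collection a `gene_lists` object.
#' @param genes non-empty character vector of genes to count.
#' @return a tibble with columns `gene` and `n_occurrences`.
#' @export
redundancy_counts <- function(collection, genes) {
  stopifnot(inherits(collection, "gene_lists"))
  genes <- unique(normalize_symbols(genes))
  if (!length(genes)) abort("genes must be non-empty")
  pooled <- unlist(collection$lists, use.names = FALSE)
  tab <- table(factor(pooled, levels = genes))
  tibble(gene = genes, n_occurrences = as.integer(tab[genes]))
}

#' Write a Venn result to disk
#'
#' @param venn a `venn_result`.
#' @param tsv_path path for the per-gene TSV (`gene`, `region`).
#' @param json_path optional path for the JSON region-count summary.
#' @return `tsv_path`, invisibly.
#' @export
write_venn <- function(venn, tsv_path, json_path = NULL) {
  stopifnot(inherits(venn, "venn_result"))
  long <- tidy.venn_result(venn)
  readr::write_tsv(dplyr::select(long, gene = "gene", region = "labels"), tsv_path)
  if (!is.null(json_path)) {
    counts <- setNames(as.list(venn$regions$n), venn$regions$labels)
    jsonlite::write_json(list(core_size = length(venn$core), regions = counts),
                         json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(tsv_path)
}
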