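#' Read a GMT gene-set collection
#'
#' Standard GMT: one term per line, tab-separated `term`, `description`,
#' then member genes. Parsed in-package so the description column is
#' retained.
#'
#' @param path GMT file path.
#' @param universe optional character vector; when omitted the universe
#'   defaults to the union of all member genes (this default changes
#'   p-values — supply an explicit background when one is known).
#' @return an object of class `geneset_collection`: list with `terms`
#'   (named list of character vectors), `descriptions` (named character)
#'   and `universe` (character).
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("no gene sets parsed: empty GMT")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short)) abort(paste0("malformed GMT line ", short[1], ": fewer than 3 fields"))
  terms <- lapply(fields, function(f) unique(normalize_symbols(f[-(1:2)])))
  names(terms) <- vapply(fields, `[[`, character(1), 1L)
  desc <- setNames(vapply(fields, `[[`, character(1), 2L), names(terms))
  geneset_collection(terms, descriptions = desc, universe = universe)
}

#' Construct a gene-set collection
#'
#' @param terms named list of character vectors (term name -> members).
#' @param descriptions optional named character vector of descriptions.
#' @param universe optional explicit gene universe; defaults to the union
#'   of all members.
#' @return a `geneset_collection`.
#' @export
geneset_collection <- function(terms, descriptions = NULL, universe = NULL) {
  if (is.null(names(terms)) || anyDuplicated(names(terms))) {
    abort("term names must be unique")
  }
  terms <- lapply(terms, function(x) unique(normalize_symbols(x)))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(terms)))
  } else {
    universe <- sort(unique(normalize_symbols(universe)))
    outside <- setdiff(unlist(terms), universe)
    if (length(outside)) {
      abort(paste0(length(outside),
                   " term member(s) outside the supplied universe (e.g. ",
                   outside[1], ")"))
    }
  }
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(terms)), names(terms))
  structure(list(terms = terms, descriptions = descriptions, universe = universe),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat("<geneset_collection> ", length(x$terms), " terms over a universe of ",
      length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' One-sided hypergeometric tail probability
#'
#' Probability of drawing at least `k` marked genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `m` are
#' marked: `P(X >= k)` with `X ~ Hypergeometric(N, m, n)`. This is the
#' one-sided Fisher exact test for over-representation.
#'
#' @param k observed overlap.
#' @param m term size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return the upper-tail probability.
#' @examples
#' hyper_tail_p(5, 5, 5, 20) # 1 / choose(20, 5)
#' @export
hyper_tail_p <- function(k, m, n, N) {
  if (any(c(k, m, n, N) < 0) || m > N || n > N) abort("invalid hypergeometric configuration")
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Over-representation analysis against a gene-set collection
#'
#' For each term, the one-sided hypergeometric (Fisher) p-value of the
#' query/term overlap is computed within the collection's universe, then
#' Benjamini-Hochberg adjusted across terms. Query genes outside the
#' universe are dropped with a warning.
#'
#' @param query character vector of query genes.
#' @param collection a [geneset_collection].
#' @param alpha significance threshold on the adjusted p-value; default 0.05.
#' @return a tibble of class `enrichment_result` with columns `term`,
#'   `description`, `overlap_k`, `term_m`, `query_n`, `universe_N`,
#'   `p_value`, `q_value`, `significant`, `genes` (list-column of overlap
#'   genes), sorted by p ascending then term ascending.
#' @export
fisher_enrich <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "geneset_collection"))
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  query <- unique(normalize_symbols(query))
  dropped <- setdiff(query, collection$universe)
  if (length(dropped)) {
    warn(paste0(length(dropped), " query gene(s) outside the universe dropped"))
  }
  query <- intersect(query, collection$universe)
  if (!length(query)) abort("empty query after restriction to the universe")
  N <- length(collection$universe)
  n <- length(query)
  rows <- purrr::imap(collection$terms, function(members, term) {
    m <- length(intersect(members, collection$universe))
    ov <- sort(intersect(query, members))
    k <- length(ov)
    tibble(term = term,
           description = unname(collection$descriptions[term]),
           overlap_k = k, term_m = m, query_n = n, universe_N = N,
           p_value = hyper_tail_p(k, m, n, N),
           genes = list(ov))
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < alpha
  out <- dplyr::arrange(out, .data$p_value, .data$term)
  out <- dplyr::select(out, "term", "description", "overlap_k", "term_m",
                       "query_n", "universe_N", "p_value", "q_value",
                       "significant", "genes")
  attr(out, "alpha") <- alpha
  attr(out, "query") <- query
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment `q_i = min_{j >= i} m p_(j) / j` (capped at 1),
#' returned in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' @rdname fisher_enrich
#' @param x an `enrichment_result`.
#' @param ... unused.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_terms = nrow(x), n_significant = sum(x$significant),
         alpha = attr(x, "alpha"))
}

#' @rdname fisher_enrich
#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- dplyr::select(as_tibble(x), -"genes")
  out
}

#' Enrichment bar chart
#'
#' Significant terms by `-log10` adjusted p-value.
#'
#' @param object an `enrichment_result`.
#' @param top show at most this many terms; default 20.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  df <- head(dplyr::filter(as_tibble(object), .data$significant), top)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$q_value), y = .data$term)) +
    ggplot2::geom_col(fill = "#4575b4") +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
                  title = "Over-represented terms") +
    ggplot2::theme_minimal()
}

#' Kappa-statistic grouping of enriched terms
#'
#' Builds, for every significant term, the binary membership vector over
#' the query genes; computes Cohen's kappa for each term pair from the 2x2
#' agreement table; and single-linkage groups terms connected by
#' `kappa >= kappa_threshold`. Each group's representative is its most
#' significant member.
#'
#' @param records an `enrichment_result` (only significant rows are used;
#'   at least one required).
#' @param kappa_threshold linkage threshold; default 0.4.
#' @return a tibble with columns `group`, `representative`, `n_terms`,
#'   `terms` (list-column).
#' @export
kappa_group <- function(records, kappa_threshold = 0.4) {
  stopifnot(inherits(records, "enrichment_result"))
  sig <- dplyr::filter(as_tibble(records), .data$significant)
  if (!nrow(sig)) abort("no significant records to group")
  query <- attr(records, "query")
  memb <- vapply(sig$genes, function(g) query %in% g, logical(length(query)))
  if (length(query) == 1L) memb <- matrix(memb, nrow = 1)
  nt <- nrow(sig)
  # union-find over terms linked by kappa >= threshold
  parent <- seq_len(nt)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nt > 1) {
    for (i in seq_len(nt - 1)) for (j in seq.int(i + 1, nt)) {
      if (cohen_kappa(memb[, i], memb[, j]) >= kappa_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(nt), find, integer(1))
  groups <- split(seq_len(nt), roots)
  rows <- lapply(groups, function(idx) {
    sub <- sig[idx, ]
    rep_idx <- order(sub$p_value, sub$term)[1]
    tibble(representative = sub$term[rep_idx], n_terms = nrow(sub),
           terms = list(sort(sub$term)))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, dplyr::desc(.data$n_terms), .data$representative)
  dplyr::mutate(out, group = dplyr::row_number(), .before = 1)
}

# Cohen's kappa between two binary membership vectors. Identical vectors
# give 1 by convention even when expected agreement is 1.
cohen_kappa <- function(x, y) {
  if (all(x == y)) return(1)
  n <- length(x)
  a <- sum(x & y); b <- sum(x & !y); c <- sum(!x & y); d <- sum(!x & !y)
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Write enrichment records to TSV
#'
#' @param records an `enrichment_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(records, path) {
  out <- tidy.enrichment_result(records)
  out$genes <- vapply(records$genes, paste, character(1), collapse = ";")
  readr::write_tsv(out, path)
  invisible(path)
}
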