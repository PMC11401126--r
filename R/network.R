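#' Construct a protein-protein interaction network
#'
#' Builds a simple, undirected, weighted network over gene symbols from an
#' edge table. Self-loops are dropped with a warning; duplicate pairs
#' (either orientation) are collapsed keeping the maximum score; edges
#' below `min_score` are removed.
#'
#' @param edges a data frame with columns `node1`, `node2`, `score`
#'   (confidence in `[0, 1]`).
#' @param min_score confidence threshold in `[0, 1]`; default 0.4, the
#'   conventional medium-confidence STRING cutoff.
#' @param keep_isolated keep query nodes with no surviving edge?
#' @param query_nodes optional character vector of query genes to retain as
#'   isolated nodes when `keep_isolated = TRUE`.
#' @return an object of class `ppi_network`: list with `edges` (tibble
#'   `node1`, `node2`, `weight`, with `node1 < node2`), `nodes` (sorted
#'   character) and `min_score`.
#' @examples
#' ppi_network(data.frame(node1 = "A", node2 = "B", score = 0.9))
#' @export
ppi_network <- function(edges, min_score = 0.4, keep_isolated = FALSE,
                        query_nodes = NULL) {
  if (min_score < 0 || min_score > 1) abort("min_score must be in [0, 1]")
  edges <- as_tibble(edges)
  if (!all(c("node1", "node2", "score") %in% names(edges))) {
    abort("edges must have columns node1, node2, score")
  }
  edges$node1 <- normalize_symbols_keep(edges$node1)
  edges$node2 <- normalize_symbols_keep(edges$node2)
  if (any(is.na(edges$score)) || any(edges$score < 0) || any(edges$score > 1)) {
    abort("edge scores must lie in [0, 1]")
  }
  loops <- edges$node1 == edges$node2
  if (any(loops)) {
    warn(paste0("dropping ", sum(loops), " self-loop(s)"))
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$node1, edges$node2)
  b <- pmax(edges$node1, edges$node2)
  edges <- tibble(node1 = a, node2 = b, weight = edges$score)
  if (nrow(edges)) {
    edges <- edges |>
      dplyr::group_by(.data$node1, .data$node2) |>
      dplyr::summarise(weight = max(.data$weight), .groups = "drop") |>
      dplyr::filter(.data$weight >= min_score) |>
      dplyr::arrange(.data$node1, .data$node2)
  }
  nodes <- sort(unique(c(edges$node1, edges$node2)))
  if (keep_isolated && !is.null(query_nodes)) {
    nodes <- sort(unique(c(nodes, normalize_symbols(query_nodes))))
  }
  structure(list(edges = edges, nodes = nodes, min_score = min_score),
            class = "ppi_network")
}

# like normalize_symbols() but vector-length preserving (errors on empties)
normalize_symbols_keep <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(is.na(x) | !nzchar(x))) abort("empty gene symbol in edge table")
  if (any(grepl("[;[:space:]]", x))) abort("gene symbols must not contain whitespace or ';'")
  x
}

#' Read a STRING-style weighted edge list
#'
#' Expects at least three tab-separated columns: node1, node2, combined
#' score. A header line is auto-detected (non-numeric third field). Scores
#' are accepted either on the 0-1 scale or as STRING's 0-1000 integers
#' (divided by 1000 when any score exceeds 1).
#'
#' @inheritParams ppi_network
#' @param path TSV file path.
#' @return a `ppi_network`.
#' @export
read_network <- function(path, min_score = 0.4, keep_isolated = FALSE,
                         query_nodes = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("no edges parsed: empty file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  # header: first line whose third field is non-numeric
  start <- 1L
  if (length(fields) && suppressWarnings(is.na(as.numeric(fields[[1]][3])))) start <- 2L
  if (length(bad) && any(bad >= start)) {
    abort(paste0("malformed row at line ", bad[bad >= start][1],
                 ": expected >= 3 tab-separated fields"))
  }
  if (start > length(fields)) abort("no edges parsed: header only")
  fields <- fields[start:length(fields)]
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(score)) {
    abort(paste0("malformed row at line ",
                 which(is.na(score))[1] + start - 1L, ": non-numeric score"))
  }
  if (any(score > 1)) {
    if (any(score > 1000) || any(score < 0)) abort("scores must be in [0,1] or [0,1000]")
    score <- score / 1000
  }
  edges <- tibble(
    node1 = vapply(fields, `[[`, character(1), 1L),
    node2 = vapply(fields, `[[`, character(1), 2L),
    score = score
  )
  ppi_network(edges, min_score = min_score, keep_isolated = keep_isolated,
              query_nodes = query_nodes)
}

#' Write a network back to TSV
#'
#' @param net a `ppi_network`.
#' @param path output TSV path (columns `node1`, `node2`, `weight`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  readr::write_tsv(net$edges, path)
  invisible(path)
}

#' @export
print.ppi_network <- function(x, ...) {
  s <- network_summary(x)
  cat("<ppi_network> ", s$n_nodes, " nodes, ", s$n_edges,
      " edges (min_score = ", x$min_score, ")\n", sep = "")
  cat("  average degree ", format(round(s$avg_degree, 1), nsmall = 1),
      ", density ", signif(s$density, 3), "\n", sep = "")
  invisible(x)
}

#' Network summary statistics
#'
#' Average degree is `2|E|/|V|` (0 for an empty node set); density is
#' `2|E|/(|V|(|V|-1))` for two or more nodes, else 0.
#'
#' @param net a `ppi_network`.
#' @return a one-row tibble: `n_nodes`, `n_edges`, `avg_degree`, `density`.
#' @examples
#' net <- ppi_network(data.frame(node1 = c("A", "A", "B"),
#'                               node2 = c("B", "C", "C"), score = 1))
#' network_summary(net) # K3: average degree 2, density 1
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  nv <- length(net$nodes)
  ne <- nrow(net$edges)
  tibble(
    n_nodes    = nv,
    n_edges    = ne,
    avg_degree = if (nv > 0) 2 * ne / nv else 0,
    density    = if (nv >= 2) 2 * ne / (nv * (nv - 1)) else 0
  )
}

# igraph view of a ppi_network; vertex order = sorted symbols.
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$node1, to = net$edges$node2,
                   weight = net$edges$weight),
    directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
  g
}
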