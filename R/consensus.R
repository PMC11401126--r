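#' Consensus ranking across hub measures
#'
#' A gene's consensus standing is the number of measures placing it in the
#' per-measure top `k` (its "frequency"), with the mean rank over those
#' measures breaking ties, then the symbol. The `meta_hubs` list holds the
#' first `k` genes under that ordering.
#'
#' @param table a `rank_table` from [compute_all()].
#' @param k top-list depth per measure and length of the consensus list;
#'   default 10.
#' @return an object of class `consensus_result`: list with `ranking`
#'   (tibble `gene`, `frequency`, `mean_rank`, `selected`) and `meta_hubs`
#'   (character vector, length at most `k`).
#' @export
consensus_rank <- function(table, k = 10) {
  stopifnot(inherits(table, "rank_table"))
  if (k < 1) abort("k must be >= 1")
  measures <- unique(table$measure)
  if (!length(measures)) abort("rank table covers no measures")
  top <- dplyr::filter(as_tibble(table), .data$rank <= k)
  ranking <- top |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(frequency = dplyr::n(), mean_rank = mean(.data$rank),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$mean_rank, .data$gene)
  ranking$selected <- seq_len(nrow(ranking)) <= k
  structure(list(ranking = ranking, meta_hubs = head(ranking$gene, k), k = k),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> top ", x$k, " meta hubs: ",
      paste(x$meta_hubs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname consensus_rank
#' @param x a `consensus_result`.
#' @param ... unused.
#' @export
tidy.consensus_result <- function(x, ...) x$ranking

#' @rdname consensus_rank
#' @export
glance.consensus_result <- function(x, ...) {
  tibble(k = x$k, n_candidates = nrow(x$ranking),
         top_gene = x$meta_hubs[1])
}

#' Consensus frequency plot
#'
#' @param object a `consensus_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.consensus_result <- function(object, ...) {
  df <- dplyr::filter(object$ranking, .data$selected)
  df$gene <- factor(df$gene, levels = rev(df$gene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$gene)) +
    ggplot2::geom_col(fill = "#1a9850") +
    ggplot2::labs(x = "measures placing gene in top-k", y = NULL,
                  title = "Consensus meta-hub frequency") +
    ggplot2::theme_minimal()
}

#' Merge hub and cluster top lists
#'
#' The union preserves hub-list order, then appends novel cluster genes in
#' cluster order; the inclusion-exclusion identity
#' `|union| = |A| + |B| - |overlap|` holds by construction.
#'
#' @param hub_top ordered, duplicate-free character vector (consensus hubs).
#' @param cluster_top ordered, duplicate-free character vector (top cluster
#'   genes).
#' @return an object of class `merge_result`: list with `union_list`,
#'   `overlap` (sorted character) and `counts` (named integer vector:
#'   `n_hub`, `n_cluster`, `n_overlap`, `n_union`).
#' @examples
#' merge_hub_cluster(LETTERS[1:10], c(LETTERS[8:10], letters[1:7]))$counts
#' @export
merge_hub_cluster <- function(hub_top, cluster_top) {
  hub_top <- normalize_symbols(hub_top)
  cluster_top <- normalize_symbols(cluster_top)
  if (!length(hub_top) || !length(cluster_top)) abort("both lists must be non-empty")
  if (anyDuplicated(hub_top)) abort("duplicates within the hub list")
  if (anyDuplicated(cluster_top)) abort("duplicates within the cluster list")
  overlap <- sort(intersect(hub_top, cluster_top))
  union_list <- c(hub_top, setdiff(cluster_top, hub_top))
  structure(list(
    union_list = union_list,
    overlap = overlap,
    counts = c(n_hub = length(hub_top), n_cluster = length(cluster_top),
               n_overlap = length(overlap), n_union = length(union_list))
  ), class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  cat("<merge_result> ", x$counts["n_hub"], " hub + ", x$counts["n_cluster"],
      " cluster genes -> union ", x$counts["n_union"], ", overlap ",
      x$counts["n_overlap"], "\n", sep = "")
  invisible(x)
}

#' @rdname merge_hub_cluster
#' @param x a `merge_result`.
#' @param ... unused.
#' @export
tidy.merge_result <- function(x, ...) {
  tibble(gene = x$union_list, in_overlap = x$union_list %in% x$overlap)
}
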