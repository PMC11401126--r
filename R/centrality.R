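#' Parameters for the topological hub measures
#'
#' @param dmnc_epsilon exponent of the DMNC denominator (`E'/V'^epsilon`);
#'   default 1.7, the conventional plugin value.
#' @param epc_realizations number of Monte-Carlo percolation realizations
#'   for EPC; default 100.
#' @param epc_retention per-edge retention probability in `(0, 1]`, or the
#'   string `"edge-weight"` to use each edge's confidence as its retention;
#'   default 0.5.
#' @param rng_seed integer seed making EPC (the only stochastic measure)
#'   reproducible; default 1.
#' @param bottleneck_fraction fraction of a shortest-path tree that must
#'   route through a node for that root to count towards its BottleNeck
#'   score; default 1/4.
#' @return a list of class `centrality_params`.
#' @export
centrality_params <- function(dmnc_epsilon = 1.7, epc_realizations = 100,
                              epc_retention = 0.5, rng_seed = 1L,
                              bottleneck_fraction = 1 / 4) {
  if (dmnc_epsilon <= 0) abort("dmnc_epsilon must be > 0")
  if (epc_realizations < 1) abort("epc_realizations must be >= 1")
  if (!identical(epc_retention, "edge-weight")) {
    if (!is.numeric(epc_retention) || epc_retention <= 0 || epc_retention > 1) {
      abort("epc_retention must be in (0, 1] or \"edge-weight\"")
    }
  }
  structure(list(dmnc_epsilon = dmnc_epsilon,
                 epc_realizations = as.integer(epc_realizations),
                 epc_retention = epc_retention,
                 rng_seed = as.integer(rng_seed),
                 bottleneck_fraction = bottleneck_fraction),
            class = "centrality_params")
}

#' The eleven hub measures
#' @return character vector of measure names.
#' @export
hub_measures <- function() {
  c("degree", "mnc", "dmnc", "mcc", "closeness", "betweenness",
    "stress", "eccentricity", "radiality", "bottleneck", "epc")
}

#' Compute one topological hub measure
#'
#' All measures treat the network as simple and unweighted (EPC's
#' `"edge-weight"` retention mode is the single exception) and follow the
#' CytoHubba-style conventions:
#' \describe{
#'   \item{degree}{neighbour count.}
#'   \item{mnc}{size of the largest connected component of the subgraph
#'     induced on the open neighbourhood `N(v)`.}
#'   \item{dmnc}{`E'/V'^epsilon` over that largest component (0 when it has
#'     fewer than 2 vertices).}
#'   \item{mcc}{sum of `(|C|-1)!` over maximal cliques `C` containing `v`;
#'     equals the degree when no two neighbours of `v` are adjacent.}
#'   \item{closeness}{harmonic closeness `sum(1/d(v,u))`; unreachable
#'     vertices contribute 0, so disconnected graphs are handled.}
#'   \item{betweenness}{shortest-path betweenness over unordered pairs.}
#'   \item{stress}{number of shortest `s`-`t` paths passing through `v`
#'     (unordered pairs, endpoints excluded).}
#'   \item{eccentricity}{`1/max(d(v, u))` over `v`'s component (0 for an
#'     isolated vertex) — inverted so that, like every other measure,
#'     larger is better.}
#'   \item{radiality}{`sum(diam + 1 - d(v,u))/(|V|-1)` over vertices
#'     reachable from `v`, with `diam` the diameter of `v`'s component.}
#'   \item{bottleneck}{number of roots `s != v` whose BFS shortest-path
#'     tree routes strictly more than `bottleneck_fraction` of its nodes
#'     through `v` (parent ties broken by smallest symbol).}
#'   \item{epc}{mean, over seeded percolation realizations, of the size of
#'     `v`'s connected component after each edge is kept independently with
#'     the retention probability.}
#' }
#'
#' @param net a [ppi_network].
#' @param measure one of [hub_measures()].
#' @param params a [centrality_params()] list.
#' @return named numeric vector of scores over all nodes.
#' @examples
#' net <- ppi_network(data.frame(node1 = c("A", "B"), node2 = c("B", "C"), score = 1))
#' compute_measure(net, "betweenness")["B"]
#' @export
compute_measure <- function(net, measure, params = centrality_params()) {
  stopifnot(inherits(net, "ppi_network"))
  if (!length(net$nodes)) abort("network has no nodes")
  measure <- match.arg(measure, hub_measures())
  g <- as_igraph(net)
  nodes <- net$nodes
  sc <- switch(measure,
    degree       = igraph::degree(g),
    mnc          = mnc_scores(g)$mnc,
    dmnc         = mnc_scores(g, epsilon = params$dmnc_epsilon)$dmnc,
    mcc          = mcc_scores(g),
    closeness    = igraph::harmonic_centrality(g, normalized = FALSE),
    betweenness  = igraph::betweenness(g, directed = FALSE, weights = NA),
    stress       = stress_scores(g),
    eccentricity = ecc_scores(g),
    radiality    = radiality_scores(g),
    bottleneck   = bottleneck_scores(g, fraction = params$bottleneck_fraction),
    epc          = epc_scores(g, realizations = params$epc_realizations,
                              retention = params$epc_retention,
                              seed = params$rng_seed)
  )
  out <- as.numeric(sc)[match(nodes, igraph::V(g)$name)]
  names(out) <- nodes
  out
}

# MNC and DMNC share the largest-component-of-neighbourhood computation.
# When components tie on size the one with most edges is taken (then the
# one containing the smallest symbol), keeping DMNC deterministic.
mnc_scores <- function(g, epsilon = 1.7) {
  nms <- igraph::V(g)$name
  mnc <- dmnc <- numeric(length(nms))
  for (i in seq_along(nms)) {
    nb <- igraph::neighbors(g, i)
    if (!length(nb)) next
    sub <- igraph::induced_subgraph(g, nb)
    comp <- igraph::components(sub)
    sizes <- comp$csize
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      info <- lapply(best, function(ci) {
        vs <- which(comp$membership == ci)
        cg <- igraph::induced_subgraph(sub, vs)
        list(ne = igraph::ecount(cg), minsym = min(igraph::V(sub)$name[vs]))
      })
      ord <- order(-vapply(info, `[[`, numeric(1), "ne"),
                   vapply(info, `[[`, character(1), "minsym"))
      best <- best[ord[1]]
    }
    vs <- which(comp$membership == best)
    cg <- igraph::induced_subgraph(sub, vs)
    vprime <- length(vs)
    eprime <- igraph::ecount(cg)
    mnc[i] <- vprime
    dmnc[i] <- if (vprime < 2) 0 else eprime / vprime^epsilon
  }
  list(mnc = setNames(mnc, nms), dmnc = setNames(dmnc, nms))
}

mcc_scores <- function(g) {
  nms <- igraph::V(g)$name
  sc <- numeric(length(nms))
  cliques <- igraph::max_cliques(g)
  for (cl in cliques) {
    w <- factorial(length(cl) - 1L)
    sc[as.integer(cl)] <- sc[as.integer(cl)] + w
  }
  # edgeless-neighbourhood convention: MCC falls back to the degree
  deg <- igraph::degree(g)
  for (i in seq_along(nms)) {
    nb <- igraph::neighbors(g, i)
    if (length(nb) < 2 || igraph::ecount(igraph::induced_subgraph(g, nb)) == 0) {
      sc[i] <- deg[i]
    }
  }
  setNames(sc, nms)
}

# Per-source BFS over the unweighted simple graph: distances and geodesic
# counts, used by stress and bottleneck.
bfs_sigma <- function(adj, s) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  sigma <- numeric(n)
  dist[s] <- 0L
  sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
        if (!is.na(dist[w]) && dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

adj_list <- function(g) {
  n <- igraph::vcount(g)
  lapply(seq_len(n), function(i) as.integer(igraph::neighbors(g, i)))
}

stress_scores <- function(g) {
  nms <- igraph::V(g)$name
  n <- length(nms)
  adj <- adj_list(g)
  bfs <- lapply(seq_len(n), function(s) bfs_sigma(adj, s))
  D <- vapply(bfs, `[[`, integer(n), "dist")     # D[u, s] = d(s, u)
  S <- vapply(bfs, `[[`, numeric(n), "sigma")    # S[u, s] = sigma_s(u)
  sc <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in seq.int(s + 1L, n)) {
    dst <- D[t, s]
    if (is.na(dst)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      dsv <- D[v, s]; dvt <- D[t, v]
      if (!is.na(dsv) && !is.na(dvt) && dsv + dvt == dst) {
        sc[v] <- sc[v] + S[v, s] * S[t, v]
      }
    }
  }
  setNames(sc, nms)
}

ecc_scores <- function(g) {
  nms <- igraph::V(g)$name
  ecc <- igraph::eccentricity(g, mode = "all")  # over reachable vertices
  deg <- igraph::degree(g)
  out <- ifelse(deg == 0 | ecc == 0, 0, 1 / ecc)
  setNames(as.numeric(out), nms)
}

radiality_scores <- function(g) {
  nms <- igraph::V(g)$name
  n <- length(nms)
  if (n < 2) return(setNames(numeric(n), nms))
  D <- igraph::distances(g, weights = NA)
  comp <- igraph::components(g)$membership
  out <- numeric(n)
  for (ci in unique(comp)) {
    vs <- which(comp == ci)
    if (length(vs) < 2) next
    Dc <- D[vs, vs, drop = FALSE]
    diam <- max(Dc[is.finite(Dc)])
    for (ii in seq_along(vs)) {
      d <- Dc[ii, -ii]
      out[vs[ii]] <- sum(diam + 1 - d) / (n - 1)
    }
  }
  setNames(out, nms)
}

# BFS shortest-path tree from s with parent ties broken by the
# lexicographically smallest parent symbol; returns parent vector.
bfs_tree_lex <- function(adj, s, nms) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  parent <- rep(NA_integer_, n)
  dist[s] <- 0L
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier[order(nms[frontier])]) {
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          parent[w] <- v
          nxt <- c(nxt, w)
        } else if (dist[w] == dist[v] + 1L && nms[v] < nms[parent[w]]) {
          parent[w] <- v
        }
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, parent = parent)
}

bottleneck_scores <- function(g, fraction = 1 / 4) {
  nms <- igraph::V(g)$name
  n <- length(nms)
  adj <- adj_list(g)
  sc <- numeric(n)
  for (s in seq_len(n)) {
    tr <- bfs_tree_lex(adj, s, nms)
    in_tree <- which(!is.na(tr$dist))
    tree_size <- length(in_tree)
    if (tree_size < 2) next
    # subtree sizes by accumulating counts up the parent chain
    sub <- rep(1L, n)
    ord <- in_tree[order(tr$dist[in_tree], decreasing = TRUE)]
    for (v in ord) {
      p <- tr$parent[v]
      if (!is.na(p)) sub[p] <- sub[p] + sub[v]
    }
    thr <- fraction * tree_size
    hits <- in_tree[in_tree != s & sub[in_tree] > thr]
    sc[hits] <- sc[hits] + 1
  }
  setNames(sc, nms)
}

epc_scores <- function(g, realizations = 100, retention = 0.5, seed = 1L) {
  nms <- igraph::V(g)$name
  n <- length(nms)
  m <- igraph::ecount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  keep_p <- if (identical(retention, "edge-weight")) {
    w <- igraph::E(g)$weight
    if (is.null(w)) abort("edge-weight retention requires edge weights")
    w
  } else rep(retention, m)
  acc <- numeric(n)
  with_seed(seed, {
    for (r in seq_len(realizations)) {
      keep <- if (m > 0) runif(m) < keep_p else logical(0)
      sub <- igraph::subgraph_from_edges(g, which(keep), delete.vertices = FALSE)
      comp <- igraph::components(sub)
      acc <- acc + comp$csize[comp$membership]
    }
  })
  setNames(acc / realizations, nms)
}

#' Compute all eleven measures and rank the nodes
#'
#' Ranks are assigned per measure by score descending with ties broken by
#' symbol ascending, so within each measure the ranks are a permutation of
#' `1..|V|` and the whole table is deterministic given `params$rng_seed`.
#'
#' @inheritParams compute_measure
#' @return a tibble of class `rank_table` with columns `measure`, `gene`,
#'   `score`, `rank`.
#' @export
compute_all <- function(net, params = centrality_params()) {
  stopifnot(inherits(net, "ppi_network"))
  if (!length(net$nodes)) abort("network has no nodes")
  rows <- purrr::map(hub_measures(), function(m) {
    sc <- compute_measure(net, m, params)
    ord <- order_score_symbol(sc, names(sc))
    tibble(measure = m, gene = names(sc)[ord], score = as.numeric(sc)[ord],
           rank = seq_along(sc))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rank_table", class(out))
  attr(out, "params") <- params
  out
}

#' Top-k genes for a measure
#'
#' @param table a `rank_table` from [compute_all()].
#' @param measure one of [hub_measures()].
#' @param k number of genes (all returned when the network is smaller).
#' @return character vector of genes ordered by rank.
#' @export
top_k <- function(table, measure, k = 10) {
  stopifnot(inherits(table, "rank_table"))
  if (k < 1) abort("k must be >= 1")
  measure <- match.arg(measure, hub_measures())
  m <- measure
  sub <- dplyr::filter(table, .data$measure == m)
  sub <- dplyr::arrange(sub, .data$rank)
  head(sub$gene, k)
}

#' @rdname compute_all
#' @param x a `rank_table`.
#' @param ... unused.
#' @export
tidy.rank_table <- function(x, ...) {
  as_tibble(unclass_keep_tbl(x))
}

#' @rdname compute_all
#' @export
glance.rank_table <- function(x, ...) {
  tibble(n_genes = dplyr::n_distinct(x$gene),
         n_measures = dplyr::n_distinct(x$measure))
}

unclass_keep_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("rank_table"))
  x
}

#' Rank-table heatmap
#'
#' Tile plot of per-measure ranks for the genes appearing in any measure's
#' top `k`, the usual way consensus across hub measures is displayed.
#'
#' @param object a `rank_table`.
#' @param k show genes in the top `k` of at least one measure; default 10.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rank_table <- function(object, k = 10, ...) {
  shown <- unique(dplyr::filter(object, .data$rank <= k)$gene)
  df <- dplyr::filter(tidy.rank_table(object), .data$gene %in% shown)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measure, y = .data$gene,
                                   fill = .data$rank)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$rank), size = 3) +
    ggplot2::scale_fill_gradient(low = "#d73027", high = "#fee8c8") +
    ggplot2::labs(x = NULL, y = NULL, fill = "rank",
                  title = "Per-measure hub ranks") +
    ggplot2::theme_minimal()
}
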