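#' MCODE-style parameters
#'
#' Defaults are the documented plugin defaults: degree cutoff 2, node score
#' cutoff (vertex weight percentage) 0.2, haircut on, fluff off, k-core
#' filter 2, max growth depth 100.
#'
#' @param degree_cutoff minimum degree for a vertex to receive a non-zero
#'   weight.
#' @param node_score_cutoff growth tolerance (VWP) in `[0, 1)`: a neighbour
#'   joins a complex when its weight is at least `(1 - VWP)` times the seed
#'   weight.
#' @param haircut remove members with within-cluster degree 1?
#' @param fluff add boundary neighbours whose closed-neighbourhood density
#'   exceeds `fluff_density`? (May place a vertex in several clusters;
#'   flagged in the result.)
#' @param fluff_density density threshold for fluff; default 0.1.
#' @param k_core_filter discard clusters whose subgraph has no k-core at
#'   this k; default 2.
#' @param max_depth maximum BFS growth depth from the seed; default 100.
#' @return a list of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         haircut = TRUE, fluff = FALSE, fluff_density = 0.1,
                         k_core_filter = 2L, max_depth = 100L) {
  if (node_score_cutoff < 0 || node_score_cutoff >= 1) {
    abort("node_score_cutoff must be in [0, 1)")
  }
  if (degree_cutoff < 0 || k_core_filter < 0) abort("cutoffs must be >= 0")
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_density = fluff_density,
                 k_core_filter = as.integer(k_core_filter),
                 max_depth = as.integer(max_depth)),
            class = "mcode_params")
}

graph_density <- function(nv, ne) if (nv >= 2) 2 * ne / (nv * (nv - 1)) else 0

#' MCODE vertex weights
#'
#' For each vertex `v` of degree at least `degree_cutoff`, the subgraph
#' induced on the open neighbourhood `N(v)` is reduced to its highest
#' k-core; the weight is that `k` times the core's density. Vertices below
#' the degree cutoff weigh 0.
#'
#' @param net a [ppi_network].
#' @param params an [mcode_params()] list.
#' @return a tibble with columns `gene`, `weight`.
#' @examples
#' k5 <- ppi_network(do.call(rbind, lapply(combn(LETTERS[1:5], 2, simplify = FALSE),
#'   function(p) data.frame(node1 = p[1], node2 = p[2], score = 1))))
#' vertex_weights(k5) # every weight 3 = core k of K4 neighbourhood x density 1
#' @export
vertex_weights <- function(net, params = mcode_params()) {
  stopifnot(inherits(net, "ppi_network"))
  if (!length(net$nodes)) abort("network has no nodes")
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  w <- numeric(length(deg))
  for (i in seq_along(deg)) {
    if (deg[i] < params$degree_cutoff) next
    nb <- igraph::neighbors(g, i)
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    if (k == 0) next
    vs <- which(core >= k)
    cg <- igraph::induced_subgraph(sub, vs)
    w[i] <- k * graph_density(length(vs), igraph::ecount(cg))
  }
  tibble(gene = igraph::V(g)$name, weight = w)
}

#' Detect dense molecular complexes
#'
#' Seeded, density-based complex growth: vertices are weighted by
#' [vertex_weights()]; complexes grow outward (BFS, to `max_depth`) from
#' the highest-weight unassigned seed, admitting neighbours whose weight is
#' at least `(1 - VWP)` times the seed weight. Haircut then trims to the
#' 2-core of the complex (so no member has within-cluster degree 1); fluff,
#' when on, adds boundary neighbours whose closed-neighbourhood density
#' exceeds `fluff_density` (such vertices may appear in several clusters
#' and are flagged). Clusters whose subgraph has no `k_core_filter`-core
#' are discarded. All ties break by symbol, so the result is deterministic.
#'
#' @inheritParams vertex_weights
#' @return a list of class `mcode_result` with elements `clusters` (list of
#'   per-cluster lists: `seed`, `members`, `fluffed`, `density`, `score`,
#'   `member_weights`) and `weights` (the vertex-weight tibble). Clusters
#'   are sorted by score descending, seed symbol ascending.
#' @export
find_clusters <- function(net, params = mcode_params()) {
  stopifnot(inherits(net, "ppi_network"))
  if (!length(net$nodes)) abort("network has no nodes")
  g <- as_igraph(net)
  nms <- igraph::V(g)$name
  wt <- vertex_weights(net, params)
  w <- setNames(wt$weight, wt$gene)[nms]
  adj <- adj_list(g)
  assigned <- rep(FALSE, length(nms))
  clusters <- list()
  seed_order <- order(-w, nms, method = "radix")
  for (s in seed_order) {
    if (assigned[s] || w[s] <= 0) next
    thr <- (1 - params$node_score_cutoff) * w[s]
    members <- s
    assigned[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (!assigned[u] && w[u] >= thr) {
            assigned[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    if (params$haircut && length(members) > 1) {
      sub <- igraph::induced_subgraph(g, members)
      core <- igraph::coreness(sub)
      keep_names <- igraph::V(sub)$name[core >= 2]  # sub may reorder vertices
      kept <- members[nms[members] %in% keep_names]
      assigned[setdiff(members, kept)] <- FALSE  # trimmed vertices may seed later
      members <- kept
    }
    if (!length(members)) next
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < params$k_core_filter) {
      assigned[members] <- FALSE
      # a discarded complex never re-seeds from the same vertex
      w[s] <- -Inf
      next
    }
    # the haircut may trim the originating vertex; report the heaviest
    # remaining member as seed so the seed always belongs to the cluster
    seed_idx <- if (s %in% members) s else members[order(-w[members], nms[members])][1]
    fluffed <- integer(0)
    if (params$fluff) {
      boundary <- setdiff(unique(unlist(adj[members])), members)
      for (u in boundary) {
        closed <- c(u, adj[[u]])
        cg <- igraph::induced_subgraph(g, closed)
        if (graph_density(length(closed), igraph::ecount(cg)) > params$fluff_density) {
          fluffed <- c(fluffed, u)
        }
      }
    }
    final <- sort(unique(c(members, fluffed)))
    cg <- igraph::induced_subgraph(g, final)
    dens <- graph_density(length(final), igraph::ecount(cg))
    clusters[[length(clusters) + 1L]] <- list(
      seed = nms[seed_idx],
      members = nms[final],
      fluffed = nms[fluffed],
      density = dens,
      score = dens * length(final),
      member_weights = setNames(pmax(w[final], 0), nms[final])
    )
  }
  ord <- order(-vapply(clusters, `[[`, numeric(1), "score"),
               vapply(clusters, `[[`, character(1), "seed"))
  structure(list(clusters = clusters[ord], weights = wt),
            class = "mcode_result")
}

#' @export
print.mcode_result <- function(x, ...) {
  cat("<mcode_result> ", length(x$clusters), " cluster(s)\n", sep = "")
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  #%d seed %s: %d nodes, density %.3f, score %.3f\n",
                i, cl$seed, length(cl$members), cl$density, cl$score))
  }
  invisible(x)
}

#' @rdname find_clusters
#' @param x an `mcode_result`.
#' @param ... unused.
#' @export
tidy.mcode_result <- function(x, ...) {
  if (!length(x$clusters)) {
    return(tibble(cluster = integer(0), seed = character(0), gene = character(0),
                  weight = numeric(0), fluffed = logical(0)))
  }
  dplyr::bind_rows(lapply(seq_along(x$clusters), function(i) {
    cl <- x$clusters[[i]]
    tibble(cluster = i, seed = cl$seed, gene = cl$members,
           weight = as.numeric(cl$member_weights[cl$members]),
           fluffed = cl$members %in% cl$fluffed)
  }))
}

#' @rdname find_clusters
#' @export
glance.mcode_result <- function(x, ...) {
  tibble(n_clusters = length(x$clusters),
         top_score = if (length(x$clusters)) x$clusters[[1]]$score else NA_real_,
         top_size = if (length(x$clusters)) length(x$clusters[[1]]$members) else NA_integer_,
         top_seed = if (length(x$clusters)) x$clusters[[1]]$seed else NA_character_)
}

#' Highest-weight genes of a cluster
#'
#' @param cluster one element of `mcode_result$clusters`.
#' @param k number of genes to return.
#' @return character vector ordered by vertex weight descending, symbol
#'   ascending.
#' @export
top_cluster_genes <- function(cluster, k = 10) {
  if (k < 1) abort("k must be >= 1")
  wts <- cluster$member_weights
  ord <- order_score_symbol(as.numeric(wts), names(wts))
  head(names(wts)[ord], k)
}

#' Write MCODE clusters to JSON
#'
#' @param result an `mcode_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(result, path) {
  stopifnot(inherits(result, "mcode_result"))
  out <- lapply(result$clusters, function(cl) {
    list(seed = cl$seed, score = cl$score, density = cl$density,
         members = cl$members, weights = as.list(cl$member_weights))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
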