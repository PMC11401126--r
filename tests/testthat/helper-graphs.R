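# Graph construction helpers used across test files.

# ppi_network from a two-column matrix/list of symbol pairs, unit scores
make_net <- function(pairs, nodes = NULL, score = 1) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  edges <- data.frame(node1 = pairs[, 1], node2 = pairs[, 2], score = score)
  ppi_network(edges, min_score = 0, keep_isolated = !is.null(nodes),
              query_nodes = nodes)
}

complete_net <- function(syms) {
  make_net(t(combn(syms, 2)))
}

path_net <- function(syms) {
  make_net(cbind(syms[-length(syms)], syms[-1]))
}

star_net <- function(center, leaves) {
  make_net(cbind(center, leaves))
}

# all labeled connected graphs on the symbols `syms` (n <= 5 in practice)
all_connected_graphs <- function(syms) {
  n <- length(syms)
  pairs <- t(combn(seq_len(n), 2))
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)
    if (length(sel) < n - 1) next
    A <- matrix(FALSE, n, n)
    for (e in sel) {
      A[pairs[e, 1], pairs[e, 2]] <- TRUE
      A[pairs[e, 2], pairs[e, 1]] <- TRUE
    }
    # connectivity by label propagation
    seen <- c(1L, integer(0))
    frontier <- 1L
    while (length(frontier)) {
      nb <- which(apply(A[, frontier, drop = FALSE], 1, any))
      frontier <- setdiff(nb, seen)
      seen <- union(seen, frontier)
    }
    if (length(seen) < n) next
    out[[length(out) + 1L]] <- make_net(cbind(syms[pairs[sel, 1]], syms[pairs[sel, 2]]))
  }
  out
}

# seeded random connected graph on n nodes (rejection sampling)
random_connected_net <- function(n, p = 0.4, seed = 1) {
  syms <- sprintf("V%02d", seq_len(n))
  set.seed(seed)
  repeat {
    pairs <- t(combn(syms, 2))
    keep <- runif(nrow(pairs)) < p
    if (!any(keep)) next
    net <- make_net(pairs[keep, , drop = FALSE], nodes = syms)
    A <- oracle_adj(net)
    if (all(is.finite(oracle_dist(A)[1, ]))) return(net)
  }
}
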