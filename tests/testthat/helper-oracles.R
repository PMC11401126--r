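# Brute-force reference implementations of every topological measure and
# the MCODE vertex weight, written without igraph (adjacency matrices,
# Floyd-Warshall, explicit path enumeration, subset clique enumeration)
# so they are independent of the package's code paths. Intended for
# graphs of at most ~8 nodes.

oracle_adj <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    A[cbind(net$edges$node1, net$edges$node2)] <- 1L
    A[cbind(net$edges$node2, net$edges$node1)] <- 1L
  }
  A
}

oracle_dist <- function(A) {
  n <- nrow(A)
  D <- ifelse(A == 1L, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# all shortest paths s -> t as integer vectors (recursive backtracking)
oracle_paths <- function(A, D, s, t) {
  if (s == t) return(list(s))
  preds <- which(A[, t] == 1L & D[s, ] == D[s, t] - 1)
  out <- list()
  for (u in preds) {
    for (p in oracle_paths(A, D, s, u)) out <- c(out, list(c(p, t)))
  }
  out
}

oracle_degree <- function(net) rowSums(oracle_adj(net))

oracle_betweenness <- function(net) {
  A <- oracle_adj(net); D <- oracle_dist(A); n <- nrow(A)
  sc <- numeric(n)
  if (n >= 3) for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    paths <- oracle_paths(A, D, s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      sc[v] <- sc[v] + through / length(paths)
    }
  }
  setNames(sc, net$nodes)
}

oracle_stress <- function(net) {
  A <- oracle_adj(net); D <- oracle_dist(A); n <- nrow(A)
  sc <- numeric(n)
  if (n >= 3) for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    paths <- oracle_paths(A, D, s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      sc[v] <- sc[v] + sum(vapply(paths, function(p) v %in% p, logical(1)))
    }
  }
  setNames(sc, net$nodes)
}

oracle_closeness <- function(net) {
  D <- oracle_dist(oracle_adj(net))
  sc <- vapply(seq_len(nrow(D)), function(v) {
    d <- D[v, -v]
    sum(1 / d[is.finite(d) & d > 0])
  }, numeric(1))
  setNames(sc, net$nodes)
}

oracle_eccentricity <- function(net) {
  D <- oracle_dist(oracle_adj(net))
  sc <- vapply(seq_len(nrow(D)), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else 1 / max(d)
  }, numeric(1))
  setNames(sc, net$nodes)
}

oracle_radiality <- function(net) {
  A <- oracle_adj(net); D <- oracle_dist(A); n <- nrow(A)
  sc <- numeric(n)
  if (n >= 2) for (v in seq_len(n)) {
    reach <- setdiff(which(is.finite(D[v, ])), v)
    if (!length(reach)) next
    comp <- c(v, reach)
    diam <- max(D[comp, comp][is.finite(D[comp, comp])])
    sc[v] <- sum(diam + 1 - D[v, reach]) / (n - 1)
  }
  setNames(sc, net$nodes)
}

# maximal cliques by subset enumeration
oracle_max_cliques <- function(A) {
  n <- nrow(A)
  out <- list()
  for (mask in seq_len(2^n) - 1L) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
    if (!length(S)) next
    ok <- TRUE
    if (length(S) > 1) {
      prs <- combn(S, 2)
      ok <- all(A[t(prs)] == 1L)
    }
    if (!ok) next
    ext <- setdiff(seq_len(n), S)
    maximal <- !any(vapply(ext, function(u) all(A[u, S] == 1L), logical(1)))
    if (maximal) out[[length(out) + 1L]] <- S
  }
  out
}

oracle_mcc <- function(net) {
  A <- oracle_adj(net)
  n <- nrow(A)
  cl <- oracle_max_cliques(A)
  sc <- numeric(n)
  for (C in cl) sc[C] <- sc[C] + factorial(length(C) - 1L)
  deg <- rowSums(A)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1L)
    if (length(nb) < 2 || sum(A[nb, nb]) == 0) sc[v] <- deg[v]
  }
  setNames(sc, net$nodes)
}

# largest connected component of the neighbourhood subgraph; ties on size
# resolved by edge count then smallest symbol (the package's stated rule)
oracle_neighbourhood_comp <- function(A, v, nms) {
  nb <- which(A[v, ] == 1L)
  if (!length(nb)) return(list(vs = integer(0), ne = 0L))
  sub <- A[nb, nb, drop = FALSE]
  seen <- rep(FALSE, length(nb))
  comps <- list()
  for (i in seq_along(nb)) {
    if (seen[i]) next
    comp <- i
    frontier <- i
    seen[i] <- TRUE
    while (length(frontier)) {
      nxt <- which(apply(sub[, frontier, drop = FALSE] == 1L, 1, any) & !seen)
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    comps[[length(comps) + 1L]] <- comp
  }
  info <- lapply(comps, function(cc) {
    list(vs = nb[cc], ne = sum(sub[cc, cc]) / 2, minsym = min(nms[nb[cc]]))
  })
  ord <- order(-vapply(info, function(x) length(x$vs), numeric(1)),
               -vapply(info, function(x) x$ne, numeric(1)),
               vapply(info, function(x) x$minsym, character(1)))
  info[[ord[1]]]
}

oracle_mnc <- function(net) {
  A <- oracle_adj(net)
  sc <- vapply(seq_len(nrow(A)), function(v) {
    length(oracle_neighbourhood_comp(A, v, net$nodes)$vs)
  }, numeric(1))
  setNames(sc, net$nodes)
}

oracle_dmnc <- function(net, epsilon = 1.7) {
  A <- oracle_adj(net)
  sc <- vapply(seq_len(nrow(A)), function(v) {
    cc <- oracle_neighbourhood_comp(A, v, net$nodes)
    if (length(cc$vs) < 2) 0 else cc$ne / length(cc$vs)^epsilon
  }, numeric(1))
  setNames(sc, net$nodes)
}

oracle_bottleneck <- function(net, fraction = 1 / 4) {
  A <- oracle_adj(net); D <- oracle_dist(A); n <- nrow(A)
  nms <- net$nodes
  sc <- numeric(n)
  for (s in seq_len(n)) {
    reach <- which(is.finite(D[s, ]))
    if (length(reach) < 2) next
    parent <- rep(NA_integer_, n)
    for (w in reach) {
      if (w == s) next
      cand <- which(A[, w] == 1L & D[s, ] == D[s, w] - 1)
      parent[w] <- cand[order(nms[cand])][1]
    }
    size <- numeric(n)
    for (u in reach) {
      x <- u
      repeat {
        size[x] <- size[x] + 1
        if (x == s) break
        x <- parent[x]
      }
    }
    thr <- fraction * length(reach)
    for (v in reach) if (v != s && size[v] > thr) sc[v] <- sc[v] + 1
  }
  setNames(sc, nms)
}

# component size of every vertex = EPC at retention 1
oracle_component_size <- function(net) {
  D <- oracle_dist(oracle_adj(net))
  setNames(rowSums(is.finite(D)), net$nodes)
}

# k-core by iterative deletion
oracle_kcore_weight <- function(net, degree_cutoff = 2) {
  A <- oracle_adj(net)
  n <- nrow(A)
  sc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1L)
    if (length(nb) < degree_cutoff) next
    sub <- A[nb, nb, drop = FALSE]
    best_k <- 0L
    best <- NULL
    k <- 1L
    repeat {
      S <- seq_len(nrow(sub))
      repeat {
        deg <- rowSums(sub[S, S, drop = FALSE])
        drop_v <- S[deg < k]
        if (!length(drop_v)) break
        S <- setdiff(S, drop_v)
        if (!length(S)) break
      }
      if (!length(S)) break
      best_k <- k
      best <- S
      k <- k + 1L
    }
    if (best_k > 0) {
      ne <- sum(sub[best, best]) / 2
      nv <- length(best)
      dens <- if (nv >= 2) 2 * ne / (nv * (nv - 1)) else 0
      sc[v] <- best_k * dens
    }
  }
  setNames(sc, net$nodes)
}

# measure dispatch for the equivalence suites (epc handled separately)
oracle_measure <- function(net, measure) {
  switch(measure,
    degree       = setNames(oracle_degree(net), net$nodes),
    mnc          = oracle_mnc(net),
    dmnc         = oracle_dmnc(net),
    mcc          = oracle_mcc(net),
    closeness    = oracle_closeness(net),
    betweenness  = oracle_betweenness(net),
    stress       = oracle_stress(net),
    eccentricity = oracle_eccentricity(net),
    radiality    = oracle_radiality(net),
    bottleneck   = oracle_bottleneck(net),
    epc          = oracle_component_size(net)
  )
}

expect_measures_match_oracle <- function(net, tol = 1e-10) {
  params <- centrality_params(epc_retention = 1, epc_realizations = 2)
  for (m in hub_measures()) {
    got <- compute_measure(net, m, params)
    want <- oracle_measure(net, m)
    expect_equal(got, want[names(got)], tolerance = tol,
                 info = paste0("measure ", m))
  }
}
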