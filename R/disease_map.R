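#' Read a directed disease signalling map
#'
#' TSV with columns `source`, `target`, `effect` (`activate`, `inhibit` or
#' `regulate`) and `disease`. Symbols are normalized; duplicate
#' `(source, target, disease)` rows collapse to one (first effect kept);
#' self-edges are an error.
#'
#' @param path TSV path.
#' @param isolated optional character vector of nodes declared present in
#'   the maps despite having no interaction (e.g. a candidate shown on a
#'   map without edges).
#' @return an object of class `disease_maps`: list with `edges` (tibble
#'   `source`, `target`, `effect`, `disease`) and `isolated` (character).
#' @export
read_disease_map <- function(path, isolated = character(0)) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!nrow(df)) {
    warn("empty disease map")
    return(disease_maps(tibble(source = character(0), target = character(0),
                               effect = character(0), disease = character(0)),
                        isolated = isolated))
  }
  if (!all(c("source", "target", "effect", "disease") %in% names(df))) {
    abort("disease map needs columns source, target, effect, disease")
  }
  disease_maps(df, isolated = isolated)
}

#' Construct disease maps from an edge table
#'
#' @param edges data frame with columns `source`, `target`, `effect`,
#'   `disease`.
#' @param isolated optional declared isolated nodes.
#' @return a `disease_maps` object.
#' @export
disease_maps <- function(edges, isolated = character(0)) {
  edges <- as_tibble(edges)
  if (nrow(edges)) {
    edges$source <- normalize_symbols_keep(edges$source)
    edges$target <- normalize_symbols_keep(edges$target)
    bad <- setdiff(unique(edges$effect), c("activate", "inhibit", "regulate"))
    if (length(bad)) abort(paste0("unknown effect token: ", bad[1]))
    selfs <- which(edges$source == edges$target)
    if (length(selfs)) abort(paste0("self-edge at row ", selfs[1], ": ", edges$source[selfs[1]]))
    edges <- dplyr::distinct(edges, .data$source, .data$target, .data$disease,
                             .keep_all = TRUE)
    edges <- dplyr::arrange(edges, .data$disease, .data$source, .data$target)
  }
  structure(list(edges = edges, isolated = unique(normalize_symbols(isolated))),
            class = "disease_maps")
}

#' @export
print.disease_maps <- function(x, ...) {
  cat("<disease_maps> ", nrow(x$edges), " edge(s) across ",
      dplyr::n_distinct(x$edges$disease), " disease(s); ",
      length(map_nodes(x)), " node(s)\n", sep = "")
  invisible(x)
}

#' Nodes of a disease map (edge endpoints plus declared isolates)
#' @param maps a `disease_maps` or `superimposed_map`.
#' @return sorted character vector.
#' @export
map_nodes <- function(maps) {
  sort(unique(c(maps$edges$source, maps$edges$target, maps$isolated)))
}

#' Superimpose disease maps
#'
#' A directed `(source, target)` pair is retained when it occurs in at
#' least `min_support` diseases. Pairs whose effect labels disagree across
#' the contributing diseases collapse to `"regulate"` with a warning.
#'
#' @param maps a `disease_maps` object covering at least two diseases.
#' @param min_support minimum number of diseases a pair must appear in;
#'   default all diseases present (edge-wise intersection).
#' @return an object of class `superimposed_map`: list with `edges`
#'   (tibble `source`, `target`, `effect`, `support`), `isolated`,
#'   `n_diseases`, `min_support`.
#' @export
superimpose <- function(maps, min_support = NULL) {
  stopifnot(inherits(maps, "disease_maps"))
  diseases <- unique(maps$edges$disease)
  if (length(diseases) < 2) abort("need maps from at least 2 diseases")
  min_support <- min_support %||% length(diseases)
  if (min_support > length(diseases)) {
    abort("min_support exceeds the number of disease maps")
  }
  agg <- maps$edges |>
    dplyr::group_by(.data$source, .data$target) |>
    dplyr::summarise(support = dplyr::n_distinct(.data$disease),
                     n_effects = dplyr::n_distinct(.data$effect),
                     effect = dplyr::first(.data$effect), .groups = "drop") |>
    dplyr::filter(.data$support >= min_support)
  conflicted <- agg$n_effects > 1
  if (any(conflicted)) {
    warn(paste0(sum(conflicted), " edge(s) with conflicting effects collapsed to \"regulate\""))
    agg$effect[conflicted] <- "regulate"
  }
  edges <- dplyr::arrange(dplyr::select(agg, -"n_effects"),
                          .data$source, .data$target)
  structure(list(edges = edges, isolated = maps$isolated,
                 n_diseases = length(diseases), min_support = min_support),
            class = "superimposed_map")
}

#' @export
print.superimposed_map <- function(x, ...) {
  cat("<superimposed_map> ", nrow(x$edges), " edge(s) supported by >= ",
      x$min_support, " of ", x$n_diseases, " diseases\n", sep = "")
  invisible(x)
}

#' @rdname superimpose
#' @param x a `superimposed_map`.
#' @param ... unused.
#' @export
tidy.superimposed_map <- function(x, ...) x$edges

directed_igraph <- function(map) {
  igraph::graph_from_data_frame(
    d = data.frame(from = map$edges$source, to = map$edges$target),
    directed = TRUE,
    vertices = data.frame(name = map_nodes(map))
  )
}

#' Most interconnected node of a superimposed map
#'
#' The hub of hubs maximizes the number of nodes in its signalling stream:
#' the union of its directed ancestors and descendants. Ties break by
#' symbol.
#'
#' @param map a `superimposed_map` with at least one edge.
#' @return a one-row tibble `gene`, `connectivity`.
#' @export
hub_of_hubs <- function(map) {
  stopifnot(inherits(map, "superimposed_map"))
  if (!nrow(map$edges)) abort("superimposed map has no edges")
  g <- directed_igraph(map)
  nms <- igraph::V(g)$name
  conn <- vapply(seq_along(nms), function(i) {
    up <- igraph::subcomponent(g, i, mode = "in")
    down <- igraph::subcomponent(g, i, mode = "out")
    length(unique(c(as.integer(up), as.integer(down)))) - 1L  # minus v itself
  }, integer(1))
  ord <- order(-conn, nms, method = "radix")[1]
  tibble(gene = nms[ord], connectivity = conn[ord])
}

#' Core signalling equation around a hub
#'
#' The equation is the hub's direct upstream inputs and direct downstream
#' outputs in the superimposed map; its node count is
#' `|inputs| + 1 + |outputs|`.
#'
#' @param map a `superimposed_map`.
#' @param hub gene symbol present in the map.
#' @return an object of class `core_equation`: list with `hub`, `inputs`,
#'   `outputs`, `n_nodes`.
#' @export
core_equation <- function(map, hub) {
  stopifnot(inherits(map, "superimposed_map"))
  hub <- normalize_symbols(hub)
  if (length(hub) != 1) abort("hub must be a single gene")
  if (!hub %in% map_nodes(map)) abort(paste0("hub absent from map: ", hub))
  inputs <- sort(unique(map$edges$source[map$edges$target == hub]))
  outputs <- sort(unique(map$edges$target[map$edges$source == hub]))
  structure(list(hub = hub, inputs = inputs, outputs = outputs,
                 n_nodes = length(inputs) + 1L + length(outputs)),
            class = "core_equation")
}

#' @export
print.core_equation <- function(x, ...) {
  lhs <- if (length(x$inputs)) paste(x$inputs, collapse = ",") else "(none)"
  rhs <- if (length(x$outputs)) paste(x$outputs, collapse = "+") else "(none)"
  cat(lhs, " => ", x$hub, " => ", rhs, "   [", x$n_nodes, " nodes]\n", sep = "")
  invisible(x)
}

#' @rdname core_equation
#' @param x a `core_equation`.
#' @param ... unused.
#' @export
tidy.core_equation <- function(x, ...) {
  tibble(gene = c(x$inputs, x$hub, x$outputs),
         role = c(rep("input", length(x$inputs)), "hub",
                  rep("output", length(x$outputs))))
}

#' Candidates participating in a superimposed map
#'
#' @param map a `superimposed_map`.
#' @param candidates non-empty character vector of candidate genes.
#' @return sorted character vector of candidates incident to at least one
#'   superimposed edge.
#' @export
participating_genes <- function(map, candidates) {
  stopifnot(inherits(map, "superimposed_map"))
  candidates <- unique(normalize_symbols(candidates))
  if (!length(candidates)) abort("candidates must be non-empty")
  incident <- unique(c(map$edges$source, map$edges$target))
  sort(intersect(candidates, incident))
}

#' Export a superimposed map as SIF
#'
#' @param map a `superimposed_map`.
#' @param path output path (`source`, `effect`, `target`).
#' @return `path`, invisibly.
#' @export
write_sif <- function(map, path) {
  stopifnot(inherits(map, "superimposed_map"))
  readr::write_tsv(dplyr::select(map$edges, "source", "effect", "target"),
                   path, col_names = FALSE)
  invisible(path)
}

#' The three-disease core map fixture
#'
#' The printed shared signalling core across type 2 diabetes,
#' osteoarthritis and triple-negative breast cancer: EGFR and CD44 feed
#' into AKT1; AKT1 drives NFKB1, STAT3 and MMP9; NFKB1 targets MMP9 and
#' STAT3 targets MMP1; CTNNB1 activates MMP1 and MMP9; IFNG sits on the
#' map with no interaction. The same nine directed edges are present in
#' all three disease maps, so superimposition at full support retains the
#' whole core.
#'
#' @param diseases labels for the three replicated maps.
#' @return a `disease_maps` object (9 edges per disease, IFNG isolated).
#' @examples
#' m <- superimpose(three_disease_core_map())
#' core_equation(m, "AKT1")
#' @export
three_disease_core_map <- function(diseases = c("T2DM", "OA", "TNBC")) {
  core <- tibble(
    source = c("EGFR", "CD44", "AKT1", "AKT1", "AKT1", "NFKB1", "STAT3",
               "CTNNB1", "CTNNB1"),
    target = c("AKT1", "AKT1", "NFKB1", "STAT3", "MMP9", "MMP9", "MMP1",
               "MMP1", "MMP9"),
    effect = "activate"
  )
  edges <- dplyr::bind_rows(lapply(diseases, function(d) dplyr::mutate(core, disease = d)))
  disease_maps(edges, isolated = "IFNG")
}

#' The candidate meta-hub gene set
#'
#' The nine prioritized candidates carried onto the three-disease map:
#' AKT1, NFKB1, CTNNB1, EGFR, MMP1, MMP9, CD44, STAT3 and IFNG (the
#' cluster seed, which has no interaction on the superimposed map).
#'
#' @return character vector of nine gene symbols.
#' @export
candidate_meta_hubs <- function() {
  c("AKT1", "NFKB1", "CTNNB1", "EGFR", "MMP1", "MMP9", "CD44", "STAT3", "IFNG")
}
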