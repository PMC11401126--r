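#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   distinct bind_rows left_join rename n n_distinct desc across all_of pull
#'   row_number slice_head count anti_join semi_join first
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_dbl map_int map2 imap pmap keep compact
#' @importFrom stats phyper p.adjust runif setNames
#' @importFrom utils head combn
NULL

#' Normalize gene symbols
#'
#' Uppercases and strips whitespace. Empty tokens are dropped. No alias or
#' HGNC resolution is attempted; identifier mapping is left to the caller.
#'
#' @param x character vector of raw gene tokens.
#' @return character vector of normalized symbols (empties removed).
#' @examples
#' normalize_symbols(c(" tp53", "Egfr ", ""))
#' @export
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- x[!is.na(x) & nzchar(x)]
  if (any(grepl("[;[:space:]]", x))) {
    abort("gene symbols must not contain whitespace or ';' after normalization")
  }
  x
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic ordering used for every tie-break: score descending,
# then symbol ascending.
order_score_symbol <- function(score, symbol) {
  order(-score, symbol, method = "radix")
}
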