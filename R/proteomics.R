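# Differential-protein screen: fold-change thresholding, a local
# hypergeometric enrichment test over user-supplied annotation maps (a
# stand-in for web enrichment services), and interaction-network degree
# ranking.

#' Partition proteins by fold-change thresholds
#'
#' Strict thresholds: `fold_change > up` is up-regulated,
#' `fold_change < down` is down-regulated, everything else (including
#' values exactly at a threshold) is unchanged. Defaults are the common
#' 1.5-fold / 0.67-fold cut-offs.
#'
#' @param table Data frame with columns `id` and `fold_change`
#'   (treated/control ratio, positive).
#' @param up,down Thresholds with `0 < down < up`.
#' @return A list with character vectors `up`, `down`, `unchanged` and an
#'   integer `counts` vector; the three sets partition the input ids.
#' @examples
#' tab <- data.frame(id = c("a", "b", "c"), fold_change = c(1.6, 0.5, 1.0))
#' filter_differential(tab)
#' @export
filter_differential <- function(table, up = 1.5, down = 0.67) {
  if (!is.data.frame(table) || !all(c("id", "fold_change") %in% names(table))) {
    synergyci_stop("`table` needs `id` and `fold_change` columns",
                   "schema_error")
  }
  if (!(down > 0 && down < up)) {
    synergyci_stop("thresholds must satisfy 0 < down < up", "invalid_argument")
  }
  fc <- as.numeric(table$fold_change)
  if (any(!is.finite(fc)) || any(fc <= 0)) {
    synergyci_stop("fold changes must be positive and finite",
                   "invalid_argument")
  }
  id <- as.character(table$id)
  up_set <- id[fc > up]
  down_set <- id[fc < down]
  unchanged <- id[fc <= up & fc >= down]
  list(up = up_set, down = down_set, unchanged = unchanged,
       counts = c(up = length(up_set), down = length(down_set),
                  unchanged = length(unchanged)))
}

#' Hypergeometric term enrichment
#'
#' For each annotation term, tests over-representation of the
#' differentially expressed set among the term's proteins with the
#' one-sided hypergeometric tail `P(X >= k)` (`k` hits among `n` drawn from
#' a background of `N` containing `K` term members), then adjusts across
#' terms with Benjamini-Hochberg. An optional EASE mode substitutes
#' `k - 1` for `k` (the conservative variant some enrichment services use);
#' it is off by default.
#'
#' @param dep_ids Character vector of differentially expressed protein ids;
#'   must be a subset of `background`.
#' @param term_map Named list mapping term id to a character vector of
#'   member proteins, or a two-column data frame `(term, protein)`.
#' @param background Character vector: the annotation universe.
#' @param ease If `TRUE`, apply the EASE `k - 1` substitution.
#' @return Data frame sorted by ascending p: `term, k, K, n, N, p, p_adj`.
#' @export
enrich_terms <- function(dep_ids, term_map, background, ease = FALSE) {
  background <- unique(as.character(background))
  if (length(background) == 0L) {
    synergyci_stop("`background` must be non-empty", "invalid_argument")
  }
  dep_ids <- unique(as.character(dep_ids))
  outside <- setdiff(dep_ids, background)
  if (length(outside)) {
    synergyci_stop(paste0("dep ids outside the background: ",
                          paste(utils::head(outside, 5), collapse = ", ")),
                   "invalid_argument")
  }
  if (is.data.frame(term_map)) {
    if (ncol(term_map) < 2L) {
      synergyci_stop("`term_map` data frame needs (term, protein) columns",
                     "schema_error")
    }
    term_map <- split(as.character(term_map[[2]]), as.character(term_map[[1]]))
  }
  if (!is.list(term_map) || is.null(names(term_map))) {
    synergyci_stop("`term_map` must be a named list or (term, protein) table",
                   "schema_error")
  }
  N <- length(background)
  n <- length(dep_ids)
  rows <- lapply(names(term_map), function(term) {
    members <- intersect(unique(as.character(term_map[[term]])), background)
    K <- length(members)
    k <- length(intersect(members, dep_ids))
    k_test <- if (ease) max(k - 1L, 0L) else k
    # one-sided upper tail P(X >= k_test)
    p <- stats::phyper(k_test - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree ranking of an interaction network
#'
#' Collapses duplicate edges and drops self-loops, then counts distinct
#' neighbours per node and ranks by degree (descending), breaking ties by
#' node id (ascending).
#'
#' @param edges Two-column data frame (or matrix) of undirected edges.
#' @return Data frame `id, degree`, ranked.
#' @examples
#' network_degree(data.frame(a = c("hub", "hub", "x"), b = c("x", "y", "y")))
#' @export
network_degree <- function(edges) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    synergyci_stop("`edges` must have two columns (id1, id2)", "schema_error")
  }
  if (nrow(edges) == 0L) {
    return(data.frame(id = character(0), degree = integer(0)))
  }
  el <- cbind(as.character(edges[[1]]), as.character(edges[[2]]))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  deg <- igraph::degree(g)
  out <- data.frame(id = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a protein fold-change table from CSV
#'
#' Columns: `id, fold_change` (header required).
#' @param path Path to the CSV file.
#' @return Data frame of protein quantifications.
#' @export
read_protein_quant <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "fold_change"), names(df))
  if (length(miss)) {
    synergyci_stop(paste0("protein CSV is missing column(s): ",
                          paste(miss, collapse = ", ")), "schema_error")
  }
  df
}

#' Read a term-to-protein map from two-column TSV
#' @param path Path to a TSV with columns `term`, `protein`.
#' @return Named list term -> protein ids.
#' @export
read_term_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    synergyci_stop("term map TSV needs two columns (term, protein)",
                   "schema_error")
  }
  split(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read an undirected edge list from two-column TSV
#' @param path Path to a TSV with two id columns.
#' @return Two-column data frame of edges.
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    synergyci_stop("edge TSV needs two columns (id1, id2)", "schema_error")
  }
  df[, 1:2]
}
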