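#' Build an interaction network from predicted pairs
#'
#' Creates a simple undirected graph over gene symbols: self-pairs are
#' dropped with a warning, duplicate edges (in either orientation) are
#' merged, and for duplicated edges the maximum predicted probability is
#' kept. The node order is lexicographic, so the construction is
#' deterministic.
#'
#' @param edges Data frame with columns `g1`, `g2` and optionally a
#'   probability column.
#' @param prob_col Name of the optional probability column.
#' @param nodes Optional character vector of node names; defaults to the
#'   edge endpoints. Extra names become isolated nodes.
#' @return An object of class `litnet_network`: list with `nodes` (sorted
#'   character), `edges` (tibble `g1 < g2`, plus `prob` if supplied), and
#'   `graph` (the underlying igraph object).
#' @export
build_network <- function(edges, prob_col = "prob", nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("g1", "g2") %in% names(edges)))
  has_prob <- prob_col %in% names(edges)
  e <- tibble::tibble(g1 = as.character(edges$g1),
                      g2 = as.character(edges$g2))
  if (has_prob) e$prob <- as.numeric(edges[[prob_col]])
  loops <- e$g1 == e$g2
  if (any(loops)) {
    warn(paste0("dropping ", sum(loops), " self-pair row(s)"))
    e <- e[!loops, ]
  }
  if (nrow(e)) {
    swap <- e$g1 > e$g2
    tmp <- e$g1[swap]; e$g1[swap] <- e$g2[swap]; e$g2[swap] <- tmp
    if (has_prob) {
      e <- dplyr::summarise(dplyr::group_by(e, .data$g1, .data$g2),
                            prob = max(.data$prob), .groups = "drop")
    } else {
      e <- dplyr::distinct(e)
    }
    e <- dplyr::arrange(e, .data$g1, .data$g2)
  }
  nodes <- sort(unique(c(e$g1, e$g2, as.character(nodes %||% character(0)))))
  g <- igraph::graph_from_data_frame(as.data.frame(e), directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = e, graph = g),
            class = "litnet_network")
}

#' @export
print.litnet_network <- function(x, ...) {
  cat("<interaction network>", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

as_seed_symbols <- function(seeds) {
  if (is.data.frame(seeds)) {
    col <- intersect(c("symbol", "gene"), names(seeds))[1]
    if (is.na(col)) abort("seed data frame needs a 'symbol' (or 'gene') column")
    seeds <- seeds[[col]]
  }
  seeds <- unique(trimws(as.character(seeds)))
  seeds[nzchar(seeds)]
}

#' Extract a seed-anchored disease subnetwork
#'
#' Keeps exactly the edges that touch at least one seed gene; the node set is
#' the endpoints of those edges. Edges between two non-seed genes are
#' excluded even when both endpoints are adjacent to seeds. Seeds absent from
#' the network are reported (they feed the seed-recall measure).
#'
#' @param net A `litnet_network`.
#' @param seeds Character vector of seed gene symbols, or a data frame with a
#'   `symbol` column.
#' @return A `litnet_network` with attribute `missing_seeds`.
#' @export
extract_disease_subnetwork <- function(net, seeds) {
  stopifnot(inherits(net, "litnet_network"))
  seeds <- as_seed_symbols(seeds)
  if (!length(seeds)) abort("seed list is empty")
  missing <- setdiff(seeds, net$nodes)
  if (length(missing)) {
    inform(paste0(length(missing), " seed(s) absent from the network: ",
                  paste(missing, collapse = ", ")))
  }
  keep <- net$edges$g1 %in% seeds | net$edges$g2 %in% seeds
  sub <- build_network(net$edges[keep, ])
  attr(sub, "missing_seeds") <- missing
  attr(sub, "seeds") <- seeds
  sub
}

centrality_tbl <- function(net, score) {
  tibble::tibble(gene = net$nodes, score = unname(score))
}

#' Centrality scores of an interaction network
#'
#' Four classical node-importance measures on the unweighted, undirected
#' graph:
#' \describe{
#'   \item{degree}{raw neighbour count, no normalization.}
#'   \item{closeness}{within each connected component,
#'     `(|comp| - 1) / sum of shortest-path distances`; isolated nodes score
#'     0. Components are scored separately so disconnected graphs produce no
#'     infinities.}
#'   \item{betweenness}{sum over pairs of other nodes of the fraction of
#'     shortest paths passing through the node; endpoints excluded, each
#'     unordered pair counted once, unnormalized by default.}
#'   \item{eigenvector}{power iteration on `A + I` (the spectral shift keeps
#'     the iteration convergent on bipartite graphs) from an all-ones start,
#'     L2-normalized, tolerance `1e-10`, at most 1000 iterations. On
#'     disconnected graphs the scores reflect the dominant component.}
#' }
#'
#' @param net A `litnet_network`.
#' @param measure One of `"degree"`, `"closeness"`, `"betweenness"`,
#'   `"eigenvector"`.
#' @param normalized For betweenness only: divide by the number of
#'   considered pairs `(n-1)(n-2)/2` (default `FALSE`).
#' @return A tibble with columns `gene`, `score` (node order).
#' @export
centrality_scores <- function(net, measure = c("degree", "closeness",
                                               "betweenness", "eigenvector"),
                              normalized = FALSE) {
  measure <- match.arg(measure)
  switch(measure,
         degree = degree_centrality(net),
         closeness = closeness_centrality(net),
         betweenness = betweenness_centrality(net, normalized = normalized),
         eigenvector = eigenvector_centrality(net))
}

#' @rdname centrality_scores
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "litnet_network"))
  centrality_tbl(net, as.numeric(igraph::degree(net$graph)))
}

#' @rdname centrality_scores
#' @export
closeness_centrality <- function(net) {
  stopifnot(inherits(net, "litnet_network"))
  n <- length(net$nodes)
  if (!n) return(centrality_tbl(net, numeric(0)))
  d <- igraph::distances(net$graph)
  memb <- igraph::components(net$graph)$membership
  score <- vapply(seq_len(n), function(v) {
    comp <- which(memb == memb[v])
    if (length(comp) < 2L) return(0)
    (length(comp) - 1) / sum(d[v, comp])
  }, numeric(1))
  centrality_tbl(net, score)
}

#' @rdname centrality_scores
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  stopifnot(inherits(net, "litnet_network"))
  b <- as.numeric(igraph::betweenness(net$graph, directed = FALSE,
                                      normalized = FALSE))
  n <- length(net$nodes)
  if (normalized && n > 2L) b <- b / ((n - 1) * (n - 2) / 2)
  centrality_tbl(net, b)
}

#' @rdname centrality_scores
#' @export
eigenvector_centrality <- function(net) {
  stopifnot(inherits(net, "litnet_network"))
  n <- length(net$nodes)
  if (!n) return(centrality_tbl(net, numeric(0)))
  if (!nrow(net$edges)) return(centrality_tbl(net, rep(0, n)))
  A <- as.matrix(igraph::as_adjacency_matrix(net$graph, sparse = FALSE))
  v <- rep(1, n) / sqrt(n)
  for (it in seq_len(1000L)) {
    nv <- drop(A %*% v) + v          # power iteration on A + I
    nv <- nv / sqrt(sum(nv^2))
    if (max(abs(nv - v)) <= 1e-10) { v <- nv; break }
    v <- nv
  }
  v[abs(v) < 1e-12] <- 0
  centrality_tbl(net, pmax(v, 0))
}

#' Summary statistics of an interaction network
#'
#' Node and edge counts, the diameter of the largest connected component
#' (unweighted), and the average clustering coefficient (mean over all nodes
#' of the local clustering coefficient, nodes of degree < 2 contributing 0).
#'
#' @param net A `litnet_network`.
#' @return A one-row tibble with columns `nodes`, `edges`, `diameter`,
#'   `clustering`. `diameter` is `NA` for edgeless graphs.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "litnet_network"))
  n <- length(net$nodes)
  m <- nrow(net$edges)
  if (!m) {
    return(tibble::tibble(nodes = n, edges = m, diameter = NA_real_,
                          clustering = if (n) 0 else NA_real_))
  }
  comp <- igraph::components(net$graph)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(net$graph, which(comp$membership == big))
  diam <- as.numeric(igraph::diameter(sub, directed = FALSE,
                                      unconnected = FALSE))
  cc <- igraph::transitivity(net$graph, type = "localaverage",
                             isolates = "zero")
  tibble::tibble(nodes = n, edges = m, diameter = diam, clustering = cc)
}

#' @export
glance.litnet_network <- function(x, ...) network_stats(x)

#' Top-n genes by centrality score
#'
#' Orders genes by descending score, breaking ties by ascending symbol, and
#' keeps the first `min(n, number of nodes)`.
#'
#' @param scores Centrality tibble (`gene`, `score`) from
#'   [centrality_scores()].
#' @param n How many genes to keep (default 15, the usual evaluation depth
#'   for disease-gene ranking).
#' @return A tibble `rank`, `gene`, `score`.
#' @export
rank_top_n <- function(scores, n = 15L) {
  stopifnot(all(c("gene", "score") %in% names(scores)), n >= 1L)
  ord <- order(-scores$score, scores$gene)
  k <- min(as.integer(n), nrow(scores))
  idx <- ord[seq_len(k)]
  tibble::tibble(rank = seq_len(k), gene = scores$gene[idx],
                 score = scores$score[idx])
}

#' Write / read an edge list
#'
#' TSV `g1<TAB>g2[<TAB>prob]` with header.
#'
#' @param net A `litnet_network` (or an edge tibble).
#' @param path File path.
#' @return `read_edges()` returns an edge tibble; `write_edges()` returns
#'   `path` invisibly.
#' @export
write_edges <- function(net, path) {
  e <- if (inherits(net, "litnet_network")) net$edges else tibble::as_tibble(net)
  readr::write_tsv(e, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    g1 = "c", g2 = "c", .default = "d"), progress = FALSE)
}
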