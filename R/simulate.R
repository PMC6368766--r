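#' Simulate an abstract corpus with a planted interaction graph
#'
#' Generates a synthetic corpus in which a hidden gene-gene interaction graph
#' drives the text: every sentence focuses on one gene pair -- an interacting
#' pair with probability `edge_sentence_prob`, otherwise a uniformly drawn
#' non-interacting pair -- and mentions both genes of the focal pair with
#' probability `p_cooccur_pos` (interacting) or `p_cooccur_neg`
#' (non-interacting); otherwise a single gene is mentioned. A jointly
#' mentioned pair is connected by an interaction cue phrase with probability
#' `p_cue` (else by a neutral connector), and each mentioned gene drags in
#' one of its GO term names with probability `p_go_mention`. The hidden graph
#' is Erdős–Rényi background plus a planted clique module of
#' `module_size` genes, the first `n_module_seeds` of which are designated
#' disease seed genes.
#'
#' Gene symbols (`G0001`, ...) and GO term names (`pathway0001x01
#' signaling`) are constructed to be collision-free under alphanumeric
#' tokenization. The output is a deterministic function of `seed`.
#'
#' @param n_genes Number of genes (default 200).
#' @param go_terms_per_gene GO annotations per gene (default 3).
#' @param n_abstracts Number of abstracts (default 2000).
#' @param sentences_per_abstract Sentences per abstract body (default 5).
#' @param edge_prob Erdős–Rényi background edge probability (default
#'   0.0075, about 1.5 expected background partners per gene).
#' @param module_size,n_module_seeds Planted disease-module clique size and
#'   how many of its genes act as seeds.
#' @param p_cooccur_pos,p_cooccur_neg Per-sentence joint-mention
#'   probabilities for interacting / non-interacting focal pairs; require
#'   `0 <= p_cooccur_neg < p_cooccur_pos <= 1`.
#' @param p_cue Probability a joint mention is linked by a cue phrase.
#' @param p_go_mention Probability a mentioned gene also mentions one of its
#'   GO terms.
#' @param edge_sentence_prob Probability a sentence focuses on an
#'   interacting pair.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `litnet_sim_corpus`: `abstracts` (tibble `id`,
#'   `title`, `body`), `lexicon`, `annotations`, `true_edges` (tibble `g1`,
#'   `g2`, `module`), `module_genes`, `seed_genes`, `config`.
#' @export
simulate_corpus <- function(n_genes = 200L, go_terms_per_gene = 3L,
                            n_abstracts = 2000L, sentences_per_abstract = 5L,
                            edge_prob = 0.0075, module_size = 10L,
                            n_module_seeds = 3L,
                            p_cooccur_pos = 0.3, p_cooccur_neg = 0.005,
                            p_cue = 0.8, p_go_mention = 0.3,
                            edge_sentence_prob = 0.5, seed = 1L) {
  stopifnot(n_genes >= 2L, go_terms_per_gene >= 1L, n_abstracts >= 1L,
            sentences_per_abstract >= 1L,
            module_size >= 0L, module_size <= n_genes,
            n_module_seeds <= module_size)
  if (!(p_cooccur_neg >= 0 && p_cooccur_neg <= p_cooccur_pos &&
        p_cooccur_pos <= 1)) {
    abort("require 0 <= p_cooccur_neg <= p_cooccur_pos <= 1")
  }
  set.seed(as.integer(seed))
  genes <- sprintf("G%04d", seq_len(n_genes))

  ann <- tibble::tibble(
    symbol = rep(genes, each = go_terms_per_gene),
    gi = rep(seq_len(n_genes), each = go_terms_per_gene),
    ti = rep(seq_len(go_terms_per_gene), times = n_genes))
  ann$go_id <- sprintf("GO:%07d", seq_len(nrow(ann)))
  ann$go_name <- sprintf("pathway%04dx%02d signaling", ann$gi, ann$ti)
  annotations <- ann[c("symbol", "go_id", "go_name")]

  # hidden graph: ER background + planted clique module
  edge_env <- new.env(parent = emptyenv())
  edges <- list()
  add_edge <- function(a, b, module) {
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    key <- paste0(a, "|", b)
    if (!exists(key, envir = edge_env, inherits = FALSE)) {
      assign(key, TRUE, envir = edge_env)
      edges[[length(edges) + 1L]] <<- c(a, b, module)
    }
  }
  module_genes <- character(0)
  if (module_size >= 2L) {
    module_genes <- sample(genes, module_size)
    cmb <- utils::combn(module_genes, 2L)
    for (k in seq_len(ncol(cmb))) add_edge(cmb[1, k], cmb[2, k], TRUE)
  }
  if (n_genes >= 2L && edge_prob > 0) {
    cmb <- utils::combn(genes, 2L)
    draw <- runif(ncol(cmb)) < edge_prob
    for (k in which(draw)) add_edge(cmb[1, k], cmb[2, k], FALSE)
  }
  em <- do.call(rbind, edges)
  true_edges <- tibble::tibble(g1 = em[, 1], g2 = em[, 2],
                               module = as.logical(em[, 3]))
  is_edge <- function(a, b) {
    key <- if (a < b) paste0(a, "|", b) else paste0(b, "|", a)
    exists(key, envir = edge_env, inherits = FALSE)
  }
  seed_genes <- head(module_genes, n_module_seeds)

  cue_phrases <- c("interacts with", "binds with", "binds to",
                   "associated with", "and")
  go_of <- split(annotations$go_name, annotations$symbol)
  one_sentence <- function() {
    use_edge <- nrow(true_edges) > 0 && runif(1) < edge_sentence_prob
    if (use_edge) {
      k <- sample.int(nrow(true_edges), 1L)
      pair <- c(true_edges$g1[k], true_edges$g2[k])
      p_joint <- p_cooccur_pos
    } else {
      repeat {
        pair <- sample(genes, 2L)
        if (!is_edge(pair[1], pair[2])) break
      }
      p_joint <- p_cooccur_neg
    }
    go_tag <- function(g) {
      if (runif(1) < p_go_mention) {
        paste(" via", sample(go_of[[g]], 1L))
      } else ""
    }
    if (runif(1) < p_joint) {
      connector <- if (runif(1) < p_cue) sample(cue_phrases, 1L) else "alongside"
      paste0(pair[1], go_tag(pair[1]), " ", connector, " ",
             pair[2], go_tag(pair[2]), " in cells.")
    } else {
      g <- sample(pair, 1L)
      paste0("We measured ", g, go_tag(g), " expression.")
    }
  }
  ids <- sprintf("A%06d", seq_len(n_abstracts))
  titles <- sprintf("Synthetic abstract %d", seq_len(n_abstracts))
  bodies <- vapply(seq_len(n_abstracts), function(i) {
    paste(replicate(sentences_per_abstract, one_sentence()), collapse = " ")
  }, character(1))
  structure(list(abstracts = tibble::tibble(id = ids, title = titles,
                                            body = bodies),
                 lexicon = as_gene_lexicon(genes),
                 annotations = annotations,
                 true_edges = true_edges,
                 module_genes = module_genes,
                 seed_genes = seed_genes,
                 config = list(n_genes = n_genes,
                               go_terms_per_gene = go_terms_per_gene,
                               n_abstracts = n_abstracts,
                               sentences_per_abstract = sentences_per_abstract,
                               edge_prob = edge_prob,
                               module_size = module_size,
                               n_module_seeds = n_module_seeds,
                               p_cooccur_pos = p_cooccur_pos,
                               p_cooccur_neg = p_cooccur_neg,
                               p_cue = p_cue, p_go_mention = p_go_mention,
                               edge_sentence_prob = edge_sentence_prob,
                               seed = seed)),
            class = "litnet_sim_corpus")
}

#' Write a simulated corpus to plain-text files
#'
#' Writes `abstracts.tsv`, `genes.txt`, `go_annotations.tsv` and
#' `true_edges.tsv` into a directory, in the formats the readers expect.
#'
#' @param sim A `litnet_sim_corpus` from [simulate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_corpus <- function(sim, dir) {
  stopifnot(inherits(sim, "litnet_sim_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abstracts(sim$abstracts, file.path(dir, "abstracts.tsv"))
  writeLines(sim$lexicon$symbol, file.path(dir, "genes.txt"))
  writeLines(paste(sim$annotations$symbol, sim$annotations$go_id,
                   sim$annotations$go_name, sep = "\t"),
             file.path(dir, "go_annotations.tsv"))
  readr::write_tsv(sim$true_edges, file.path(dir, "true_edges.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Simulate a labeled feature table from a known logistic model
#'
#' Draws nine features i.i.d. on `[0, 1]` and labels from
#' `y ~ Bernoulli(plogis(b0 + x %*% beta_star))`, with the intercept `b0`
#' solved numerically so the achieved event fraction matches the target
#' prevalence (a rare-event setting by default).
#'
#' @param n_rows Number of pairs.
#' @param beta_star True slope vector of length 9.
#' @param prevalence Target event fraction in (0, 0.5).
#' @param dist Feature distribution: `"uniform"` on \[0,1\] or `"beta"`
#'   (Beta(2, 5), right-skewed like sparse co-occurrence ratios).
#' @param seed Integer seed.
#' @return A tibble `pair`, `W1..W9`, `label`, with attributes `beta_star`
#'   and `intercept`.
#' @export
simulate_feature_table <- function(n_rows = 5000L,
                                   beta_star = c(1.5, -2, 1, 0.5, -0.5,
                                                 0, 2, -1, 0.25),
                                   prevalence = 0.05,
                                   dist = c("uniform", "beta"),
                                   seed = 1L) {
  dist <- match.arg(dist)
  stopifnot(length(beta_star) == 9L, prevalence > 0, prevalence < 0.5)
  set.seed(as.integer(seed))
  x <- switch(dist,
              uniform = matrix(runif(n_rows * 9L), n_rows, 9L),
              beta = matrix(stats::rbeta(n_rows * 9L, 2, 5), n_rows, 9L))
  x[x < 0] <- 0; x[x > 1] <- 1
  colnames(x) <- feature_cols()
  eta0 <- drop(x %*% beta_star)
  b0 <- uniroot(function(b) mean(plogis(b + eta0)) - prevalence,
                lower = -50, upper = 50, tol = 1e-10)$root
  y <- rbinom(n_rows, 1L, plogis(b0 + eta0))
  out <- tibble::as_tibble(as.data.frame(x))
  out <- dplyr::bind_cols(tibble::tibble(pair = sprintf("P%06d",
                                                        seq_len(n_rows))), out)
  out$label <- as.integer(y)
  attr(out, "beta_star") <- beta_star
  attr(out, "intercept") <- b0
  out
}

#' Fixture graphs with brute-force centrality answers
#'
#' A bundle of small named graphs -- the path P3, the star K1,4, the
#' triangle K3, the clique K4, a barbell (two triangles joined by a bridge)
#' -- plus seeded random graphs of at most `max_nodes` nodes, each carrying
#' a centrality table computed by the independent brute-force oracle
#' [oracle_centrality()] (exhaustive shortest-path enumeration and direct
#' eigen-decomposition, no graph library).
#'
#' @param n_random Number of random graphs (default 50).
#' @param max_nodes Maximum random-graph order (default 8).
#' @param seed Integer seed; the bundle regenerates identically under the
#'   same seed.
#' @return Named list; each element has `nodes`, `edges` (tibble `g1`,
#'   `g2`) and `centrality` (tibble `gene`, `degree`, `closeness`,
#'   `betweenness`, `eigenvector`).
#' @export
fixture_graphs <- function(n_random = 50L, max_nodes = 8L, seed = 1L) {
  set.seed(as.integer(seed))
  lab <- function(n) sprintf("n%02d", seq_len(n))
  pack <- function(nodes, e1, e2) {
    edges <- tibble::tibble(g1 = pmin(e1, e2), g2 = pmax(e1, e2))
    edges <- dplyr::arrange(dplyr::distinct(edges), .data$g1, .data$g2)
    list(nodes = nodes, edges = edges,
         centrality = oracle_centrality(nodes, edges))
  }
  out <- list(
    p3 = pack(lab(3), c("n01", "n02"), c("n02", "n03")),
    star5 = pack(lab(5), rep("n01", 4), lab(5)[-1]),
    k3 = pack(lab(3), c("n01", "n01", "n02"), c("n02", "n03", "n03")),
    k4 = {
      cmb <- utils::combn(lab(4), 2L)
      pack(lab(4), cmb[1, ], cmb[2, ])
    },
    barbell = pack(lab(6),
                   c("n01", "n01", "n02", "n03", "n04", "n04", "n05"),
                   c("n02", "n03", "n03", "n04", "n05", "n06", "n06")))
  for (r in seq_len(n_random)) {
    n <- sample(4:max_nodes, 1L)
    nodes <- lab(n)
    cmb <- utils::combn(nodes, 2L)
    keep <- runif(ncol(cmb)) < runif(1, 0.25, 0.6)
    out[[sprintf("random%02d", r)]] <-
      pack(nodes, cmb[1, keep], cmb[2, keep])
  }
  out
}

#' Brute-force centrality oracle
#'
#' Reference centralities for small graphs, computed without any graph
#' library: Floyd-Warshall distances, closeness per connected component,
#' betweenness by exhaustive enumeration of all shortest paths, and
#' eigenvector centrality as the normalized projection of the all-ones
#' vector onto the dominant eigenspace of the adjacency matrix (the exact
#' limit of a convergent power iteration). Intended as an independent oracle
#' for [centrality_scores()]; quadratic-to-exponential cost, use on graphs
#' of at most a dozen nodes.
#'
#' @param nodes Character vector of node names.
#' @param edges Tibble with columns `g1`, `g2` (endpoints must be in
#'   `nodes`).
#' @return A tibble `gene`, `degree`, `closeness`, `betweenness`,
#'   `eigenvector`.
#' @export
oracle_centrality <- function(nodes, edges) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    i <- match(edges$g1, nodes); j <- match(edges$g2, nodes)
    stopifnot(!anyNA(i), !anyNA(j))
    A[cbind(i, j)] <- 1; A[cbind(j, i)] <- 1
  }
  # Floyd-Warshall
  D <- ifelse(A > 0, 1, Inf); diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- D[i, k] + D[k, ]
      upd <- nd < D[i, ]
      D[i, upd] <- nd[upd]
    }
  }
  degree <- unname(rowSums(A))
  closeness <- vapply(seq_len(n), function(v) {
    comp <- which(is.finite(D[v, ]))
    if (length(comp) < 2L) return(0)
    (length(comp) - 1) / sum(D[v, comp])
  }, numeric(1))

  betweenness <- numeric(n)
  if (n >= 3L) {
    paths_between <- function(s, t) {
      # all shortest s-t paths as lists of node indices
      if (!is.finite(D[s, t]) || s == t) return(list())
      grow <- function(v) {
        if (v == t) return(list(t))
        nexts <- which(A[v, ] > 0 & D[, t] == D[v, t] - 1)
        out <- list()
        for (u in nexts) {
          for (p in grow(u)) out[[length(out) + 1L]] <- c(v, p)
        }
        out
      }
      grow(s)
    }
    for (s in seq_len(n - 1L)) {
      for (t in (s + 1L):n) {
        ps <- paths_between(s, t)
        if (!length(ps)) next
        sigma <- length(ps)
        inner <- unlist(lapply(ps, function(p) p[-c(1L, length(p))]))
        if (length(inner)) {
          tab <- table(inner)
          idx <- as.integer(names(tab))
          betweenness[idx] <- betweenness[idx] + as.numeric(tab) / sigma
        }
      }
    }
  }

  eigenvector <- rep(0, n)
  if (any(A > 0)) {
    eg <- eigen(A, symmetric = TRUE)
    lam1 <- eg$values[1]
    top <- which(eg$values > lam1 - 1e-9)
    V <- eg$vectors[, top, drop = FALSE]
    v <- drop(V %*% crossprod(V, rep(1, n)))
    if (sqrt(sum(v^2)) < 1e-12) v <- eg$vectors[, 1]
    v <- v / sqrt(sum(v^2))
    if (sum(v) < 0) v <- -v
    v[abs(v) < 1e-12] <- 0
    eigenvector <- pmax(v, 0)
  }
  tibble::tibble(gene = nodes, degree = degree, closeness = closeness,
                 betweenness = betweenness, eigenvector = eigenvector)
}
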