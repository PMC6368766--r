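#' Read a benchmark or seed gene set
#'
#' One gene symbol per line; whitespace is trimmed, blank lines dropped.
#' Multiple benchmark files can be combined with `union()` of the returned
#' vectors (benchmark union is how multi-source evaluation is done here).
#'
#' @param path File path.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  unique(x[nzchar(x)])
}

#' Precision of the top-n ranked genes against a benchmark
#'
#' The fraction of the first `n` ranked genes present in the benchmark set.
#' Symbol matching is exact and case-sensitive after whitespace trimming; no
#' alias resolution is attempted.
#'
#' @param ranked Character vector of ranked gene symbols (best first), or a
#'   tibble from [rank_top_n()] with a `gene` column.
#' @param benchmark Character vector of benchmark gene symbols (or a data
#'   frame with a `symbol` column).
#' @param n Evaluation depth, `1 <= n <= length(ranked)`; no padding is
#'   performed.
#' @return An object of class `litnet_precision`: list with `n`,
#'   `precision`, `n_hit` and `hits` (tibble `rank`, `gene`,
#'   `in_benchmark`).
#' @export
precision_at_n <- function(ranked, benchmark, n = 15L) {
  if (is.data.frame(ranked)) ranked <- ranked$gene
  ranked <- trimws(as.character(ranked))
  benchmark <- as_seed_symbols(benchmark)
  n <- as.integer(n)
  if (n < 1L) abort("n must be >= 1")
  if (n > length(ranked)) {
    abort(paste0("n = ", n, " exceeds the ranking length (",
                 length(ranked), "); no padding is performed"))
  }
  top <- ranked[seq_len(n)]
  flag <- top %in% benchmark
  structure(list(n = n, precision = sum(flag) / n, n_hit = sum(flag),
                 hits = tibble::tibble(rank = seq_len(n), gene = top,
                                       in_benchmark = flag)),
            class = "litnet_precision")
}

#' @export
print.litnet_precision <- function(x, ...) {
  cat("<precision@", x$n, "> ", x$n_hit, "/", x$n, " = ",
      sprintf("%.1f%%", 100 * x$precision), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.litnet_precision <- function(x, ...) x$hits

#' @export
glance.litnet_precision <- function(x, ...) {
  tibble::tibble(n = x$n, n_hit = x$n_hit, precision = x$precision)
}

#' Seed recall of a network
#'
#' The fraction of seed genes that appear as nodes of the network: an
#' indication of how much of the curated disease knowledge the co-occurrence
#' network covers.
#'
#' @param net A `litnet_network`.
#' @param seeds Seed gene symbols (character vector or data frame with a
#'   `symbol` column); must be non-empty.
#' @return A fraction in `[0, 1]`.
#' @export
seed_recall <- function(net, seeds) {
  stopifnot(inherits(net, "litnet_network"))
  seeds <- as_seed_symbols(seeds)
  if (!length(seeds)) abort("seed list is empty")
  length(intersect(seeds, net$nodes)) / length(seeds)
}

check_scores_labels <- function(p, y) {
  y <- check_labels(y)
  stopifnot(length(p) == length(y), all(is.finite(p)))
  if (length(unique(y)) < 2L) abort("both classes must be present")
  list(p = as.numeric(p), y = y)
}

roc_points <- function(p, y) {
  ord <- order(p, decreasing = TRUE)
  p <- p[ord]; y <- y[ord]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  # group tied scores: one operating point per distinct threshold
  last <- cumsum(rle(p)$lengths)
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == 0)[last]
  tibble::tibble(threshold = c(Inf, p[last]),
                 fpr = c(0, fp / n0),
                 tpr = c(0, tp / n1))
}

#' ROC curve and area under it
#'
#' Operating points swept over all distinct score thresholds (a pair is
#' predicted positive when its score strictly exceeds the threshold), with
#' the terminal points (0,0) and (1,1) included. `auc()` integrates the
#' curve by the trapezoid rule; it equals the concordance probability
#' between a random positive and a random negative (ties counting 1/2).
#'
#' @param data Data frame with the label and score columns.
#' @param truth,estimate Column names of the 0/1 labels and the scores.
#' @return `roc_curve()`: a tibble of class `litnet_roc` with columns
#'   `threshold`, `fpr`, `tpr`; `pr_curve()`: class `litnet_pr` with
#'   `threshold`, `recall`, `precision`; `auc()`: a scalar in `[0, 1]`.
#' @export
roc_curve <- function(data, truth = "label", estimate = "prob") {
  pl <- check_scores_labels(data[[estimate]], data[[truth]])
  out <- roc_points(pl$p, pl$y)
  class(out) <- c("litnet_roc", class(out))
  out
}

#' @rdname roc_curve
#' @param curve A `litnet_roc` tibble (or any tibble with `fpr`, `tpr`).
#' @export
auc <- function(curve) {
  stopifnot(all(c("fpr", "tpr") %in% names(curve)))
  x <- curve$fpr; y <- curve$tpr
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @rdname roc_curve
#' @export
pr_curve <- function(data, truth = "label", estimate = "prob") {
  pl <- check_scores_labels(data[[estimate]], data[[truth]])
  ord <- order(pl$p, decreasing = TRUE)
  p <- pl$p[ord]; y <- pl$y[ord]
  n1 <- sum(y == 1)
  last <- cumsum(rle(p)$lengths)
  tp <- cumsum(y == 1)[last]
  pred <- last
  out <- tibble::tibble(threshold = c(Inf, p[last]),
                        recall = c(0, tp / n1),
                        precision = c(1, tp / pred))
  class(out) <- c("litnet_pr", class(out))
  out
}

#' Summarize a flagged top-n validation table
#'
#' For a ranked prediction list whose rows carry a validation status
#' (`"YES"`: validated by a benchmark; `"YES+Seed"`: validated and a seed
#' gene; `"Seed"`: seed gene only; `"candidate"`: unvalidated novel
#' prediction) and, optionally, a competing method's ranked list, computes
#' the validated fraction (`YES` or `YES+Seed`), the seed fraction
#' (`YES+Seed` or `Seed`) and the overlap with the competing list.
#'
#' @param tbl Data frame with columns `symbol`, `status` and optionally
#'   `comparison_symbol`.
#' @return A one-row tibble with `n`, `n_validated`, `validated_frac`,
#'   `n_seed`, `seed_frac`, `n_shared` (NA without a comparison column) and
#'   a list-column `shared` of the overlapping symbols.
#' @export
summarize_validation <- function(tbl) {
  stopifnot(all(c("symbol", "status") %in% names(tbl)))
  n <- nrow(tbl)
  validated <- tbl$status %in% c("YES", "YES+Seed")
  seed <- tbl$status %in% c("YES+Seed", "Seed")
  shared <- if ("comparison_symbol" %in% names(tbl)) {
    intersect(trimws(tbl$symbol), trimws(tbl$comparison_symbol))
  } else NULL
  tibble::tibble(n = n,
                 n_validated = sum(validated),
                 validated_frac = sum(validated) / n,
                 n_seed = sum(seed),
                 seed_frac = sum(seed) / n,
                 n_shared = if (is.null(shared)) NA_integer_ else length(shared),
                 shared = list(shared %||% character(0)))
}
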