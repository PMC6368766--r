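#' Default interaction cue lexicon
#'
#' Lowercase phrases that, when found strictly between two entity mentions in
#' a sentence, mark the pair as semantically linked. The single-word cues
#' `"and"` / `"or"` are matched as standalone tokens.
#'
#' @return Character vector of cue phrases.
#' @export
default_cues <- function() {
  c("binds with", "interacts with", "interact with", "binds to",
    "associated with", "and", "or")
}

cue_regex <- function(cues) {
  esc <- gsub("([][.\\\\+*?^$(){}=!<>|:#-])", "\\\\\\1", cues, perl = TRUE)
  esc <- esc[order(-nchar(cues))]
  paste0("(?<![a-z0-9])(?:", paste(esc, collapse = "|"), ")(?![a-z0-9])")
}

#' Build a three-level occurrence index from mentions
#'
#' Collapses entity mentions into per-entity occurrence sets at the abstract
#' level (abstract ids) and sentence level (abstract id, sentence index), and
#' records semantic links: a link between two entities is recorded for a
#' sentence when both are mentioned in it and a cue phrase occurs strictly
#' between the two mention spans (for at least one ordering of their mention
#' pairs), with no third entity mention lying between them -- the cue must
#' link the two mentions directly, so in "A was studied; B and C rose" only
#' (B, C) is linked.
#'
#' @param mentions Mention tibble from [find_mentions()].
#' @param abstracts The corpus the mentions came from (needed to read the
#'   text between mentions).
#' @param cues Cue lexicon, see [default_cues()].
#' @return An object of class `litnet_index`: a list with tibbles
#'   `abstract_occ` (`entity_kind`, `entity_id`, `abstract_id`),
#'   `sentence_occ` (adds `sentence_index`) and `semantic_links`
#'   (`kind_a`, `id_a`, `kind_b`, `id_b`, `abstract_id`, `sentence_index`,
#'   entity keys ordered so that `(kind_a, id_a) < (kind_b, id_b)`).
#' @export
build_occurrence_index <- function(mentions, abstracts, cues = default_cues()) {
  stopifnot(is.character(cues), length(cues) >= 1L)
  abstract_occ <- dplyr::distinct(
    mentions[c("entity_kind", "entity_id", "abstract_id")])
  sentence_occ <- dplyr::distinct(
    mentions[c("entity_kind", "entity_id", "abstract_id", "sentence_index")])

  links <- empty_links()
  if (nrow(mentions)) {
    texts <- setNames(abstract_text(abstracts$title, abstracts$body),
                      abstracts$id)
    rx <- cue_regex(tolower(cues))
    pieces <- list()
    grp <- split(seq_len(nrow(mentions)),
                 paste(mentions$abstract_id, mentions$sentence_index, sep = "\r"))
    for (ix in grp) {
      if (length(ix) < 2L) next
      mm <- mentions[ix, ]
      cmb <- utils::combn(seq_len(nrow(mm)), 2L)
      for (k in seq_len(ncol(cmb))) {
        a <- cmb[1L, k]; b <- cmb[2L, k]
        if (mm$entity_kind[a] == mm$entity_kind[b] &&
            mm$entity_id[a] == mm$entity_id[b]) next
        if (mm$start[a] > mm$start[b]) { tmp <- a; a <- b; b <- tmp }
        others <- setdiff(seq_len(nrow(mm)), c(a, b))
        if (any(mm$start[others] < mm$start[b] & mm$end[others] > mm$end[a])) {
          next  # a third mention sits between the two: no direct link
        }
        between <- substr(texts[[mm$abstract_id[a]]],
                          mm$end[a] + 1L, mm$start[b])
        if (!grepl(rx, tolower(between), perl = TRUE)) next
        ka <- paste(mm$entity_kind[a], mm$entity_id[a])
        kb <- paste(mm$entity_kind[b], mm$entity_id[b])
        if (ka > kb) { tmp <- a; a <- b; b <- tmp }
        pieces[[length(pieces) + 1L]] <- tibble::tibble(
          kind_a = mm$entity_kind[a], id_a = mm$entity_id[a],
          kind_b = mm$entity_kind[b], id_b = mm$entity_id[b],
          abstract_id = mm$abstract_id[a],
          sentence_index = mm$sentence_index[a])
      }
    }
    if (length(pieces)) {
      links <- dplyr::distinct(dplyr::bind_rows(pieces))
    }
  }
  structure(list(abstract_occ = abstract_occ,
                 sentence_occ = sentence_occ,
                 semantic_links = links),
            class = "litnet_index")
}

empty_links <- function() {
  tibble::tibble(kind_a = character(), id_a = character(),
                 kind_b = character(), id_b = character(),
                 abstract_id = character(), sentence_index = integer())
}

#' @export
print.litnet_index <- function(x, ...) {
  cat("<litnet occurrence index>\n")
  cat("  entities (abstract level):",
      nrow(dplyr::distinct(x$abstract_occ[c("entity_kind", "entity_id")])), "\n")
  cat("  abstract-level occurrences:", nrow(x$abstract_occ), "\n")
  cat("  sentence-level occurrences:", nrow(x$sentence_occ), "\n")
  cat("  semantic links:", nrow(x$semantic_links), "\n")
  invisible(x)
}

# occurrence sets for a raw entity
entity_units <- function(index, id, kind, level) {
  if (level == "abstract") {
    occ <- index$abstract_occ
    occ$unit <- occ$abstract_id
  } else {
    occ <- index$sentence_occ
    occ$unit <- paste(occ$abstract_id, occ$sentence_index, sep = "\r")
  }
  unique(occ$unit[occ$entity_kind == kind & occ$entity_id == id])
}

semantic_units <- function(index, id_a, kind_a, id_b, kind_b) {
  ln <- index$semantic_links
  ka <- paste(kind_a, id_a); kb <- paste(kind_b, id_b)
  if (ka > kb) {
    tmp <- id_a; id_a <- id_b; id_b <- tmp
    tmp <- kind_a; kind_a <- kind_b; kind_b <- tmp
  }
  sel <- ln$kind_a == kind_a & ln$id_a == id_a &
    ln$kind_b == kind_b & ln$id_b == id_b
  unique(paste(ln$abstract_id[sel], ln$sentence_index[sel], sep = "\r"))
}

#' Joint and individual occurrence counts for an entity pair
#'
#' Counts at one of the three text levels. At the abstract level, shared and
#' individual abstract ids are counted; at the sentence level, shared and
#' individual (abstract, sentence) units. At the semantic level the joint
#' count is the number of sentence units in which the pair is linked by a cue
#' phrase, while the individual counts are taken from the sentence level
#' (semantic links are a subset of sentence co-occurrences, so a
#' relation-level "individual appearance" does not exist).
#'
#' @param index A `litnet_index`.
#' @param a,b Entity ids (gene symbols or GO ids).
#' @param level `"abstract"`, `"sentence"` or `"semantic"`.
#' @param kind_a,kind_b Entity kinds (`"gene"` or `"go_term"`).
#' @return A one-row tibble with columns `c` (joint), `n_a`, `n_b`. Unknown
#'   entities count 0.
#' @export
level_counts <- function(index, a, b,
                         level = c("abstract", "sentence", "semantic"),
                         kind_a = "gene", kind_b = "gene") {
  level <- match.arg(level)
  base <- if (level == "abstract") "abstract" else "sentence"
  ua <- entity_units(index, a, kind_a, base)
  ub <- entity_units(index, b, kind_b, base)
  joint <- if (level == "semantic") {
    length(semantic_units(index, a, kind_a, b, kind_b))
  } else {
    length(intersect(ua, ub))
  }
  tibble::tibble(c = joint, n_a = length(ua), n_b = length(ub))
}

feature_ratio <- function(c, n_a, n_b, normalization = "jaccard") {
  denom <- switch(normalization,
                  jaccard = n_a + n_b - c,
                  min = pmin(n_a, n_b),
                  product = n_a * n_b,
                  abort(paste0("unknown feature normalization: ", normalization)))
  out <- ifelse(denom > 0, c / denom, 0)
  out
}

# GO-composite occurrence units of a gene: units where >= 1 of its GO ids occurs
composite_units <- function(index, gene, annotations, level) {
  ids <- unique(annotations$go_id[annotations$symbol == gene])
  if (!length(ids)) return(character(0))
  if (level == "abstract") {
    occ <- index$abstract_occ
    unit <- occ$abstract_id
  } else {
    occ <- index$sentence_occ
    unit <- paste(occ$abstract_id, occ$sentence_index, sep = "\r")
  }
  unique(unit[occ$entity_kind == "go_term" & occ$entity_id %in% ids])
}

composite_semantic_units <- function(index, gene, other, annotations) {
  ids <- unique(annotations$go_id[annotations$symbol == other])
  if (!length(ids)) return(character(0))
  ln <- index$semantic_links
  sel <- (ln$kind_a == "gene" & ln$id_a == gene &
            ln$kind_b == "go_term" & ln$id_b %in% ids) |
    (ln$kind_b == "gene" & ln$id_b == gene &
       ln$kind_a == "go_term" & ln$id_a %in% ids)
  unique(paste(ln$abstract_id[sel], ln$sentence_index[sel], sep = "\r"))
}

#' Nine co-occurrence features for one gene pair
#'
#' Computes the feature vector `W1..W9` for a pair of genes. `W1`-`W3` relate
#' the two gene symbols at the abstract, sentence and semantic level; `W4`-`W6`
#' relate gene 1 to the GO terms of gene 2 (the GO terms collapse into one
#' composite entity that occurs in a unit when at least one of them does);
#' `W7`-`W9` relate gene 2 to the GO terms of gene 1. Each feature is the
#' joint count over the configured normalization of the individual counts
#' (default Jaccard, `c / (n_a + n_b - c)`), defined as 0 when the
#' denominator is 0, hence always in `[0, 1]`.
#'
#' @param index A `litnet_index`.
#' @param g1,g2 Gene symbols; both must carry at least one GO annotation.
#' @param annotations GO annotation tibble (`symbol`, `go_id`, `go_name`).
#' @param normalization `"jaccard"` (default), `"min"` or `"product"`.
#' @return A one-row tibble `g1, g2, W1..W9`.
#' @export
pair_features <- function(index, g1, g2, annotations,
                          normalization = "jaccard") {
  for (g in c(g1, g2)) {
    if (!any(annotations$symbol == g)) {
      abort(paste0("gene has no GO annotation: ", g))
    }
  }
  gene_abs <- lapply(setNames(c(g1, g2), c(g1, g2)),
                     function(g) entity_units(index, g, "gene", "abstract"))
  gene_sent <- lapply(setNames(c(g1, g2), c(g1, g2)),
                      function(g) entity_units(index, g, "gene", "sentence"))
  comp_abs <- lapply(setNames(c(g1, g2), c(g1, g2)),
                     function(g) composite_units(index, g, annotations, "abstract"))
  comp_sent <- lapply(setNames(c(g1, g2), c(g1, g2)),
                      function(g) composite_units(index, g, annotations, "sentence"))

  jac <- function(c, na, nb) feature_ratio(c, na, nb, normalization)
  w1 <- jac(length(intersect(gene_abs[[g1]], gene_abs[[g2]])),
            length(gene_abs[[g1]]), length(gene_abs[[g2]]))
  w2 <- jac(length(intersect(gene_sent[[g1]], gene_sent[[g2]])),
            length(gene_sent[[g1]]), length(gene_sent[[g2]]))
  w3 <- jac(length(semantic_units(index, g1, "gene", g2, "gene")),
            length(gene_sent[[g1]]), length(gene_sent[[g2]]))
  cross <- function(x, y) {
    c(jac(length(intersect(gene_abs[[x]], comp_abs[[y]])),
          length(gene_abs[[x]]), length(comp_abs[[y]])),
      jac(length(intersect(gene_sent[[x]], comp_sent[[y]])),
          length(gene_sent[[x]]), length(comp_sent[[y]])),
      jac(length(composite_semantic_units(index, x, y, annotations)),
          length(gene_sent[[x]]), length(comp_sent[[y]])))
  }
  w456 <- cross(g1, g2)
  w789 <- cross(g2, g1)
  out <- tibble::tibble(g1 = g1, g2 = g2)
  vals <- c(w1, w2, w3, w456, w789)
  for (k in 1:9) out[[paste0("W", k)]] <- vals[k]
  out
}

feature_cols <- function() paste0("W", 1:9)

#' Feature table for all co-occurring gene pairs
#'
#' Vectorized computation of [pair_features()] over every unordered pair of
#' eligible genes that shares at least one abstract-level unit (directly or
#' through a GO composite). Pairs whose nine features are all zero are
#' dropped by default.
#'
#' @param index A `litnet_index`.
#' @param genes Character vector of eligible gene symbols (see
#'   [eligible_genes()]); genes without GO annotations are dropped with a
#'   message.
#' @param annotations GO annotation tibble.
#' @param normalization Feature normalization, see [pair_features()].
#' @param drop_zero Drop all-zero rows (default `TRUE`). With `FALSE`, every
#'   unordered pair of `genes` gets a row.
#' @return A tibble with columns `g1 < g2` (lexicographic) and `W1..W9`,
#'   ordered by `g1` then `g2`.
#' @export
all_pair_features <- function(index, genes, annotations,
                              normalization = "jaccard", drop_zero = TRUE) {
  genes <- unique(genes)
  annotated <- genes %in% unique(annotations$symbol)
  if (any(!annotated)) {
    inform(paste0("dropping ", sum(!annotated), " unannotated gene(s)"))
    genes <- genes[annotated]
  }
  ann <- annotations[annotations$symbol %in% genes, c("symbol", "go_id")]
  ann <- dplyr::distinct(ann)

  occ_tbl <- function(level) {
    if (level == "abstract") {
      occ <- index$abstract_occ
      occ$unit <- occ$abstract_id
    } else {
      occ <- index$sentence_occ
      occ$unit <- paste(occ$abstract_id, occ$sentence_index, sep = "\r")
    }
    occ
  }
  # per-gene occurrence units for the gene entity and its GO composite
  layer <- function(level) {
    occ <- occ_tbl(level)
    gu <- dplyr::distinct(tibble::tibble(
      gene = occ$entity_id[occ$entity_kind == "gene"],
      unit = occ$unit[occ$entity_kind == "gene"]))
    gu <- gu[gu$gene %in% genes, ]
    go_occ <- occ[occ$entity_kind == "go_term", c("entity_id", "unit")]
    cu <- dplyr::inner_join(go_occ, ann, by = c(entity_id = "go_id"),
                            relationship = "many-to-many")
    cu <- dplyr::distinct(tibble::tibble(gene = cu$symbol, unit = cu$unit))
    list(gene = gu, comp = cu,
         n_gene = table_count(gu$gene), n_comp = table_count(cu$gene))
  }
  abs_l <- layer("abstract")
  sent_l <- layer("sentence")

  pair_join <- function(u1, u2, ordered = FALSE) {
    j <- dplyr::inner_join(u1, u2, by = "unit",
                           relationship = "many-to-many",
                           suffix = c("_1", "_2"))
    j <- j[j$gene_1 != j$gene_2, ]
    if (!ordered) j <- j[j$gene_1 < j$gene_2, ]
    dplyr::count(j, .data$gene_1, .data$gene_2, name = "c")
  }
  gg_abs <- pair_join(abs_l$gene, abs_l$gene)
  gg_sent <- pair_join(sent_l$gene, sent_l$gene)
  gc_abs <- pair_join(abs_l$gene, abs_l$comp, ordered = TRUE)
  gc_sent <- pair_join(sent_l$gene, sent_l$comp, ordered = TRUE)

  # semantic joint counts
  ln <- index$semantic_links
  ln$unit <- paste(ln$abstract_id, ln$sentence_index, sep = "\r")
  gg_ln <- ln[ln$kind_a == "gene" & ln$kind_b == "gene" &
                ln$id_a %in% genes & ln$id_b %in% genes, ]
  gg_sem <- dplyr::count(
    dplyr::distinct(tibble::tibble(gene_1 = gg_ln$id_a, gene_2 = gg_ln$id_b,
                                   unit = gg_ln$unit)),
    .data$gene_1, .data$gene_2, name = "c")
  gt_ln <- dplyr::bind_rows(
    tibble::tibble(gene = ln$id_a[ln$kind_a == "gene" & ln$kind_b == "go_term"],
                   go_id = ln$id_b[ln$kind_a == "gene" & ln$kind_b == "go_term"],
                   unit = ln$unit[ln$kind_a == "gene" & ln$kind_b == "go_term"]),
    tibble::tibble(gene = ln$id_b[ln$kind_b == "gene" & ln$kind_a == "go_term"],
                   go_id = ln$id_a[ln$kind_b == "gene" & ln$kind_a == "go_term"],
                   unit = ln$unit[ln$kind_b == "gene" & ln$kind_a == "go_term"]))
  gt_ln <- gt_ln[gt_ln$gene %in% genes, ]
  gc_sem <- dplyr::inner_join(gt_ln, ann, by = "go_id",
                              relationship = "many-to-many")
  gc_sem <- gc_sem[gc_sem$gene != gc_sem$symbol, ]
  gc_sem <- dplyr::count(
    dplyr::distinct(tibble::tibble(gene_1 = gc_sem$gene, gene_2 = gc_sem$symbol,
                                   unit = gc_sem$unit)),
    .data$gene_1, .data$gene_2, name = "c")

  # candidate pairs: any abstract-level sharing, direct or via a composite
  pairs <- dplyr::bind_rows(
    gg_abs[c("gene_1", "gene_2")],
    canonical_pairs(gc_abs$gene_1, gc_abs$gene_2))
  pairs <- dplyr::distinct(pairs)
  if (!drop_zero) {
    if (length(genes) >= 2L) {
      gs <- sort(genes)
      cmb <- utils::combn(gs, 2L)
      pairs <- tibble::tibble(gene_1 = cmb[1L, ], gene_2 = cmb[2L, ])
    } else {
      pairs <- tibble::tibble(gene_1 = character(), gene_2 = character())
    }
  }
  if (!nrow(pairs)) {
    out <- tibble::tibble(g1 = character(), g2 = character())
    for (k in feature_cols()) out[[k]] <- numeric(0)
    return(out)
  }
  pairs <- dplyr::arrange(pairs, .data$gene_1, .data$gene_2)

  lk_pair <- function(tbl, a, b) {
    key <- paste(tbl$gene_1, tbl$gene_2, sep = "\r")
    v <- tbl$c[match(paste(a, b, sep = "\r"), key)]
    ifelse(is.na(v), 0L, v)
  }
  cnt <- function(tab, g) {
    v <- tab[g]
    ifelse(is.na(v), 0L, v)
  }
  a <- pairs$gene_1; b <- pairs$gene_2
  na_ga <- cnt(abs_l$n_gene, a); nb_ga <- cnt(abs_l$n_gene, b)
  na_gs <- cnt(sent_l$n_gene, a); nb_gs <- cnt(sent_l$n_gene, b)
  na_ca <- cnt(abs_l$n_comp, a); nb_ca <- cnt(abs_l$n_comp, b)
  na_cs <- cnt(sent_l$n_comp, a); nb_cs <- cnt(sent_l$n_comp, b)

  fr <- function(c, na, nb) feature_ratio(c, na, nb, normalization)
  out <- tibble::tibble(g1 = a, g2 = b)
  out$W1 <- fr(lk_pair(gg_abs, a, b), na_ga, nb_ga)
  out$W2 <- fr(lk_pair(gg_sent, a, b), na_gs, nb_gs)
  out$W3 <- fr(lk_pair(gg_sem, a, b), na_gs, nb_gs)
  out$W4 <- fr(lk_pair(gc_abs, a, b), na_ga, nb_ca)
  out$W5 <- fr(lk_pair(gc_sent, a, b), na_gs, nb_cs)
  out$W6 <- fr(lk_pair(gc_sem, a, b), na_gs, nb_cs)
  out$W7 <- fr(lk_pair(gc_abs, b, a), nb_ga, na_ca)
  out$W8 <- fr(lk_pair(gc_sent, b, a), nb_gs, na_cs)
  out$W9 <- fr(lk_pair(gc_sem, b, a), nb_gs, na_cs)
  if (drop_zero) {
    keep <- rowSums(as.matrix(out[feature_cols()])) > 0
    out <- out[keep, ]
  }
  out
}

table_count <- function(x) {
  if (!length(x)) return(setNames(integer(0), character(0)))
  tab <- table(x)
  setNames(as.integer(tab), names(tab))
}

canonical_pairs <- function(a, b) {
  tibble::tibble(gene_1 = pmin(a, b), gene_2 = pmax(a, b))
}

#' Write / read a pair feature table
#'
#' TSV with header `g1 g2 W1..W9`.
#'
#' @param features Feature tibble from [all_pair_features()].
#' @param path File path.
#' @return `read_pair_features()` returns the tibble; `write_pair_features()`
#'   returns `path` invisibly.
#' @export
write_pair_features <- function(features, path) {
  readr::write_tsv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pair_features
#' @export
read_pair_features <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    g1 = "c", g2 = "c", .default = "d"), progress = FALSE)
}
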