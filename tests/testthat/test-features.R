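make_index <- function(tc = tiny_corpus()) {
  mentions <- find_mentions(tc$abstracts, tc$lexicon, tc$annotations)
  list(tc = tc, mentions = mentions,
       index = build_occurrence_index(mentions, tc$abstracts))
}

test_that("semantic links require a cue strictly between the two mentions", {
  ab <- tibble::tibble(
    id = c("A1", "A2", "A3"),
    title = c("T", "T", "T"),
    body = c("TP53 binds with BRCA2 today",
             "TP53 arrived. BRCA2 arrived.",
             "TP53 was studied; BRCA2 and MDM2 rose"))
  lex <- c("TP53", "BRCA2", "MDM2")
  m <- find_mentions(ab, lex, NULL)
  idx <- build_occurrence_index(m, ab)
  ln <- idx$semantic_links
  key <- paste(ln$id_a, ln$id_b, ln$abstract_id)

  # cue between the pair -> link, recorded with sorted entity keys
  expect_true("BRCA2 TP53 A1" %in% key)
  # co-abstract but different sentences -> no link, only abstract overlap
  expect_false(any(ln$abstract_id == "A2"))
  expect_equal(level_counts(idx, "TP53", "BRCA2", "abstract")$c, 3L)
  # "and" links only the flanked pair, not the distant one
  expect_true("BRCA2 MDM2 A3" %in% key)
  expect_false("MDM2 TP53 A3" %in% key)
  expect_false("BRCA2 TP53 A3" %in% key)
})

test_that("level counts match hand counts and handle unknown entities", {
  mi <- make_index()
  idx <- mi$index
  # TP53 in A1+A2 (title of A1 counts), BRCA2 in A1+A2
  expect_equal(level_counts(idx, "TP53", "BRCA2", "abstract"),
               tibble::tibble(c = 2L, n_a = 2L, n_b = 2L))
  lc <- level_counts(idx, "GHOST", "BRCA2", "sentence")
  expect_equal(lc$c, 0L)
  expect_equal(lc$n_a, 0L)
  expect_gt(lc$n_b, 0L)
  # semantic joint counts are bounded by sentence joint counts
  for (pair in list(c("TP53", "BRCA2"), c("BRCA2", "MDM2"))) {
    cs <- level_counts(idx, pair[1], pair[2], "semantic")$c
    cj <- level_counts(idx, pair[1], pair[2], "sentence")$c
    expect_lte(cs, cj)
  }
})

test_that("pair features match hand-computed Jaccard ratios", {
  ab <- tibble::tibble(id = c("A1", "A2", "A3"),
                       title = c("X", "Y", "Z"),
                       body = c("GALPHA near GBETA done",
                                "GALPHA alone",
                                "Nothing"))
  ann <- tibble::tibble(symbol = c("GALPHA", "GBETA"),
                        go_id = c("GO:0000010", "GO:0000020"),
                        go_name = c("term one", "term two"))
  m <- find_mentions(ab, c("GALPHA", "GBETA"), ann)
  idx <- build_occurrence_index(m, ab)
  pf <- pair_features(idx, "GALPHA", "GBETA", ann)
  # g1 in 2 abstracts, g2 in 1, shared 1 -> 1/(2+1-1)
  expect_equal(pf$W1, 0.5)
  # no GO mentions and no cues -> remaining features 0
  expect_equal(unlist(pf[paste0("W", 3:9)], use.names = FALSE), rep(0, 7))
  expect_error(pair_features(idx, "GALPHA", "GHOST", ann), "GHOST")
})

test_that("swapping the pair exchanges W4-6 with W7-9 and W1-3 are symmetric", {
  mi <- make_index()
  a <- pair_features(mi$index, "TP53", "BRCA2", mi$tc$annotations)
  b <- pair_features(mi$index, "BRCA2", "TP53", mi$tc$annotations)
  expect_equal(unlist(a[c("W1", "W2", "W3")], use.names = FALSE),
               unlist(b[c("W1", "W2", "W3")], use.names = FALSE))
  expect_equal(unlist(a[c("W4", "W5", "W6")], use.names = FALSE),
               unlist(b[c("W7", "W8", "W9")], use.names = FALSE))
  expect_equal(unlist(a[c("W7", "W8", "W9")], use.names = FALSE),
               unlist(b[c("W4", "W5", "W6")], use.names = FALSE))
})

test_that("features equal the brute-force recount on small corpora", {
  mi <- make_index()
  tc <- mi$tc
  genes <- eligible_genes(tc$lexicon, tc$annotations, quiet = TRUE)
  tbl <- all_pair_features(mi$index, genes, tc$annotations)
  expect_true(all(tbl$g1 < tbl$g2))
  for (r in seq_len(nrow(tbl))) {
    w_oracle <- oracle_pair_features(tc$abstracts, tc$lexicon, tc$annotations,
                                     tbl$g1[r], tbl$g2[r])
    expect_equal(unlist(tbl[r, paste0("W", 1:9)], use.names = FALSE),
                 unname(w_oracle), tolerance = 1e-12)
    # the per-pair path agrees with the vectorized table
    pf <- pair_features(mi$index, tbl$g1[r], tbl$g2[r], tc$annotations)
    expect_equal(as.data.frame(pf), as.data.frame(tbl[r, names(pf)]),
                 ignore_attr = TRUE)
  }
  expect_true(all(as.matrix(tbl[paste0("W", 1:9)]) >= 0))
  expect_true(all(as.matrix(tbl[paste0("W", 1:9)]) <= 1))
})

test_that("feature table agrees with brute force on simulated mini-corpora", {
  for (seed in 1:3) {
    sim <- simulate_corpus(n_genes = 6, go_terms_per_gene = 2, n_abstracts = 5,
                           sentences_per_abstract = 3, edge_prob = 0.3,
                           module_size = 0, n_module_seeds = 0,
                           p_cooccur_pos = 0.6,
                           p_cooccur_neg = 0.1, p_go_mention = 0.6,
                           seed = seed)
    m <- find_mentions(sim$abstracts, sim$lexicon, sim$annotations)
    idx <- build_occurrence_index(m, sim$abstracts)
    genes <- sim$lexicon$symbol
    tbl <- all_pair_features(idx, genes, sim$annotations)
    for (r in seq_len(nrow(tbl))) {
      w_oracle <- oracle_pair_features(sim$abstracts, sim$lexicon,
                                       sim$annotations, tbl$g1[r], tbl$g2[r])
      expect_equal(unlist(tbl[r, paste0("W", 1:9)], use.names = FALSE),
                   unname(w_oracle), tolerance = 1e-12)
    }
    # drop_zero = FALSE scores every unordered pair
    full <- all_pair_features(idx, genes, sim$annotations, drop_zero = FALSE)
    expect_equal(nrow(full), choose(length(genes), 2))
  }
})

test_that("adding a joint-sentence abstract never decreases W1 or W2", {
  tc <- tiny_corpus()
  run <- function(abstracts) {
    m <- find_mentions(abstracts, tc$lexicon, tc$annotations)
    idx <- build_occurrence_index(m, abstracts)
    pair_features(idx, "BRCA2", "TP53", tc$annotations)
  }
  before <- run(tc$abstracts)
  extra <- tibble::tibble(id = "A9", title = "Joint",
                          body = "TP53 and BRCA2 interact in cells.")
  after <- run(dplyr::bind_rows(tc$abstracts, extra))
  expect_gte(after$W1, before$W1)
  expect_gte(after$W2, before$W2)
})

test_that("feature tables round-trip through TSV", {
  mi <- make_index()
  tbl <- all_pair_features(mi$index,
                           eligible_genes(mi$tc$lexicon, mi$tc$annotations,
                                          quiet = TRUE),
                           mi$tc$annotations)
  tf <- withr::local_tempfile()
  write_pair_features(tbl, tf)
  expect_equal(as.data.frame(read_pair_features(tf)), as.data.frame(tbl))
})

test_that("alternative normalizations stay within [0, 1]", {
  mi <- make_index()
  genes <- eligible_genes(mi$tc$lexicon, mi$tc$annotations, quiet = TRUE)
  for (norm in c("jaccard", "min", "product")) {
    tbl <- all_pair_features(mi$index, genes, mi$tc$annotations,
                             normalization = norm)
    vals <- as.matrix(tbl[paste0("W", 1:9)])
    expect_true(all(vals >= 0 & vals <= 1), info = norm)
  }
  expect_error(pair_features(mi$index, "TP53", "BRCA2", mi$tc$annotations,
                             normalization = "bogus"), "normalization")
})
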