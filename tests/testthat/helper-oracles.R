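`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: naive loops, generic optimizers, closed forms.

# tiny two-gene / two-GO corpus used in several corpus/feature tests
tiny_corpus <- function() {
  list(
    abstracts = tibble::tibble(
      id = c("A1", "A2", "A3"),
      title = c("A TP53 study", "Another report", "Unrelated work"),
      body = c("TP53 interacts with BRCA2 via cell division. BRCA2 was seen.",
               "TP53 alone here. BRCA2 and MDM2 rose.",
               "Nothing relevant.")),
    lexicon = as_gene_lexicon(c("TP53", "BRCA2", "MDM2")),
    annotations = tibble::tibble(
      symbol = c("TP53", "BRCA2", "MDM2"),
      go_id = c("GO:0000001", "GO:0000002", "GO:0000003"),
      go_name = c("apoptosis regulation", "cell division", "protein binding")))
}

# brute-force recount of the nine features from raw mentions (set semantics),
# independent of the occurrence-index join machinery
oracle_pair_features <- function(abstracts, lexicon, annotations, g1, g2,
                                 cues = default_cues()) {
  mentions <- find_mentions(abstracts, as_gene_lexicon(lexicon), annotations)
  units_of <- function(kind, ids, level) {
    sel <- mentions$entity_kind == kind & mentions$entity_id %in% ids
    if (level == "abstract") {
      unique(mentions$abstract_id[sel])
    } else {
      unique(paste(mentions$abstract_id[sel], mentions$sentence_index[sel]))
    }
  }
  cue_hit <- function(between) {
    between <- tolower(between)
    any(vapply(cues, function(cu) {
      grepl(paste0("(?<![a-z0-9])", cu, "(?![a-z0-9])"), between, perl = TRUE)
    }, logical(1)))
  }
  sem_units <- function(kind_a, ids_a, kind_b, ids_b) {
    out <- character(0)
    for (r in seq_len(nrow(abstracts))) {
      aid <- abstracts$id[r]
      text <- ifelse(nzchar(abstracts$body[r]),
                     paste(abstracts$title[r], abstracts$body[r], sep = "\n"),
                     abstracts$title[r])
      ms <- mentions[mentions$abstract_id == aid, ]
      for (s in unique(ms$sentence_index)) {
        mm <- ms[ms$sentence_index == s, ]
        hit <- FALSE
        for (i in seq_len(nrow(mm))) {
          for (j in seq_len(nrow(mm))) {
            if (i == j) next
            if (!(mm$entity_kind[i] == kind_a && mm$entity_id[i] %in% ids_a)) next
            if (!(mm$entity_kind[j] == kind_b && mm$entity_id[j] %in% ids_b)) next
            if (mm$entity_kind[i] == mm$entity_kind[j] &&
                mm$entity_id[i] == mm$entity_id[j]) next
            lo <- min(mm$end[i], mm$end[j])
            hi <- max(mm$start[i], mm$start[j])
            if (lo > hi) next
            others <- setdiff(seq_len(nrow(mm)), c(i, j))
            if (any(mm$start[others] < hi & mm$end[others] > lo)) next
            if (cue_hit(substr(text, lo + 1L, hi))) hit <- TRUE
          }
        }
        if (hit) out <- c(out, paste(aid, s))
      }
    }
    unique(out)
  }
  jac <- function(cc, na, nb) if (na + nb - cc > 0) cc / (na + nb - cc) else 0
  go1 <- annotations$go_id[annotations$symbol == g1]
  go2 <- annotations$go_id[annotations$symbol == g2]
  w <- numeric(9)
  for (level in c("abstract", "sentence")) {
    ua1 <- units_of("gene", g1, level); ua2 <- units_of("gene", g2, level)
    uc1 <- units_of("go_term", go1, level); uc2 <- units_of("go_term", go2, level)
    k <- if (level == "abstract") 0L else 1L
    w[1 + k] <- jac(length(intersect(ua1, ua2)), length(ua1), length(ua2))
    w[4 + k] <- jac(length(intersect(ua1, uc2)), length(ua1), length(uc2))
    w[7 + k] <- jac(length(intersect(ua2, uc1)), length(ua2), length(uc1))
  }
  us1 <- units_of("gene", g1, "sentence"); us2 <- units_of("gene", g2, "sentence")
  uc1 <- units_of("go_term", go1, "sentence")
  uc2 <- units_of("go_term", go2, "sentence")
  w[3] <- jac(length(sem_units("gene", g1, "gene", g2)),
              length(us1), length(us2))
  w[6] <- jac(length(sem_units("gene", g1, "go_term", go2)),
              length(us1), length(uc2))
  w[9] <- jac(length(sem_units("gene", g2, "go_term", go1)),
              length(us2), length(uc1))
  setNames(w, paste0("W", 1:9))
}

# independently coded weighted ridge logistic objective, maximized with optim
oracle_ridge_logistic <- function(x, y, w, lambda) {
  x <- as.matrix(x)
  X <- cbind(1, x)
  negobj <- function(b) {
    eta <- drop(X %*% b)
    ll <- sum(w * (y * eta - ifelse(eta > 30, eta, log1p(exp(eta)))))
    -(ll - lambda / 2 * sum(b[-1]^2))
  }
  neggrad <- function(b) {
    p <- 1 / (1 + exp(-drop(X %*% b)))
    -(drop(crossprod(X, w * (y - p))) - lambda * c(0, b[-1]))
  }
  o <- optim(rep(0, ncol(X)), negobj, neggrad, method = "BFGS",
             control = list(maxit = 5000, reltol = 1e-15))
  o$par
}

# pairwise concordance AUC oracle (ties count one half)
oracle_auc <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# exhaustive threshold-sweep PR oracle at the distinct score cutoffs
oracle_pr <- function(p, y) {
  th <- sort(unique(p), decreasing = TRUE)
  recall <- precision <- numeric(length(th))
  for (i in seq_along(th)) {
    pred <- p >= th[i]
    recall[i] <- sum(pred & y == 1) / sum(y == 1)
    precision[i] <- sum(pred & y == 1) / sum(pred)
  }
  tibble::tibble(recall = c(0, recall), precision = c(1, precision))
}

canonical_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# run the full text pipeline on a simulated corpus; returns feature table with
# true labels attached
sim_pipeline_features <- function(sim) {
  mentions <- find_mentions(sim$abstracts, sim$lexicon, sim$annotations)
  index <- build_occurrence_index(mentions, sim$abstracts)
  genes <- eligible_genes(sim$lexicon, sim$annotations, quiet = TRUE)
  feats <- all_pair_features(index, genes, sim$annotations)
  truth <- canonical_key(sim$true_edges$g1, sim$true_edges$g2)
  feats$label <- as.integer(canonical_key(feats$g1, feats$g2) %in% truth)
  feats
}
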