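#' Read a corpus of abstracts
#'
#' Reads abstract records from either a headerless three-column TSV
#' (`id<TAB>title<TAB>body`, UTF-8) or a MEDLINE-like plain-text file in which
#' records are separated by blank lines and carry `PMID-`, `TI  -` and
#' `AB  -` prefixed lines (continuation lines are indented).
#'
#' @param path Path to the corpus file.
#' @param format `"tsv"` (default) or `"medline"`.
#' @return A tibble with columns `id`, `title`, `body`, one row per abstract,
#'   input order preserved.
#' @details Duplicate ids and malformed rows are errors; the error message
#'   names the offending id or line number. `body` may be empty.
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines("A1\tTP53 study\tTP53 binds MDM2.", tf)
#' read_abstracts(tf)
read_abstracts <- function(path, format = c("tsv", "medline")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("corpus file does not exist: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- if (format == "tsv") {
    parse_abstract_tsv(lines)
  } else {
    parse_medline(lines)
  }
  dup <- recs$id[duplicated(recs$id)]
  if (length(dup)) {
    abort(paste0("duplicate abstract id(s): ", paste(unique(dup), collapse = ", ")))
  }
  recs
}

parse_abstract_tsv <- function(lines) {
  if (!length(lines)) {
    return(tibble::tibble(id = character(), title = character(), body = character()))
  }
  ntab <- lengths(gregexpr("\t", lines, fixed = TRUE))
  ntab[!grepl("\t", lines, fixed = TRUE)] <- 0L
  bad <- which(ntab != 2L)
  if (length(bad)) {
    abort(paste0("malformed corpus row at line ", bad[1],
                 ": expected 3 tab-separated fields, found ", ntab[bad[1]] + 1L))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    length(f) <- 3L
    f[is.na(f)] <- ""
    f
  })
  m <- do.call(rbind, fields)
  out <- tibble::tibble(id = m[, 1], title = m[, 2], body = m[, 3])
  if (any(out$id == "")) {
    abort(paste0("empty abstract id at line ", which(out$id == "")[1]))
  }
  out
}

parse_medline <- function(lines) {
  lines <- c(lines, "")
  blank <- grepl("^\\s*$", lines)
  block_id <- cumsum(c(TRUE, diff(blank) == -1L))
  block_id[blank] <- NA_integer_
  ids <- titles <- bodies <- character(0)
  for (b in split(lines[!blank], block_id[!blank])) {
    rec <- c(PMID = "", TI = "", AB = "")
    tag <- NA_character_
    for (ln in b) {
      m <- regmatches(ln, regexec("^([A-Z]+)\\s*- ?(.*)$", ln))[[1]]
      if (length(m)) {
        tag <- m[2]
        val <- m[3]
        if (tag %in% names(rec)) {
          rec[tag] <- if (nzchar(rec[tag])) paste(rec[tag], val) else val
        }
      } else if (!is.na(tag) && grepl("^\\s+", ln) && tag %in% names(rec)) {
        rec[tag] <- paste(rec[tag], trimws(ln))
      }
    }
    if (!nzchar(rec[["PMID"]])) {
      abort("MEDLINE record without a PMID field")
    }
    ids <- c(ids, rec[["PMID"]])
    titles <- c(titles, rec[["TI"]])
    bodies <- c(bodies, rec[["AB"]])
  }
  tibble::tibble(id = ids, title = titles, body = bodies)
}

#' Write a corpus back to TSV
#'
#' Inverse of [read_abstracts()] for the TSV dialect; round-trips exactly.
#'
#' @param abstracts Tibble with columns `id`, `title`, `body`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abstracts <- function(abstracts, path) {
  stopifnot(all(c("id", "title", "body") %in% names(abstracts)))
  writeLines(paste(abstracts$id, abstracts$title, abstracts$body, sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene lexicon
#'
#' One official gene symbol per line. Matching downstream is case-sensitive
#' exact-token matching of the symbol itself; additional surface forms
#' (synonyms) can be added to the returned tibble as extra rows, but none are
#' generated by default.
#'
#' @param path Path to the symbol list.
#' @return A tibble with columns `symbol` and `surface` (default: the symbol).
#' @export
read_gene_lexicon <- function(path) {
  syms <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  syms <- syms[nzchar(syms)]
  if (anyDuplicated(syms)) {
    syms <- unique(syms)
  }
  as_gene_lexicon(syms)
}

#' Coerce a character vector of symbols to a lexicon tibble
#'
#' @param symbols Character vector of gene symbols, or an existing lexicon
#'   tibble with columns `symbol`, `surface`.
#' @return A tibble with columns `symbol`, `surface`.
#' @export
as_gene_lexicon <- function(symbols) {
  if (is.data.frame(symbols)) {
    stopifnot(all(c("symbol", "surface") %in% names(symbols)))
    return(tibble::as_tibble(symbols[c("symbol", "surface")]))
  }
  stopifnot(is.character(symbols), !any(is.na(symbols)), all(nzchar(symbols)))
  tibble::tibble(symbol = symbols, surface = symbols)
}

#' Read gene-to-GO annotations
#'
#' Headerless TSV with columns `gene<TAB>GO_id<TAB>term_name` (a minimal
#' GAF-inspired dialect). When a lexicon is supplied, rows whose gene symbol
#' is absent from it are skipped with a warning.
#'
#' @param path Path to the annotation table.
#' @param lexicon Optional lexicon (see [as_gene_lexicon()]) used to validate
#'   gene symbols.
#' @return A tibble with columns `symbol`, `go_id`, `go_name`.
#' @export
read_go_annotations <- function(path, lexicon = NULL) {
  tbl <- readr::read_tsv(path, col_names = c("symbol", "go_id", "go_name"),
                         col_types = "ccc", progress = FALSE)
  if (!is.null(lexicon)) {
    lexicon <- as_gene_lexicon(lexicon)
    unknown <- setdiff(tbl$symbol, lexicon$symbol)
    if (length(unknown)) {
      warn(paste0("skipping annotation rows for symbols absent from the lexicon: ",
                  paste(unique(unknown), collapse = ", ")))
      tbl <- tbl[tbl$symbol %in% lexicon$symbol, ]
    }
  }
  dplyr::distinct(tbl)
}

#' Genes eligible for feature extraction
#'
#' A gene takes part in pair-feature extraction only if it carries at least
#' one GO annotation (the GO-composite features are undefined otherwise).
#' Unannotated lexicon genes are reported and excluded.
#'
#' @param lexicon Lexicon (see [as_gene_lexicon()]).
#' @param annotations Annotation tibble from [read_go_annotations()].
#' @param quiet Suppress the report of excluded genes.
#' @return Character vector of eligible gene symbols (lexicon order).
#' @export
eligible_genes <- function(lexicon, annotations, quiet = FALSE) {
  lexicon <- as_gene_lexicon(lexicon)
  syms <- unique(lexicon$symbol)
  annotated <- syms %in% unique(annotations$symbol)
  if (any(!annotated) && !quiet) {
    inform(paste0("excluding ", sum(!annotated),
                  " gene(s) with no GO annotation: ",
                  paste(syms[!annotated], collapse = ", ")))
  }
  syms[annotated]
}

#' Default sentence-boundary abbreviation guard
#'
#' Tokens (including their trailing period) after which a period is not
#' treated as a sentence terminator.
#'
#' @return Character vector of guarded abbreviations.
#' @export
default_abbreviations <- function() {
  c("E.", "S.", "i.e.", "e.g.", "cf.", "vs.", "ca.", "al.", "et.",
    "Fig.", "Figs.", "Dr.", "St.", "No.", "approx.")
}

#' Split a text into sentence spans
#'
#' A sentence boundary is a run of `.`, `!` or `?` followed by whitespace and
#' an uppercase letter or digit, unless the token ending at the terminator is
#' in the abbreviation guard list. Spans are 0-based half-open character
#' ranges, trimmed of surrounding whitespace, non-overlapping and ordered;
#' together they cover all non-whitespace text.
#'
#' @param text A single character string.
#' @param abbreviations Guard list, see [default_abbreviations()].
#' @return A tibble with columns `index` (0-based), `start`, `end`.
#' @export
#' @examples
#' split_sentences("A binds B. C grows.")
split_sentences <- function(text, abbreviations = default_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  n <- nchar(text)
  cut_after <- integer(0)
  m <- gregexpr("[.!?]+(?=[ \t\r\n]+[A-Z0-9])", text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    starts <- as.integer(m)
    ends <- starts + attr(m, "match.length") - 1L
    guarded <- vapply(seq_along(starts), function(i) {
      tok <- sub(".*[ \t\r\n(\\[]", "", substr(text, 1L, ends[i]))
      tok %in% abbreviations
    }, logical(1))
    cut_after <- ends[!guarded]
  }
  seg_start <- c(1L, cut_after + 1L)
  seg_end <- c(cut_after, n)
  out_start <- integer(0)
  out_end <- integer(0)
  for (k in seq_along(seg_start)) {
    seg <- substr(text, seg_start[k], seg_end[k])
    first_nw <- regexpr("[^ \t\r\n]", seg)
    if (first_nw == -1L) next
    last_nw <- nchar(sub("[ \t\r\n]+$", "", seg))
    out_start <- c(out_start, seg_start[k] + first_nw - 1L)
    out_end <- c(out_end, seg_start[k] + last_nw - 1L)
  }
  tibble::tibble(index = seq_along(out_start) - 1L,
                 start = out_start - 1L,
                 end = out_end)
}

# One abstract-level text unit: title and body joined by a newline separator.
# The title is sentence 0; body sentences follow. Offsets index the joined text.
abstract_text <- function(title, body) {
  ifelse(nzchar(body), paste(title, body, sep = "\n"), title)
}

#' Sentence spans of an abstract
#'
#' The abstract is treated as one text unit: `title` and `body` joined with a
#' newline. The whole title is sentence 0 (when non-empty); body sentences
#' follow with consecutive indices.
#'
#' @param title,body Title and body strings.
#' @param abbreviations Guard list for [split_sentences()].
#' @return A tibble with columns `index`, `start`, `end` (0-based half-open
#'   offsets into the joined text).
#' @export
abstract_sentences <- function(title, body,
                               abbreviations = default_abbreviations()) {
  spans <- list()
  offset <- 0L
  idx0 <- 0L
  tt <- split_sentences(title, abbreviations)
  if (nrow(tt)) {
    # title is a single sentence regardless of internal punctuation
    spans[[1]] <- tibble::tibble(index = 0L, start = min(tt$start),
                                 end = max(tt$end))
    idx0 <- 1L
  }
  if (nzchar(body)) {
    offset <- nchar(title) + 1L
    bb <- split_sentences(body, abbreviations)
    if (nrow(bb)) {
      bb$start <- bb$start + offset
      bb$end <- bb$end + offset
      bb$index <- bb$index + idx0
      spans[[length(spans) + 1L]] <- bb
    }
  }
  if (!length(spans)) {
    return(tibble::tibble(index = integer(), start = integer(), end = integer()))
  }
  dplyr::bind_rows(spans)
}

# ---- dictionary matcher -----------------------------------------------------

tokenize_positions <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1L) {
    return(list(token = character(0), start = integer(0), end = integer(0)))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  list(token = substring(text, start, start + len - 1L),
       start = start - 1L,            # 0-based
       end = start + len - 1L)        # 0-based half-open
}

# Compile gene + GO dictionaries into a first-token hash. Gene surfaces match
# case-sensitively; GO term names (and literal GO ids) case-insensitively.
compile_dictionary <- function(lexicon, annotations) {
  lexicon <- as_gene_lexicon(lexicon)
  entries <- list()
  add <- function(key, tokens, kind, id, ci) {
    entries[[length(entries) + 1L]] <<-
      list(key = key, tokens = tokens, kind = kind, id = id, ci = ci)
  }
  for (i in seq_len(nrow(lexicon))) {
    toks <- tokenize_positions(lexicon$surface[i])$token
    if (!length(toks)) next
    add(toks[1], toks, "gene", lexicon$symbol[i], FALSE)
  }
  if (!is.null(annotations) && nrow(annotations)) {
    terms <- dplyr::distinct(annotations[c("go_id", "go_name")])
    for (i in seq_len(nrow(terms))) {
      toks <- tolower(tokenize_positions(terms$go_name[i])$token)
      if (length(toks)) {
        add(paste0("\tci:", toks[1]), toks, "go_term", terms$go_id[i], TRUE)
      }
      idtoks <- tolower(tokenize_positions(terms$go_id[i])$token)
      if (length(idtoks)) {
        add(paste0("\tci:", idtoks[1]), idtoks, "go_term", terms$go_id[i], TRUE)
      }
    }
  }
  env <- new.env(parent = emptyenv(), size = max(16L, 2L * length(entries)))
  for (e in entries) {
    cur <- if (exists(e$key, envir = env, inherits = FALSE)) {
      get(e$key, envir = env)
    } else list()
    cur[[length(cur) + 1L]] <- e
    assign(e$key, cur, envir = env)
  }
  # deterministic candidate order: longer phrases first, genes before GO terms,
  # then by entity id -- independent of lexicon row order
  for (k in ls(env)) {
    cand <- get(k, envir = env)
    ord <- order(-vapply(cand, function(e) length(e$tokens), integer(1)),
                 vapply(cand, function(e) e$kind, character(1)),
                 vapply(cand, function(e) e$id, character(1)))
    assign(k, cand[ord], envir = env)
  }
  env
}

match_entities_text <- function(text, dict) {
  tk <- tokenize_positions(text)
  ntok <- length(tk$token)
  lower <- tolower(tk$token)
  kind <- character(0); id <- character(0); s0 <- integer(0); e0 <- integer(0)
  i <- 1L
  while (i <= ntok) {
    cands <- list()
    if (exists(tk$token[i], envir = dict, inherits = FALSE)) {
      cands <- get(tk$token[i], envir = dict)
    }
    key_ci <- paste0("\tci:", lower[i])
    if (exists(key_ci, envir = dict, inherits = FALSE)) {
      cands <- c(cands, get(key_ci, envir = dict))
    }
    if (length(cands) > 1L) {
      ord <- order(-vapply(cands, function(e) length(e$tokens), integer(1)),
                   vapply(cands, function(e) e$kind, character(1)),
                   vapply(cands, function(e) e$id, character(1)))
      cands <- cands[ord]
    }
    hit <- NULL
    for (e in cands) {
      L <- length(e$tokens)
      if (i + L - 1L > ntok) next
      seg <- if (e$ci) lower[i:(i + L - 1L)] else tk$token[i:(i + L - 1L)]
      if (identical(seg, e$tokens)) { hit <- e; break }
    }
    if (!is.null(hit)) {
      L <- length(hit$tokens)
      kind <- c(kind, hit$kind)
      id <- c(id, hit$id)
      s0 <- c(s0, tk$start[i])
      e0 <- c(e0, tk$end[i + L - 1L])
      i <- i + L
    } else {
      i <- i + 1L
    }
  }
  tibble::tibble(entity_kind = kind, entity_id = id, start = s0, end = e0)
}

#' Find gene and GO-term mentions in abstracts
#'
#' Dictionary named-entity recognition over the joined title+body text of each
#' abstract. Tokens are maximal alphanumeric runs; gene symbols match
#' case-sensitively, GO term names (and literal GO ids) case-insensitively.
#' At each position the longest matching phrase wins, scanning left to right;
#' a token belongs to at most one mention. Each mention is assigned the
#' sentence span that contains it.
#'
#' @param abstracts Tibble with columns `id`, `title`, `body` (one or more
#'   rows), as returned by [read_abstracts()].
#' @param lexicon Gene lexicon (see [as_gene_lexicon()]).
#' @param annotations GO annotation tibble (`symbol`, `go_id`, `go_name`);
#'   `NULL` to search for genes only.
#' @param abbreviations Sentence-boundary guard list.
#' @return A tibble with columns `abstract_id`, `entity_kind`
#'   (`"gene"`/`"go_term"`), `entity_id`, `sentence_index`, `start`, `end`
#'   (0-based half-open offsets into the joined title+body text).
#' @export
#' @examples
#' ab <- tibble::tibble(id = "A1", title = "A study",
#'                      body = "TP53 interacts with BRCA2.")
#' find_mentions(ab, c("TP53", "BRCA2"))
find_mentions <- function(abstracts, lexicon, annotations = NULL,
                          abbreviations = default_abbreviations()) {
  stopifnot(all(c("id", "title", "body") %in% names(abstracts)))
  dict <- compile_dictionary(lexicon, annotations)
  out <- vector("list", nrow(abstracts))
  for (r in seq_len(nrow(abstracts))) {
    text <- abstract_text(abstracts$title[r], abstracts$body[r])
    hits <- match_entities_text(text, dict)
    if (!nrow(hits)) next
    spans <- abstract_sentences(abstracts$title[r], abstracts$body[r],
                                abbreviations)
    sidx <- rep(NA_integer_, nrow(hits))
    if (nrow(spans)) {
      j <- findInterval(hits$start, spans$start)
      ok <- j >= 1L & hits$start >= spans$start[pmax(j, 1L)] &
        hits$end <= spans$end[pmax(j, 1L)]
      sidx[ok] <- spans$index[j[ok]]
    }
    keep <- !is.na(sidx)
    if (!any(keep)) next
    out[[r]] <- tibble::tibble(abstract_id = abstracts$id[r],
                               entity_kind = hits$entity_kind[keep],
                               entity_id = hits$entity_id[keep],
                               sentence_index = sidx[keep],
                               start = hits$start[keep],
                               end = hits$end[keep])
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(abstract_id = character(), entity_kind = character(),
                          entity_id = character(), sentence_index = integer(),
                          start = integer(), end = integer())
  }
  res
}
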