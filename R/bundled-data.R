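#' OMIM-derived cancer seed-gene lists
#'
#' Curated seed genes for three cancers (18 prostate, 23 breast, 16 lung),
#' as retrieved from the OMIM gene/phenotype map. These anchor disease
#' subnetwork extraction and seed-recall evaluation.
#'
#' @param disease `"prostate"`, `"breast"`, `"lung"`, or `"all"` (default)
#'   for the full table.
#' @return A tibble with columns `disease`, `symbol`.
#' @export
#' @examples
#' nrow(cancer_seed_genes("breast"))
cancer_seed_genes <- function(disease = c("all", "prostate", "breast", "lung")) {
  disease <- match.arg(disease)
  path <- system.file("extdata", "omim_seed_genes.tsv", package = "litnet",
                      mustWork = TRUE)
  tbl <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (disease != "all") tbl <- tbl[tbl$disease == disease, ]
  tbl
}

#' Published top-30 breast-cancer prediction list with validation flags
#'
#' A worked validation example: 30 top-ranked breast-cancer candidate genes
#' from a large-corpus run of this pipeline, each flagged `YES` (validated
#' by the MalaCards / NCI-GDC benchmarks), `YES+Seed` (validated and an OMIM
#' seed), `Seed` (seed only) or `candidate` (novel, unvalidated), alongside
#' the top-30 list of a competing literature-mining method for overlap
#' comparison. Summarize with [summarize_validation()].
#'
#' @return A tibble with columns `rank`, `symbol`, `status`,
#'   `comparison_symbol`.
#' @export
breast_validation_table <- function() {
  path <- system.file("extdata", "breast_top30_validation.tsv",
                      package = "litnet", mustWork = TRUE)
  readr::read_tsv(path, col_types = "iccc", progress = FALSE)
}
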