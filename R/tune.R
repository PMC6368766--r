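#' Default hyperparameter grids and reference presets
#'
#' `default_lambda_grid()` is log-spaced over `1e-4 ... 1e4` (13 points);
#' `default_sigma_grid()` is `{0.25, 0.5, 1, 2, 4}`.
#' `preset_hyperparameters()` returns reference values obtained from a
#' large-corpus fit of the same models (WLR: `lambda = 4328`; WKLR:
#' `lambda = 5.7e-3`, `sigma = 0.5`); they are documented starting points,
#' not tuned values for your data.
#'
#' @return Numeric vectors, or a list of two lists for the presets.
#' @export
default_lambda_grid <- function() 10^seq(-4, 4, length.out = 13)

#' @rdname default_lambda_grid
#' @export
default_sigma_grid <- function() c(0.25, 0.5, 1, 2, 4)

#' @rdname default_lambda_grid
#' @export
preset_hyperparameters <- function() {
  list(wlr = list(lambda = 4328),
       wklr = list(lambda = 5.7e-3, sigma = 0.5))
}

balanced_accuracy <- function(y, yhat) {
  sens <- mean(yhat[y == 1] == 1)
  spec <- mean(yhat[y == 0] == 0)
  (sens + spec) / 2
}

stratified_resample <- function(y) {
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  c(sample(idx1, length(idx1), replace = TRUE),
    sample(idx0, length(idx0), replace = TRUE))
}

#' Bootstrap tuning of lambda (and sigma)
#'
#' For every grid point, fits the classifier on `B` bootstrap resamples
#' (drawn with replacement, stratified by class, shared across grid points)
#' and scores balanced accuracy on the out-of-bag rows at threshold 0.5. The
#' best point maximizes the mean out-of-bag score; ties are broken toward the
#' larger `lambda`, then the larger `sigma` (more shrinkage / smoother
#' kernel). Resamples whose out-of-bag set lacks a class are redrawn (at most
#' 100 times each).
#'
#' @inheritParams fit_wlr
#' @param model `"wlr"` or `"wklr"`.
#' @param lambda_grid,sigma_grid Candidate values (`sigma_grid` is ignored
#'   for `"wlr"`).
#' @param B Number of bootstrap rounds, `>= 1`.
#' @param seed Optional integer seed; the result is reproducible under a
#'   fixed seed.
#' @return An object of class `litnet_tune`: list with `grid` (tibble of
#'   `lambda`, `sigma`, `mean_score`), `best` (one-row tibble), `B`, `seed`,
#'   `model`.
#' @export
bootstrap_tune <- function(data, outcome = "label", features = NULL,
                           model = c("wlr", "wklr"),
                           lambda_grid = default_lambda_grid(),
                           sigma_grid = default_sigma_grid(),
                           B = 100L, tau = NULL, seed = NULL) {
  model <- match.arg(model)
  stopifnot(B >= 1L, length(lambda_grid) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  xy <- resolve_xy(data, outcome, features)
  y <- xy$y
  if (length(unique(y)) < 2L) abort("both classes must be present")
  df <- as.data.frame(xy$x)
  df[[outcome]] <- y

  resamples <- vector("list", B)
  for (b in seq_len(B)) {
    for (try in seq_len(100L)) {
      idx <- stratified_resample(y)
      oob <- setdiff(seq_along(y), unique(idx))
      if (length(unique(y[oob])) == 2L) break
      idx <- NULL
    }
    if (is.null(idx)) {
      abort("could not draw a bootstrap resample with both classes out-of-bag")
    }
    resamples[[b]] <- list(inbag = idx, oob = oob)
  }

  grid <- if (model == "wlr") {
    tibble::tibble(lambda = as.numeric(lambda_grid), sigma = NA_real_)
  } else {
    tidyr::expand_grid(lambda = as.numeric(lambda_grid),
                       sigma = as.numeric(sigma_grid))
  }
  grid$mean_score <- NA_real_
  for (g in seq_len(nrow(grid))) {
    scores <- vapply(resamples, function(rs) {
      train <- df[rs$inbag, , drop = FALSE]
      test <- df[rs$oob, , drop = FALSE]
      fit <- tryCatch({
        if (model == "wlr") {
          fit_wlr(train, outcome = outcome, features = xy$features,
                  tau = tau, lambda = grid$lambda[g])
        } else {
          fit_wklr(train, outcome = outcome, features = xy$features,
                   tau = tau, lambda = grid$lambda[g], sigma = grid$sigma[g])
        }
      }, error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      yhat <- predict(fit, test, type = "class", threshold = 0.5)
      balanced_accuracy(y[rs$oob], yhat)
    }, numeric(1))
    grid$mean_score[g] <- mean(scores, na.rm = TRUE)
  }
  ord <- order(-grid$mean_score, -grid$lambda,
               -ifelse(is.na(grid$sigma), 0, grid$sigma))
  best <- grid[ord[1], ]
  structure(list(grid = grid, best = best, B = B, seed = seed, model = model),
            class = "litnet_tune")
}

#' @export
print.litnet_tune <- function(x, ...) {
  cat("<bootstrap tuning result (", x$model, ", B = ", x$B, ")>\n", sep = "")
  cat("  best: lambda =", format(x$best$lambda),
      if (!is.na(x$best$sigma)) paste(" sigma =", format(x$best$sigma)),
      " mean OOB balanced accuracy =", round(x$best$mean_score, 4), "\n")
  invisible(x)
}

#' Threshold persistence of predicted pairs
#'
#' For each pair, the highest threshold in an ascending list at which the
#' pair is still predicted positive (probability strictly greater than the
#' threshold); `NA` when the pair is positive at no threshold. Pairs that
#' persist at high thresholds signal the strongest predicted relations.
#'
#' @param pairs Data frame with a probability column (and typically `g1`,
#'   `g2`).
#' @param thresholds Ascending thresholds in (0, 1); default
#'   `c(0.5, 0.6, 0.7, 0.8)`.
#' @param prob_col Name of the probability column.
#' @return `pairs` with an added `persistence` column.
#' @export
threshold_persistence <- function(pairs, thresholds = c(0.5, 0.6, 0.7, 0.8),
                                  prob_col = "prob") {
  stopifnot(is.data.frame(pairs), prob_col %in% names(pairs),
            all(thresholds > 0), all(thresholds < 1),
            !is.unsorted(thresholds, strictly = TRUE))
  p <- pairs[[prob_col]]
  pers <- vapply(p, function(pi) {
    ok <- thresholds[pi > thresholds]
    if (length(ok)) max(ok) else NA_real_
  }, numeric(1))
  out <- tibble::as_tibble(pairs)
  out$persistence <- pers
  out
}

#' Gene-level threshold persistence
#'
#' The persistence of a gene is the maximum persistence over its incident
#' pairs.
#'
#' @param pairs Output of [threshold_persistence()] with columns `g1`, `g2`,
#'   `persistence`.
#' @return A tibble `gene`, `persistence`, sorted by decreasing persistence
#'   then gene symbol.
#' @export
gene_persistence <- function(pairs) {
  stopifnot(all(c("g1", "g2", "persistence") %in% names(pairs)))
  long <- tibble::tibble(gene = c(pairs$g1, pairs$g2),
                         persistence = rep(pairs$persistence, 2L))
  out <- dplyr::summarise(dplyr::group_by(long, .data$gene),
                          persistence = if (all(is.na(.data$persistence))) {
                            NA_real_
                          } else {
                            max(.data$persistence, na.rm = TRUE)
                          },
                          .groups = "drop")
  dplyr::arrange(out, dplyr::desc(.data$persistence), .data$gene)
}

# ---- model text serialization ----------------------------------------------

#' Write / read a fitted model as self-describing text
#'
#' Plain-text model files carrying the model kind, hyperparameters,
#' coefficient (or dual) vector and, for WKLR, the stored training feature
#' rows plus a checksum.
#'
#' @param model A `litnet_wlr` or `litnet_wklr` fit.
#' @param path File path.
#' @return `read_model()` returns the fit object; `write_model()` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  if (inherits(model, "litnet_wlr")) {
    writeLines(c("kind: wlr",
                 paste0("lambda: ", fmt(model$lambda)),
                 paste0("features: ", paste(model$features, collapse = "\t")),
                 "beta:"), con)
    writeLines(paste(names(model$beta), fmt(model$beta), sep = "\t"), con)
  } else if (inherits(model, "litnet_wklr")) {
    writeLines(c("kind: wklr",
                 paste0("lambda: ", fmt(model$lambda)),
                 paste0("sigma: ", fmt(model$sigma)),
                 paste0("features: ", paste(model$features, collapse = "\t")),
                 paste0("train_checksum: ", fmt(sum(model$train_x))),
                 "alpha:"), con)
    writeLines(fmt(model$alpha), con)
    writeLines("train_x:", con)
    writeLines(apply(model$train_x, 1L, function(r)
      paste(fmt(r), collapse = "\t")), con)
  } else {
    abort("write_model() expects a litnet_wlr or litnet_wklr fit")
  }
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  field <- function(key) {
    ln <- grep(paste0("^", key, ": "), lines, value = TRUE)[1]
    sub(paste0("^", key, ": "), "", ln)
  }
  kind <- field("kind")
  features <- strsplit(field("features"), "\t", fixed = TRUE)[[1]]
  if (kind == "wlr") {
    i <- which(lines == "beta:")
    rows <- strsplit(lines[(i + 1L):length(lines)], "\t", fixed = TRUE)
    beta <- vapply(rows, function(r) as.numeric(r[2]), numeric(1))
    names(beta) <- vapply(rows, `[`, character(1), 1L)
    structure(list(beta = beta, lambda = as.numeric(field("lambda")),
                   converged = NA, iterations = NA_integer_,
                   loglik = NA_real_, features = features, weights = NULL,
                   n = NA_integer_),
              class = "litnet_wlr")
  } else if (kind == "wklr") {
    ia <- which(lines == "alpha:")
    ix <- which(lines == "train_x:")
    alpha <- as.numeric(lines[(ia + 1L):(ix - 1L)])
    xr <- strsplit(lines[(ix + 1L):length(lines)], "\t", fixed = TRUE)
    train_x <- do.call(rbind, lapply(xr, as.numeric))
    colnames(train_x) <- features
    chk <- as.numeric(field("train_checksum"))
    if (abs(sum(train_x) - chk) > 1e-6 * max(1, abs(chk))) {
      abort("training-feature checksum mismatch in model file")
    }
    structure(list(alpha = alpha, sigma = as.numeric(field("sigma")),
                   lambda = as.numeric(field("lambda")), train_x = train_x,
                   converged = NA, iterations = NA_integer_,
                   loglik = NA_real_, features = features, weights = NULL,
                   n = nrow(train_x)),
              class = "litnet_wklr")
  } else {
    abort(paste0("unknown model kind in file: ", kind))
  }
}
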