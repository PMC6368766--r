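#' Tidiers for fitted classifiers and tuning results
#'
#' broom-style accessors: `tidy()` returns per-term (or per-grid-point)
#' tibbles, `glance()` one-row model summaries.
#'
#' @param x A `litnet_wlr`, `litnet_wklr` or `litnet_tune` object.
#' @param ... Unused.
#' @return A tibble.
#' @name litnet-tidiers
NULL

#' @rdname litnet-tidiers
#' @export
tidy.litnet_wlr <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @rdname litnet-tidiers
#' @export
glance.litnet_wlr <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, loglik = x$loglik,
                 converged = x$converged, iterations = x$iterations, n = x$n)
}

#' @rdname litnet-tidiers
#' @export
tidy.litnet_wklr <- function(x, ...) {
  tibble::tibble(row = seq_along(x$alpha), alpha = x$alpha)
}

#' @rdname litnet-tidiers
#' @export
glance.litnet_wklr <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, sigma = x$sigma, loglik = x$loglik,
                 converged = x$converged, iterations = x$iterations, n = x$n)
}

#' @rdname litnet-tidiers
#' @export
tidy.litnet_tune <- function(x, ...) x$grid

#' @rdname litnet-tidiers
#' @export
glance.litnet_tune <- function(x, ...) {
  tibble::tibble(model = x$model, B = x$B,
                 best_lambda = x$best$lambda, best_sigma = x$best$sigma,
                 best_score = x$best$mean_score)
}
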