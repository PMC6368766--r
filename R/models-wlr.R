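#' Rare-event case weights
#'
#' Per-row weights for weighted (kernel) logistic regression. With a known
#' population event fraction `tau`, the prior-correction weights are
#' `tau / ybar` for events and `(1 - tau) / (1 - ybar)` for non-events
#' (`ybar` = sample event fraction). Without `tau`, balanced weights
#' `n / (2 n1)` and `n / (2 n0)` are used. Weights are rescaled to sum to `n`
#' so that the effective sample size is unchanged.
#'
#' @param y Binary 0/1 label vector containing both classes.
#' @param tau Optional assumed population event fraction in (0, 1).
#' @return Numeric weight vector of length `length(y)`, with attributes
#'   `tau` and `event_weight` / `nonevent_weight`.
#' @export
#' @examples
#' compute_weights(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0))
compute_weights <- function(y, tau = NULL) {
  y <- check_labels(y)
  n <- length(y)
  n1 <- sum(y == 1)
  n0 <- n - n1
  if (n1 == 0L || n0 == 0L) {
    abort("both classes must be present to compute case weights")
  }
  if (is.null(tau)) {
    w1 <- n / (2 * n1)
    w0 <- n / (2 * n0)
  } else {
    stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0, tau < 1)
    ybar <- n1 / n
    w1 <- tau / ybar
    w0 <- (1 - tau) / (1 - ybar)
  }
  w <- ifelse(y == 1, w1, w0)
  w <- w * n / sum(w)
  structure(w, tau = tau,
            event_weight = w[match(1, y)],
            nonevent_weight = w[match(0, y)])
}

check_labels <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    abort("labels must be binary 0/1 with no missing values")
  }
  y
}

# numerically stable log(1 + exp(eta))
log1pexp <- function(eta) {
  out <- numeric(length(eta))
  big <- eta > 30
  out[big] <- eta[big] + log1p(exp(-eta[big]))
  out[!big] <- log1p(exp(eta[!big]))
  out
}

# design matrix with intercept column from a feature matrix
add_intercept <- function(x) {
  cbind("(Intercept)" = 1, x)
}

#' Weighted ridge-penalized logistic log-likelihood and gradient
#'
#' The objective maximized by [fit_wlr()]:
#' `sum_i w_i * (y_i * eta_i - log(1 + exp(eta_i))) - lambda/2 * ||beta_slopes||^2`
#' with `eta = cbind(1, x) %*% beta` and the intercept excluded from the
#' penalty. The gradient is `t(X) %*% (w * (y - p)) - lambda * beta_tilde`
#' where `beta_tilde` zeroes the intercept slot.
#'
#' @param beta Coefficient vector, intercept first (length `ncol(x) + 1`).
#' @param x Feature matrix (no intercept column).
#' @param y Binary labels.
#' @param w Case weights (default all 1).
#' @param lambda Ridge penalty, `>= 0`.
#' @return `wlr_loglik()` a scalar; `wlr_gradient()` a vector of
#'   `length(beta)`.
#' @export
wlr_loglik <- function(beta, x, y, w = rep(1, length(y)), lambda = 0) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) abort("non-finite feature values")
  eta <- drop(add_intercept(x) %*% beta)
  pen <- lambda / 2 * sum(beta[-1]^2)
  sum(w * (y * eta - log1pexp(eta))) - pen
}

#' @rdname wlr_loglik
#' @export
wlr_gradient <- function(beta, x, y, w = rep(1, length(y)), lambda = 0) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) abort("non-finite feature values")
  X <- add_intercept(x)
  p <- plogis(drop(X %*% beta))
  g <- drop(crossprod(X, w * (y - p)))
  g - lambda * c(0, beta[-1])
}

resolve_xy <- function(data, outcome, features) {
  stopifnot(is.data.frame(data))
  if (!outcome %in% names(data)) {
    abort(paste0("outcome column not found: ", outcome))
  }
  y <- check_labels(data[[outcome]])
  if (is.null(features)) {
    numcols <- names(data)[vapply(data, is.numeric, logical(1))]
    features <- setdiff(numcols, outcome)
  }
  x <- as.matrix(data[features])
  if (!all(is.finite(x))) abort("non-finite feature values")
  storage.mode(x) <- "double"
  list(x = x, y = y, features = features)
}

#' Fit weighted logistic regression (WLR)
#'
#' Maximizes the weighted, ridge-penalized log-likelihood (see
#' [wlr_loglik()]) by Newton-Raphson with step-halving, from a zero start
#' vector. An unpenalized intercept is always included. Convergence is
#' declared when the gradient infinity-norm drops to `tol` (default `1e-8`)
#' or after `max_iter` iterations.
#'
#' @param data Data frame containing the binary outcome column and numeric
#'   feature columns.
#' @param outcome Name of the 0/1 label column (default `"label"`).
#' @param features Character vector of feature column names; default: all
#'   numeric columns except the outcome.
#' @param weights Case weight vector, or `NULL` to compute them with
#'   [compute_weights()] (using `tau`). Pass `rep(1, nrow(data))` for an
#'   unweighted fit.
#' @param tau Optional population event fraction forwarded to
#'   [compute_weights()] when `weights` is `NULL`.
#' @param lambda Ridge penalty `>= 0` on the slope coefficients.
#' @param tol,max_iter Convergence controls.
#' @return An object of class `litnet_wlr` with elements `beta` (named,
#'   intercept first), `lambda`, `converged`, `iterations`, `loglik`,
#'   `features`, `weights`, `n`.
#' @export
fit_wlr <- function(data, outcome = "label", features = NULL, weights = NULL,
                    tau = NULL, lambda = 0, tol = 1e-8, max_iter = 100L) {
  stopifnot(lambda >= 0)
  xy <- resolve_xy(data, outcome, features)
  x <- xy$x; y <- xy$y
  if (length(unique(y)) < 2L) abort("both classes must be present")
  w <- weights %||% compute_weights(y, tau = tau)
  stopifnot(length(w) == length(y), all(w > 0))

  X <- add_intercept(x)
  d <- ncol(X)
  beta <- numeric(d)
  pen_diag <- c(0, rep(lambda, d - 1L))
  obj <- wlr_loglik(beta, x, y, w, lambda)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    g <- drop(crossprod(X, w * (y - p))) - pen_diag * beta
    if (max(abs(g)) <= tol) { converged <- TRUE; it <- it - 1L; break }
    wpp <- w * p * (1 - p)
    H <- crossprod(X, X * wpp) + diag(pen_diag, d)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      abort(paste0("Hessian numerically singular; the data may be separable ",
                   "-- refit with lambda > 0"))
    }
    # step-halving on the penalized log-likelihood
    t_sh <- 1
    repeat {
      cand <- beta + t_sh * step
      cand_obj <- wlr_loglik(cand, x, y, w, lambda)
      if (cand_obj >= obj - 1e-12 || t_sh < 1e-8) break
      t_sh <- t_sh / 2
    }
    beta <- beta + t_sh * step
    obj <- wlr_loglik(beta, x, y, w, lambda)
    if (max(abs(wlr_gradient(beta, x, y, w, lambda))) <= tol) {
      converged <- TRUE
      break
    }
  }
  if (!all(is.finite(beta)) || max(abs(beta)) > 1e10) {
    abort("WLR coefficients diverged; the data may be separable -- refit with lambda > 0")
  }
  if (lambda == 0) {
    p_fit <- plogis(drop(X %*% beta))
    if (all(abs(y - p_fit) < 1e-6)) {
      abort(paste0("data are perfectly separable at lambda = 0 (all fitted ",
                   "probabilities at their labels); refit with lambda > 0"))
    }
  }
  structure(list(beta = setNames(beta, colnames(X)),
                 lambda = lambda, converged = converged, iterations = it,
                 loglik = obj, features = xy$features, weights = w,
                 n = length(y)),
            class = "litnet_wlr")
}

#' @export
print.litnet_wlr <- function(x, ...) {
  cat("<weighted logistic regression>\n")
  cat("  n =", x$n, " lambda =", format(x$lambda),
      " converged:", x$converged, "(", x$iterations, "iterations )\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Predict interaction probabilities from a WLR fit
#'
#' @param object A `litnet_wlr` fit.
#' @param newdata Data frame containing the training feature columns.
#' @param type `"prob"` (default), `"link"` (the logit), or `"class"`.
#' @param threshold Classification threshold for `type = "class"`; positives
#'   require `p > threshold` (strict), ties go to class 0.
#' @param ... Unused.
#' @return Numeric (or integer for `"class"`) vector.
#' @export
predict.litnet_wlr <- function(object, newdata,
                               type = c("prob", "link", "class"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) {
    abort(paste0("newdata is missing feature column(s): ",
                 paste(miss, collapse = ", ")))
  }
  x <- as.matrix(newdata[object$features])
  storage.mode(x) <- "double"
  eta <- drop(add_intercept(x) %*% object$beta)
  switch(type,
         link = eta,
         prob = plogis(eta),
         class = classify_interactions(plogis(eta), threshold))
}

#' Threshold classification of interaction probabilities
#'
#' A pair is predicted interacting iff its probability strictly exceeds the
#' threshold; probabilities equal to the threshold go to class 0.
#'
#' @param p Probability vector.
#' @param threshold Scalar in (0, 1).
#' @return Integer 0/1 vector.
#' @export
classify_interactions <- function(p, threshold = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  as.integer(p > threshold)
}
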