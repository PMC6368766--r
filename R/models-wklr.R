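#' Gaussian RBF kernel
#'
#' `k(x_i, x_j) = exp(-||x_i - x_j||^2 / (2 sigma^2))`, so `k` is in (0, 1]
#' and equals 1 at zero distance.
#'
#' @param x_i,x_j Numeric feature vectors of equal length.
#' @param sigma Kernel width, `> 0`.
#' @return Scalar kernel value.
#' @export
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), sigma = 1)
rbf_kernel <- function(x_i, x_j, sigma) {
  check_sigma(sigma)
  stopifnot(length(x_i) == length(x_j))
  exp(-sum((x_i - x_j)^2) / (2 * sigma^2))
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    abort("sigma must be a single positive number")
  }
  invisible(sigma)
}

#' RBF kernel matrix
#'
#' Kernel matrix between the rows of `x` and `y` (default `y = x`). For the
#' square training kernel a jitter of `1e-10` is added to the diagonal for
#' numerical conditioning.
#'
#' @param x,y Feature matrices with matching column count.
#' @param sigma Kernel width, `> 0`.
#' @param jitter Diagonal jitter used when `y` is `NULL`.
#' @return `nrow(x) x nrow(y)` kernel matrix.
#' @export
build_kernel_matrix <- function(x, sigma, y = NULL, jitter = 1e-10) {
  check_sigma(sigma)
  x <- as.matrix(x)
  square <- is.null(y)
  y <- if (square) x else as.matrix(y)
  stopifnot(ncol(x) == ncol(y))
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  K <- exp(-d2 / (2 * sigma^2))
  if (square) {
    K <- (K + t(K)) / 2
    diag(K) <- diag(K) + jitter
  }
  K
}

#' Fit weighted kernel logistic regression (WKLR)
#'
#' Maximizes the dual-penalized weighted log-likelihood
#' `sum_i w_i * (y_i * eta_i - log(1 + exp(eta_i))) - lambda/2 * t(alpha) K alpha`
#' with `eta = K alpha` and `K` the RBF kernel matrix of the training
#' features, by damped Newton ascent from a zero start. The training feature
#' rows are stored in the fit for later kernel evaluation against new pairs.
#'
#' @inheritParams fit_wlr
#' @param sigma RBF kernel width, `> 0`.
#' @param lambda Ridge penalty `>= 0` on the dual vector.
#' @param tol Gradient infinity-norm tolerance (default `1e-6`).
#' @param max_iter Iteration cap (default 500).
#' @return An object of class `litnet_wklr` with elements `alpha`, `sigma`,
#'   `lambda`, `train_x`, `converged`, `iterations`, `loglik`, `features`,
#'   `weights`, `n`.
#' @export
fit_wklr <- function(data, outcome = "label", features = NULL, weights = NULL,
                     tau = NULL, lambda = 0, sigma = 1, tol = 1e-6,
                     max_iter = 500L) {
  stopifnot(lambda >= 0)
  check_sigma(sigma)
  xy <- resolve_xy(data, outcome, features)
  x <- xy$x; y <- xy$y
  if (length(unique(y)) < 2L) abort("both classes must be present")
  w <- weights %||% compute_weights(y, tau = tau)
  stopifnot(length(w) == length(y), all(w > 0))

  K <- build_kernel_matrix(x, sigma)
  n <- length(y)
  alpha <- numeric(n)
  objective <- function(a) {
    eta <- drop(K %*% a)
    sum(w * (y * eta - log1pexp(eta))) - lambda / 2 * drop(crossprod(a, K %*% a))
  }
  obj <- objective(alpha)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(K %*% alpha)
    p <- plogis(eta)
    u <- w * (y - p) - lambda * alpha
    grad <- drop(K %*% u)
    if (max(abs(grad)) <= tol) { converged <- TRUE; it <- it - 1L; break }
    # Newton system: (diag(w p (1-p)) K + lambda I) delta = u
    A <- K * (w * p * (1 - p)) + diag(lambda + 1e-12, n)
    step <- tryCatch(solve(A, u), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      abort(paste0("WKLR Newton system is numerically singular; the data may ",
                   "be separable -- refit with lambda > 0"))
    }
    t_sh <- 1
    repeat {
      cand <- alpha + t_sh * step
      if (objective(cand) >= obj - 1e-12 || t_sh < 1e-8) break
      t_sh <- t_sh / 2
    }
    alpha <- alpha + t_sh * step
    obj <- objective(alpha)
    eta <- drop(K %*% alpha)
    p <- plogis(eta)
    if (max(abs(drop(K %*% (w * (y - p) - lambda * alpha)))) <= tol) {
      converged <- TRUE
      break
    }
  }
  if (!all(is.finite(alpha)) || max(abs(alpha)) > 1e10) {
    abort("WKLR dual vector diverged; refit with lambda > 0")
  }
  structure(list(alpha = alpha, sigma = sigma, lambda = lambda,
                 train_x = x, converged = converged, iterations = it,
                 loglik = obj, features = xy$features, weights = w, n = n),
            class = "litnet_wklr")
}

#' @export
print.litnet_wklr <- function(x, ...) {
  cat("<weighted kernel logistic regression (RBF)>\n")
  cat("  n =", x$n, " sigma =", format(x$sigma), " lambda =",
      format(x$lambda), " converged:", x$converged,
      "(", x$iterations, "iterations )\n")
  invisible(x)
}

#' Predict interaction probabilities from a WKLR fit
#'
#' @inheritParams predict.litnet_wlr
#' @param object A `litnet_wklr` fit.
#' @export
predict.litnet_wklr <- function(object, newdata,
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
  Kq <- build_kernel_matrix(x, object$sigma, y = object$train_x)
  eta <- drop(Kq %*% object$alpha)
  switch(type,
         link = eta,
         prob = plogis(eta),
         class = classify_interactions(plogis(eta), threshold))
}
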