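test_that("case weights follow the balanced and prior-correction formulas", {
  y <- c(rep(1, 2), rep(0, 8))
  w <- compute_weights(y)
  expect_equal(unname(w[y == 1][1]), 2.5)
  expect_equal(unname(w[y == 0][1]), 0.625)
  expect_equal(sum(w), 10)

  # balanced classes without tau -> all weights 1
  expect_equal(as.numeric(compute_weights(c(0, 1, 0, 1))), rep(1, 4))
  # tau equal to the sample event rate -> all weights 1 after rescale
  expect_equal(as.numeric(compute_weights(y, tau = 0.2)), rep(1, 10))
  # tau-weighted: events upweighted when tau exceeds the sample rate
  wt <- compute_weights(y, tau = 0.4)
  expect_gt(wt[y == 1][1], wt[y == 0][1])
  expect_equal(sum(wt), 10)
  expect_error(compute_weights(rep(1, 5)), "both classes")
})

test_that("log-likelihood closed forms and gradient identities hold", {
  set.seed(1)
  n <- 40
  x <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, 0.4)
  beta0 <- rep(0, 4)
  expect_equal(wlr_loglik(beta0, x, y), -n * log(2))

  # finite-difference gradient check
  set.seed(2)
  beta <- rnorm(4, sd = 0.5)
  w <- runif(n, 0.5, 2)
  g <- wlr_gradient(beta, x, y, w, lambda = 0.7)
  fd <- vapply(seq_along(beta), function(j) {
    h <- 1e-6
    bp <- beta; bp[j] <- bp[j] + h
    bm <- beta; bm[j] <- bm[j] - h
    (wlr_loglik(bp, x, y, w, 0.7) - wlr_loglik(bm, x, y, w, 0.7)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(g), fd, tolerance = 1e-6)

  # extreme linear predictors stay finite (log1p/exp formulation)
  expect_true(is.finite(wlr_loglik(c(0, 100, 100, 100), x, y)))
})

test_that("fit_wlr matches glm at lambda 0 and the optim oracle at lambda > 0", {
  set.seed(3)
  n <- 250
  x <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(-1 + x %*% c(2, -1, 0.5)))
  df <- data.frame(x, label = y)

  f0 <- fit_wlr(df, weights = rep(1, n), lambda = 0)
  g0 <- stats::glm(label ~ a + b + c, data = df, family = stats::binomial())
  expect_equal(unname(f0$beta), unname(stats::coef(g0)), tolerance = 1e-7)
  expect_true(f0$converged)
  expect_lte(max(abs(wlr_gradient(f0$beta, x, y, rep(1, n), 0))), 1e-6)

  w <- compute_weights(y)
  f1 <- fit_wlr(df, lambda = 2.5)
  b_oracle <- oracle_ridge_logistic(x, y, w, 2.5)
  expect_equal(unname(f1$beta), b_oracle, tolerance = 1e-4)
})

test_that("fit_wlr is deterministic and weight-consistent under row duplication", {
  set.seed(4)
  n <- 120
  x <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, 0.35)
  df <- data.frame(x, label = y)
  f1 <- fit_wlr(df, weights = rep(1, n), lambda = 0)
  f2 <- fit_wlr(rbind(df, df), weights = rep(1, 2 * n), lambda = 0)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  # with a penalty the ridge term must scale with the duplicated likelihood
  f3 <- fit_wlr(df, weights = rep(1, n), lambda = 1.5)
  f4 <- fit_wlr(rbind(df, df), weights = rep(1, 2 * n), lambda = 3)
  expect_equal(f3$beta, f4$beta, tolerance = 1e-9)
  expect_identical(f1$beta, fit_wlr(df, weights = rep(1, n), lambda = 0)$beta)
})

test_that("huge shrinkage drives slopes to zero and the intercept to log-odds", {
  set.seed(5)
  n <- 150
  df <- data.frame(a = runif(n), b = runif(n), label = rbinom(n, 1, 0.3))
  f <- fit_wlr(df, weights = rep(1, n), lambda = 1e9)
  expect_lt(max(abs(f$beta[-1])), 1e-5)
  expect_equal(unname(f$beta[1]), qlogis(mean(df$label)), tolerance = 1e-5)
})

test_that("separable data at lambda 0 raises an advisory error", {
  df <- data.frame(a = c(0, 0.1, 0.9, 1), label = c(0, 0, 1, 1))
  expect_error(fit_wlr(df, weights = rep(1, 4), lambda = 0), "lambda > 0")
  # and succeeds with a positive penalty
  expect_true(fit_wlr(df, weights = rep(1, 4), lambda = 0.5)$converged)
})

test_that("RBF kernel closed forms, PSD and guards", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), sigma = 0.7), 1)
  sg <- 1.3
  x1 <- c(0, 0); x2 <- c(sg, sg)  # distance sg*sqrt(2)
  expect_equal(rbf_kernel(x1, x2, sg), exp(-1))
  expect_error(rbf_kernel(1, 2, -1), "sigma")
  expect_error(build_kernel_matrix(matrix(1), 0), "sigma")

  set.seed(6)
  X <- matrix(runif(45), 5, 9)
  K <- build_kernel_matrix(X, 0.8)
  expect_equal(K, t(K))
  expect_equal(unname(diag(K)), rep(1 + 1e-10, 5))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
})

test_that("fit_wklr matches a black-box optimizer of the same objective", {
  set.seed(7)
  n <- 40
  x <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(-1 + 2 * x[, 1]))
  df <- data.frame(x, label = y)
  w <- compute_weights(y)
  fk <- fit_wklr(df, lambda = 0.3, sigma = 0.8)
  expect_true(fk$converged)
  K <- build_kernel_matrix(x, 0.8)
  negobj <- function(a) {
    eta <- drop(K %*% a)
    -(sum(w * (y * eta - log1p(exp(eta)))) -
        0.3 / 2 * drop(crossprod(a, K %*% a)))
  }
  o <- optim(rep(0, n), negobj, method = "BFGS",
             control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(predict(fk, df), plogis(drop(K %*% o$par)), tolerance = 1e-4)
})

test_that("WKLR label-flip symmetry and kernel-flattening limit", {
  set.seed(8)
  n <- 50
  x <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(2 * x[, 1] - 1))
  df <- data.frame(x, label = y)
  w <- compute_weights(y)
  f1 <- fit_wklr(df, weights = w, lambda = 0.2, sigma = 0.7)
  df_flip <- df; df_flip$label <- 1 - y
  f2 <- fit_wklr(df_flip, weights = w, lambda = 0.2, sigma = 0.7)
  expect_equal(predict(f1, df), 1 - predict(f2, df), tolerance = 1e-8)

  # very wide kernel: constant kernel rows -> intercept-only model rate
  fw <- fit_wklr(df, weights = rep(1, n), lambda = 1e-6, sigma = 1e4)
  expect_equal(unname(predict(fw, df)), rep(mean(y), n), tolerance = 1e-2)
})

test_that("predictions follow the logit closed forms", {
  wlr <- structure(list(beta = c("(Intercept)" = 0, a = 1, b = 0),
                        lambda = 0, converged = TRUE, iterations = 0L,
                        loglik = 0, features = c("a", "b"), weights = NULL,
                        n = 0L), class = "litnet_wlr")
  nd <- data.frame(a = c(0, log(3)), b = c(5, -2))
  expect_equal(predict(wlr, nd), c(0.5, 0.75))
  expect_error(predict(wlr, data.frame(a = 1)), "missing feature")

  # a query equal to a lone training point with alpha = 2 gives plogis(2)
  wklr <- structure(list(alpha = 2, sigma = 1, lambda = 0,
                         train_x = matrix(c(0.3, 0.6), 1, 2,
                                          dimnames = list(NULL, c("a", "b"))),
                         converged = TRUE, iterations = 0L, loglik = 0,
                         features = c("a", "b"), weights = NULL, n = 1L),
                    class = "litnet_wklr")
  expect_equal(predict(wklr, data.frame(a = 0.3, b = 0.6)), plogis(2))
})

test_that("classification is strict at the threshold with ties to class 0", {
  expect_equal(classify_interactions(c(0.5, 0.5001, 0.2), 0.5), c(0L, 1L, 0L))
  expect_equal(classify_interactions(c(0.1, 0.2), 0.5), c(0L, 0L))
  expect_error(classify_interactions(0.5, 1.2), "threshold")
})

test_that("bootstrap tuning is deterministic, tie-broken toward shrinkage", {
  tb <- simulate_feature_table(n_rows = 150, prevalence = 0.2, seed = 5)
  t1 <- bootstrap_tune(tb, lambda_grid = c(0.01, 1), B = 5, seed = 9)
  t2 <- bootstrap_tune(tb, lambda_grid = c(0.01, 1), B = 5, seed = 9)
  expect_identical(t1$grid, t2$grid)
  expect_identical(t1$best, t2$best)
  expect_equal(t1$best$mean_score, max(t1$grid$mean_score))

  single <- bootstrap_tune(tb, lambda_grid = 0.3, B = 3, seed = 1)
  expect_equal(single$best$lambda, 0.3)

  tk <- bootstrap_tune(tb[1:60, ], model = "wklr", lambda_grid = c(0.1),
                       sigma_grid = c(0.5, 2), B = 3, seed = 2)
  expect_equal(nrow(tk$grid), 2L)
})

test_that("noisier data attracts at least as much shrinkage (majority)", {
  bstar <- c(1.5, -2, 1, 0.5, -0.5, 0, 2, -1, 0.25)
  grid <- c(1e-3, 1e-1, 10)
  res <- vapply(1:10, function(s) {
    weak <- simulate_feature_table(n_rows = 200, beta_star = 0.25 * bstar,
                                   prevalence = 0.2, seed = 1000 + s)
    strong <- simulate_feature_table(n_rows = 200, beta_star = 4 * bstar,
                                     prevalence = 0.2, seed = 2000 + s)
    lw <- bootstrap_tune(weak, lambda_grid = grid, B = 10, seed = s)$best$lambda
    ls <- bootstrap_tune(strong, lambda_grid = grid, B = 10, seed = s)$best$lambda
    lw >= ls
  }, logical(1))
  expect_gte(sum(res), 6)
})

test_that("WKLR beats WLR on a nonlinear decision rule (majority of seeds)", {
  wins <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 120
    x <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    y <- rbinom(n, 1, ifelse(xor(x[, 1] > 0.5, x[, 2] > 0.5), 0.95, 0.05))
    if (length(unique(y)) < 2) next
    df <- data.frame(x, label = y)
    fl <- fit_wlr(df, lambda = 0.01)
    fk <- fit_wklr(df, lambda = 0.01, sigma = 0.25)
    al <- auc(roc_curve(data.frame(label = y, prob = predict(fl, df))))
    ak <- auc(roc_curve(data.frame(label = y, prob = predict(fk, df))))
    wins <- wins + (ak >= al)
  }
  expect_gte(wins, 6L)
})

test_that("threshold persistence reports the highest surviving threshold", {
  pairs <- tibble::tibble(g1 = c("A", "A", "B", "C"),
                          g2 = c("B", "C", "C", "D"),
                          prob = c(0.85, 0.55, 0.3, 0.65))
  tp <- threshold_persistence(pairs)
  expect_equal(tp$persistence, c(0.8, 0.5, NA, 0.6))
  # monotone in p over a dense grid
  grid <- seq(0.01, 0.99, by = 0.01)
  pg <- threshold_persistence(tibble::tibble(prob = grid))$persistence
  pg[is.na(pg)] <- 0
  expect_true(!is.unsorted(pg))

  gp <- gene_persistence(tp)
  expect_equal(gp$persistence[gp$gene == "A"], 0.8)
  expect_equal(gp$persistence[gp$gene == "C"], 0.6)
  expect_error(threshold_persistence(pairs, thresholds = c(0.8, 0.5)))
})

test_that("models round-trip through the text serialization", {
  set.seed(10)
  n <- 60
  x <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, 0.4)
  df <- data.frame(x, label = y)
  fl <- fit_wlr(df, lambda = 0.2)
  tf <- withr::local_tempfile()
  write_model(fl, tf)
  fl2 <- read_model(tf)
  expect_equal(fl2$beta, fl$beta)
  expect_equal(predict(fl2, df), predict(fl, df))

  fk <- fit_wklr(df, lambda = 0.2, sigma = 0.6)
  tf2 <- withr::local_tempfile()
  write_model(fk, tf2)
  fk2 <- read_model(tf2)
  expect_equal(predict(fk2, df), predict(fk, df), tolerance = 1e-12)
})

test_that("tidiers expose coefficients and fit summaries", {
  tb <- simulate_feature_table(n_rows = 120, prevalence = 0.2, seed = 3)
  f <- fit_wlr(tb, lambda = 0.1)
  td <- tidy(f)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 10L)
  gl <- glance(f)
  expect_true(gl$converged)
  expect_equal(gl$lambda, 0.1)
})
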