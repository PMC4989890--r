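test_that("lasso on an orthonormal design equals entry-wise soft-thresholding", {
  X <- orthonormal_design(n = 24, J = 5)
  n <- nrow(X)
  set.seed(4)
  y <- X[, 1] * 1.5 - X[, 2] * 0.4 + rnorm(n, sd = 0.3)
  Y <- matrix(y, dimnames = list(rownames(X), "t1"))
  yc <- y - mean(y)
  ols <- crossprod(X, yc) / n          # X'X = nI
  for (lam in c(0.5, 2, 10, 40)) {
    fit <- fit_lasso(X, Y, lam, tol = 1e-12)
    closed <- sign(ols) * pmax(abs(ols) - lam / (2 * n), 0)
    expect_lt(max(abs(fit$beta[, 1] - closed)), 1e-8)
  }
})

test_that("lasso limits: full shrinkage above the zero threshold, OLS at lambda 0", {
  tr <- toy_regression(n = 30, J = 4, K = 2, seed = 8)
  Xc <- sweep(tr$X, 2, colMeans(tr$X))
  Yc <- sweep(tr$Y, 2, colMeans(tr$Y))
  lmax <- 2 * max(abs(crossprod(Xc, Yc)))
  expect_true(all(fit_lasso(tr$X, tr$Y, lmax * (1 + 1e-10))$beta == 0))
  expect_false(all(fit_lasso(tr$X, tr$Y, lmax * 0.9)$beta == 0))
  f0 <- fit_lasso(tr$X, tr$Y, 0, tol = 1e-12)
  ols <- solve(crossprod(Xc), crossprod(Xc, Yc))
  expect_lt(max(abs(f0$beta - ols)), 1e-6)
  expect_error(fit_lasso(tr$X, tr$Y, -1), ">= 0")
})

test_that("lasso agrees with an independent solver on a general design", {
  skip_if_not_installed("glmnet")
  tr <- toy_regression(n = 40, J = 8, K = 1, seed = 15)
  n <- nrow(tr$X)
  lam <- 6
  fit <- fit_lasso(tr$X, tr$Y, lam, tol = 1e-12)
  g <- glmnet::glmnet(tr$X, tr$Y[, 1], lambda = lam / (2 * n),
                      standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(fit$beta[, 1] - as.numeric(g$beta))), 1e-5)
  expect_lt(abs(fit$intercept[1] - g$a0), 1e-5)
})

test_that("reduction identities hold to 1e-5 relative objective gap", {
  tr <- toy_regression(n = 25, J = 6, K = 3, seed = 30)
  X <- tr$X
  Y <- tr$Y
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  lam <- 4
  las <- fit_lasso(X, Y, lam, tol = 1e-10)
  obj_las <- lasso_objective(las$beta, Xc, Yc, lam)
  relgap <- function(beta) {
    abs(lasso_objective(beta, Xc, Yc, lam) - obj_las) / abs(obj_las)
  }
  # GFLasso with gamma = 0 and with an empty edge set
  g0 <- empty_trait_graph(colnames(Y))
  expect_lt(relgap(fit_gflasso(X, Y, g0, lam, 0, tol = 1e-10)$beta), 1e-5)
  expect_lt(relgap(fit_gflasso(X, Y, g0, lam, 5, tol = 1e-10)$beta), 1e-5)
  # SGL alpha = 1 (lasso penalty at the 1/(2n) loss scaling)
  grp <- setNames(rep(1:2, each = 3), colnames(X))
  expect_lt(relgap(fit_sgl(X, Y, grp, lam / (2 * n), 1, tol = 1e-12)$beta), 1e-5)
  # SGL alpha = 0 with singleton groups (norm of a scalar is its magnitude)
  singl <- setNames(seq_len(ncol(X)), colnames(X))
  expect_lt(relgap(fit_sgl(X, Y, singl, lam / (2 * n), 0, tol = 1e-12)$beta), 1e-5)
  # SIOL with group penalties off (1/2 loss scaling)
  H1 <- setNames(rep(1L, ncol(Y)), colnames(Y))
  expect_lt(relgap(fit_siol(X, Y, grp, H1, lam / 2, 0, 0, tol = 1e-12)$beta), 1e-5)
  # SIOL with singleton groups on both sides: penalties add entry-wise
  singH <- setNames(seq_len(ncol(Y)), colnames(Y))
  l1 <- lam / 8
  fs <- fit_siol(X, Y, singl, singH, l1, l1, 2 * l1, tol = 1e-12)
  expect_lt(relgap(fs$beta), 1e-5)
})

test_that("every solver's objective trajectory is non-increasing and beats B = 0", {
  tr <- toy_regression(n = 20, J = 5, K = 2, seed = 44)
  graph <- build_trait_graph(tr$Y, 0.1)
  grp <- setNames(rep(1:2, length.out = 5), colnames(tr$X))
  H <- setNames(rep(1L, 2), colnames(tr$Y))
  fits <- list(
    fit_lasso(tr$X, tr$Y, 3),
    fit_gflasso(tr$X, tr$Y, graph, 3, 1),
    fit_sgl(tr$X, tr$Y, grp, 0.05, 0.3),
    fit_siol(tr$X, tr$Y, grp, H, 1, 0.5, 0.5))
  for (f in fits) {
    for (tr_k in f$diagnostics$trajectory) {
      expect_true(all(diff(tr_k) <= 1e-9))
      expect_lte(tr_k[length(tr_k)], tr_k[1])
    }
  }
})

test_that("solver errors: self-loops, unknown features, bad penalties", {
  tr <- toy_regression(n = 15, J = 4, K = 2, seed = 2)
  bad <- structure(list(edges = data.frame(a = "t01", b = "t01", r = 1, w = 1),
                        threshold = 0.7, trait_ids = colnames(tr$Y)),
                   class = "trait_graph")
  expect_error(fit_gflasso(tr$X, tr$Y, bad, 1, 1), "self-loop")
  expect_error(fit_sgl(tr$X, tr$Y, setNames(1:3, c("f01", "f02", "zz")), 1),
               "unknown|without a group")
  expect_error(fit_sgl(tr$X, tr$Y, setNames(rep(1, 4), colnames(tr$X)), 1,
                       alpha = 1.5), "alpha")
  expect_error(fit_siol(tr$X, tr$Y, setNames(rep(1, 4), colnames(tr$X)),
                        setNames(1:2, colnames(tr$Y)), -1, 0, 0), ">= 0")
})

test_that("cross-validation tracks signal strength and reports its grid", {
  set.seed(61)
  X <- standardize(toy_matrix(36, 5, seed = 61, prefix = "f"))
  # pure noise: the all-zero model should be competitive at the chosen lambda
  Ynoise <- matrix(rnorm(36), dimnames = list(rownames(X), "t1"))
  cv <- select_lambda_cv("lasso", X, Ynoise, folds = 4, seed = 1)
  expect_identical(nrow(cv$table), 30L)
  expect_true(all(is.finite(cv$table$cv_mse)))
  null_mse <- cv$table$cv_mse[1]  # grid starts at lambda_max (all-zero fit)
  expect_lte(min(cv$table$cv_mse), null_mse)
  expect_lt((null_mse - min(cv$table$cv_mse)) / null_mse, 0.15)
  # strong single-feature signal: chosen lambda keeps the feature alive
  Ysig <- matrix(X[, 1] * 3 + rnorm(36, sd = 0.05),
                 dimnames = list(rownames(X), "t1"))
  cv2 <- select_lambda_cv("lasso", X, Ysig, folds = 4, seed = 1)
  fit <- fit_lasso(X, Ysig, cv2$best_lambda)
  expect_true(fit$beta["f01", 1] != 0)
  expect_error(select_lambda_cv("lasso", X, Ysig, folds = 1, seed = 1), "folds")
  expect_error(select_lambda_cv("lasso", X[1:3, ], Ysig[1:3, , drop = FALSE],
                                folds = 5, seed = 1), "fewer samples")
})

test_that("sgl lambda_max is the exact all-zero threshold", {
  tr <- toy_regression(n = 30, J = 6, K = 2, seed = 77)
  grp <- setNames(rep(1:2, each = 3), colnames(tr$X))
  cv <- select_lambda_cv("sgl", tr$X, tr$Y, folds = 3, seed = 2, groups = grp,
                         alpha = 0.1, n_lambda = 4, lambda_min_fraction = 0.8)
  lmax <- cv$table$lambda[1]
  expect_true(all(fit_sgl(tr$X, tr$Y, grp, lmax * 1.001, 0.1)$beta == 0))
  expect_false(all(fit_sgl(tr$X, tr$Y, grp, lmax * 0.97, 0.1,
                           tol = 1e-10)$beta == 0))
})

test_that("gflasso penalty heuristic is median of nonzeros times trait count", {
  B <- matrix(0, 3, 2)
  B[cbind(c(1, 2, 3), c(1, 1, 2))] <- c(0.1, -0.3, 0.5)
  h <- gflasso_lambda_heuristic(B, K = 10)
  expect_equal(h$lambda, 3.0)
  expect_equal(h$gamma, 1)
  h1 <- gflasso_lambda_heuristic(matrix(c(0, 0.2), 1), K = 5)
  expect_equal(h1$lambda, 1.0)
  # randomized check against a sort-based median oracle
  set.seed(9)
  Br <- matrix(rnorm(40) * rbinom(40, 1, 0.4), 8, 5)
  nz <- sort(abs(Br[Br != 0]))
  med <- if (length(nz) %% 2) nz[(length(nz) + 1) / 2] else
    mean(nz[length(nz) / 2 + 0:1])
  expect_equal(gflasso_lambda_heuristic(Br, K = 7)$lambda, med * 7)
  expect_error(gflasso_lambda_heuristic(matrix(0, 2, 2), 3), "all-zero")
})

test_that("mse evaluation matches residual arithmetic", {
  tr <- toy_regression(n = 12, J = 3, K = 2, seed = 3)
  fit <- fit_lasso(tr$X, tr$Y, 0.01, tol = 1e-10)
  self_mse <- evaluate_mse(fit, tr$X, tr$Y)
  pred <- sweep(tr$X %*% fit$beta, 2, fit$intercept, `+`)
  expect_equal(self_mse$per_trait, colMeans((tr$Y - pred)^2), tolerance = 1e-12)
  expect_equal(self_mse$mean, mean(self_mse$per_trait))
  # a perfect linear system evaluates to zero
  fitp <- fit
  fitp$beta <- tr$B
  dimnames(fitp$beta) <- dimnames(fit$beta)
  fitp$intercept <- setNames(rep(0, 2), colnames(tr$Y))
  Yhat <- tr$X %*% tr$B
  dimnames(Yhat) <- dimnames(tr$Y)
  expect_equal(evaluate_mse(fitp, tr$X, Yhat)$mean, 0, tolerance = 1e-20)
  # the zero model on standardized traits gives MSE ~ Var(Y)
  fit0 <- fit
  fit0$beta[] <- 0
  fit0$intercept[] <- colMeans(tr$Y)
  Ys <- standardize(tr$Y)
  fit0$intercept[] <- 0
  expect_equal(evaluate_mse(fit0, tr$X, Ys)$per_trait,
               apply(Ys, 2, function(v) mean(v^2)), tolerance = 1e-12)
  expect_error(evaluate_mse(fit, tr$X[, 1:2], tr$Y), "feature ids|dimension")
})

test_that("support_auc matches a pairwise-comparison oracle", {
  set.seed(99)
  beta <- matrix(rnorm(30) * rbinom(30, 1, 0.6), 6, 5)
  supp <- matrix(rbinom(30, 1, 0.3) == 1, 6, 5)
  supp[1, 1] <- TRUE  # ensure both classes
  supp[2, 1] <- FALSE
  expect_equal(support_auc(beta, supp),
               oracle_auc(abs(as.vector(beta)), as.vector(supp)),
               tolerance = 1e-12)
})
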