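#' @keywords internal
soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' @keywords internal
new_fit <- function(beta, intercept, method, penalty, diagnostics) {
  structure(list(beta = beta, intercept = intercept, method = method,
                 penalty = penalty, diagnostics = diagnostics,
                 sparsity = mean(beta == 0)),
            class = "irnet_fit")
}

#' @export
print.irnet_fit <- function(x, ...) {
  cat("irnet_fit [", x$method, "]: ", nrow(x$beta), " features x ",
      ncol(x$beta), " traits; sparsity ", round(x$sparsity, 3),
      "; converged: ", x$diagnostics$converged, "\n", sep = "")
  invisible(x)
}

# Centre X and Y, run `engine` on the centred problem, restore intercepts.
# Profiling the intercept out by centring is exact for all four objectives.
center_fit <- function(X, Y, engine) {
  Y <- as.matrix(Y)
  check_paired(X, Y)
  xbar <- colMeans(X)
  ybar <- colMeans(Y)
  Xc <- sweep(X, 2, xbar)
  Yc <- sweep(Y, 2, ybar)
  res <- engine(Xc, Yc)
  res$intercept <- setNames(as.numeric(ybar - crossprod(res$beta, xbar)),
                            colnames(Y))
  res
}

# Monotone accelerated proximal-gradient engine (MFISTA) with backtracking
# line search. Candidate steps from the momentum point are only accepted
# when the full objective does not increase; otherwise a plain proximal
# step from the incumbent is tried. Guarantees a non-increasing objective
# trajectory even with an inexact prox. Backtracking starts from `L` (a
# cheap local estimate, e.g. the loss curvature) and doubles until the
# quadratic upper bound holds, so a conservative global Lipschitz constant
# (e.g. from penalty smoothing) never throttles the step size. Convergence
# requires the relative objective change to stay below `tol` for several
# consecutive iterations.
mfista <- function(B0, grad_f, f_smooth, penalty_val, prox, L, tol, maxit) {
  bt_step <- function(point, f_point, g_point) {
    repeat {
      z <- prox(point - g_point / L, 1 / L)
      dz <- z - point
      ub <- f_point + sum(g_point * dz) + (L / 2) * sum(dz^2)
      fz <- f_smooth(z)
      if (fz <= ub + 1e-12 * max(1, abs(ub)) || L > 1e18) {
        return(list(z = z, Fz = fz + penalty_val(z)))
      }
      L <<- L * 2
    }
  }
  x <- B0
  y <- B0
  tk <- 1
  Fx <- f_smooth(x) + penalty_val(x)
  traj <- numeric(maxit + 1)
  traj[1] <- Fx
  converged <- FALSE
  it <- 0
  quiet <- 0
  for (it in seq_len(maxit)) {
    st <- bt_step(y, f_smooth(y), grad_f(y))
    z <- st$z
    if (st$Fz <= Fx) {
      x_new <- z
      F_new <- st$Fz
    } else {
      st2 <- bt_step(x, f_smooth(x), grad_f(x))
      if (st2$Fz <= Fx) {
        x_new <- st2$z
        F_new <- st2$Fz
      } else {
        x_new <- x
        F_new <- Fx
      }
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- x_new + (tk / t_new) * (z - x_new) +
      ((tk - 1) / t_new) * (x_new - x)
    traj[it + 1] <- F_new
    rel <- (Fx - F_new) / max(1, abs(Fx))
    x <- x_new
    Fx <- F_new
    tk <- t_new
    L <- L * 0.95  # allow the step size to grow back between iterations
    quiet <- if (rel < tol) quiet + 1 else 0
    if (quiet >= 5) {
      converged <- TRUE
      break
    }
  }
  list(x = x, trajectory = traj[seq_len(it + 1)], iterations = it,
       converged = converged)
}

#' Fit the L1-penalized (lasso) regression, one trait at a time
#'
#' Minimizes, independently for every trait k,
#' `sum_i (y_ik - b0 - x_i' b_k)^2 + lambda * sum_j |b_jk|`
#' by cyclic coordinate descent with soft-thresholding updates. Coefficients
#' are driven to exact zeros by the threshold operator. The intercept is
#' profiled out by centring and never penalized.
#'
#' @param X Standardized feature matrix (samples x features).
#' @param Y Trait matrix (samples x traits) or vector.
#' @param lambda Nonnegative L1 penalty (on the unscaled squared-error loss).
#' @param tol Relative objective-change convergence tolerance.
#' @param maxit Maximum coordinate-descent sweeps per trait.
#' @param beta_init Optional J x K warm-start matrix.
#' @return An `irnet_fit` with the J x K coefficient matrix, intercepts and
#'   per-trait objective trajectories.
#' @export
fit_lasso <- function(X, Y, lambda, tol = 1e-7, maxit = 10000,
                      beta_init = NULL) {
  if (lambda < 0) stop("lambda must be >= 0")
  Y <- as.matrix(Y)
  res <- center_fit(X, Y, function(Xc, Yc) {
    J <- ncol(Xc)
    K <- ncol(Yc)
    beta <- matrix(0, J, K, dimnames = list(colnames(X), colnames(Y)))
    trajs <- vector("list", K)
    iters <- integer(K)
    conv <- logical(K)
    for (k in seq_len(K)) {
      b0 <- if (is.null(beta_init)) rep(0, J) else beta_init[, k]
      fit <- cd_lasso_cpp(Xc, Yc[, k], lambda, b0, tol, maxit)
      beta[, k] <- fit$beta
      trajs[[k]] <- fit$objective
      iters[k] <- fit$iterations
      conv[k] <- fit$converged
    }
    list(beta = beta, trajs = trajs, iters = iters, conv = conv)
  })
  objective <- sum(vapply(res$trajs, function(tr) tr[length(tr)], 0))
  new_fit(res$beta, res$intercept, "lasso", list(lambda = lambda),
          list(objective = objective, trajectory = res$trajs,
               iterations = max(res$iters), converged = all(res$conv)))
}

#' Fit the graph-guided fused lasso over all traits jointly
#'
#' Minimizes the multi-output objective
#' `sum_k ||y_k - X b_k||^2 + lambda ||B||_1 +
#'  gamma * sum_(m,l) in E f(r_ml) sum_j |b_jm - sign(r_ml) b_jl|`
#' where `E` is the trait correlation graph and `f(r) = |r|`. The
#' non-separable fusion term is handled by Nesterov smoothing (parameter
#' `mu`) inside a monotone accelerated proximal-gradient loop; the L1 term
#' stays exact in the prox, so entries are zeroed exactly.
#'
#' The recorded objective trajectory is the smoothed surrogate actually
#' minimized; the returned `objective` diagnostic is the exact printed
#' objective at the solution.
#'
#' @inheritParams fit_lasso
#' @param graph Trait graph from [build_trait_graph()].
#' @param gamma Nonnegative fusion penalty.
#' @param mu Smoothing parameter for the fusion term.
#' @return An `irnet_fit`.
#' @export
fit_gflasso <- function(X, Y, graph, lambda, gamma, tol = 1e-7,
                        maxit = 10000, mu = 1e-4, beta_init = NULL) {
  if (lambda < 0 || gamma < 0) stop("penalties must be >= 0")
  Y <- as.matrix(Y)
  e <- graph$edges
  if (!is.null(e) && nrow(e)) {
    if (any(e$a == e$b)) stop("trait graph contains a self-loop")
    unknown <- setdiff(c(e$a, e$b), colnames(Y))
    if (length(unknown)) {
      stop("trait graph references unknown traits: ",
           paste(head(unknown, 5), collapse = ", "))
    }
  }
  res <- center_fit(X, Y, function(Xc, Yc) {
    J <- ncol(Xc)
    K <- ncol(Yc)
    XtX <- crossprod(Xc)
    XtY <- crossprod(Xc, Yc)
    L_loss <- 2 * max(eigen(XtX, symmetric = TRUE, only.values = TRUE)$values)
    has_edges <- !is.null(e) && nrow(e) > 0 && gamma > 0
    if (has_edges) {
      mi <- match(e$a, colnames(Yc))
      li <- match(e$b, colnames(Yc))
      we <- gamma * abs(e$r)
      se <- sign(e$r)
      wdeg <- numeric(K)
      for (k in seq_along(we)) {
        wdeg[mi[k]] <- wdeg[mi[k]] + we[k]
        wdeg[li[k]] <- wdeg[li[k]] + we[k]
      }
      # backtracking raises L where the smoothed term actually bends, so we
      # start from the loss curvature rather than the worst-case
      # L_loss + 2*max(wdeg)/mu smoothing bound
      L <- L_loss
      fusion_smooth <- function(B) {
        D <- B[, mi, drop = FALSE] -
          sweep(B[, li, drop = FALSE], 2, se, `*`)
        phi <- ifelse(abs(D) > mu, abs(D) - mu / 2, D^2 / (2 * mu))
        sum(sweep(phi, 2, we, `*`))
      }
      # incidence matrix of the difference operator: row e has +1 at trait
      # m(e) and -sign(r_e) at trait l(e); the smoothed-fusion gradient is
      # then a single dense product
      IncT <- matrix(0, length(we), K)
      IncT[cbind(seq_along(we), mi)] <- 1
      IncT[cbind(seq_along(we), li)] <- IncT[cbind(seq_along(we), li)] - se
      fusion_grad <- function(B) {
        D <- B[, mi, drop = FALSE] -
          sweep(B[, li, drop = FALSE], 2, se, `*`)
        A <- sweep(pmin(pmax(D / mu, -1), 1), 2, we, `*`)
        A %*% IncT
      }
    } else {
      L <- L_loss
      fusion_smooth <- function(B) 0
      fusion_grad <- function(B) 0
    }
    f_smooth <- function(B) {
      sum((Yc - Xc %*% B)^2) + fusion_smooth(B)
    }
    grad_f <- function(B) 2 * (XtX %*% B - XtY) + fusion_grad(B)
    penalty_val <- function(B) lambda * sum(abs(B))
    prox <- function(V, tau) soft_threshold(V, tau * lambda)
    B0 <- if (is.null(beta_init)) matrix(0, J, K) else beta_init
    opt <- mfista(B0, grad_f, f_smooth, penalty_val, prox, L, tol, maxit)
    beta <- opt$x
    dimnames(beta) <- list(colnames(X), colnames(Y))
    list(beta = beta, opt = opt)
  })
  opt <- res$opt
  obj <- gflasso_objective(res$beta, sweep(X, 2, colMeans(X)),
                           sweep(Y, 2, colMeans(Y)), graph, lambda, gamma)
  new_fit(res$beta, res$intercept, "gflasso",
          list(lambda = lambda, gamma = gamma, mu = mu),
          list(objective = obj, trajectory = list(opt$trajectory),
               iterations = opt$iterations, converged = opt$converged))
}

# Smallest penalty level at which the sparse-group-lasso fit is entirely
# zero: for every (group g, trait k) block, zero is optimal iff
# ||soft(X_g' y_k / n, alpha*lambda)||_2 <= (1-alpha)*lambda*sqrt(p_g);
# the threshold is the largest root over blocks (found by bisection).
sgl_lambda_max <- function(Xc, Yc, g_index, alpha) {
  n <- nrow(Xc)
  V <- crossprod(Xc, Yc) / n
  lam <- 0
  for (rows in g_index) {
    p <- length(rows)
    for (k in seq_len(ncol(V))) {
      v <- V[rows, k]
      if (alpha >= 1) {
        lam <- max(lam, max(abs(v)))
        next
      }
      phi <- function(l) {
        sqrt(sum(soft_threshold(v, alpha * l)^2)) - (1 - alpha) * l * sqrt(p)
      }
      hi <- if (alpha > 0) max(abs(v)) / alpha
            else sqrt(sum(v^2)) / sqrt(p) * (1 + 1e-9)
      if (phi(hi) > 0) hi <- hi * (1 + 1e-6)
      root <- tryCatch(stats::uniroot(phi, c(0, hi), tol = 1e-10)$root,
                       error = function(e) hi)
      lam <- max(lam, root)
    }
  }
  lam
}

# Exact prox of tau*(alpha*lambda*||.||_1 + (1-alpha)*lambda*sum sqrt(p_l)||.||_2)
# over disjoint groups: soft-threshold then group soft-threshold.
sgl_prox <- function(v, tau, g_index, g_sizes, lambda, alpha) {
  u <- soft_threshold(v, tau * alpha * lambda)
  for (l in seq_along(g_index)) {
    rows <- g_index[[l]]
    nrm <- sqrt(sum(u[rows]^2))
    t2 <- tau * (1 - alpha) * lambda * sqrt(g_sizes[l])
    u[rows] <- if (nrm <= t2) 0 else u[rows] * (1 - t2 / nrm)
  }
  u
}

#' Fit the sparse group lasso, one trait at a time
#'
#' Minimizes, per trait,
#' `(1/(2n)) ||y - X b||^2 + (1-alpha) lambda sum_l sqrt(p_l) ||b^(l)||_2 +
#'  alpha lambda ||b||_1`
#' over a disjoint partition of the features into groups, giving sparsity at
#' both the group and the individual-feature level. `alpha = 1` reduces to
#' the lasso penalty, `alpha = 0` to the group lasso. Solved by a monotone
#' accelerated proximal-gradient loop; the prox of the combined penalty is
#' exact (soft-threshold followed by groupwise shrinkage).
#'
#' @inheritParams fit_lasso
#' @param groups Named integer vector mapping every feature to a group
#'   (see [cluster_features()]).
#' @param alpha Mixing parameter in `[0, 1]`; pipeline default 0.1.
#' @return An `irnet_fit`.
#' @export
fit_sgl <- function(X, Y, groups, lambda, alpha = 0.1, tol = 1e-7,
                    maxit = 10000, beta_init = NULL) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  Y <- as.matrix(Y)
  g <- check_groups(groups, colnames(X))
  g_index <- split(seq_along(g), g)
  g_sizes <- lengths(g_index)
  res <- center_fit(X, Y, function(Xc, Yc) {
    n <- nrow(Xc)
    J <- ncol(Xc)
    K <- ncol(Yc)
    XtX <- crossprod(Xc)
    L <- max(eigen(XtX, symmetric = TRUE, only.values = TRUE)$values) / n
    beta <- matrix(0, J, K, dimnames = list(colnames(X), colnames(Y)))
    trajs <- vector("list", K)
    iters <- integer(K)
    conv <- logical(K)
    for (k in seq_len(K)) {
      yk <- Yc[, k]
      Xty <- crossprod(Xc, yk)
      grad_f <- function(b) (XtX %*% b - Xty) / n
      f_smooth <- function(b) sum((yk - Xc %*% b)^2) / (2 * n)
      penalty_val <- function(b) {
        alpha * lambda * sum(abs(b)) +
          (1 - alpha) * lambda *
            sum(sqrt(g_sizes) *
                  vapply(g_index, function(r) sqrt(sum(b[r]^2)), 0))
      }
      prox <- function(v, tau) sgl_prox(v, tau, g_index, g_sizes, lambda, alpha)
      b0 <- if (is.null(beta_init)) matrix(0, J, 1) else beta_init[, k, drop = FALSE]
      opt <- mfista(b0, grad_f, f_smooth, penalty_val, prox, L, tol, maxit)
      beta[, k] <- opt$x
      trajs[[k]] <- opt$trajectory
      iters[k] <- opt$iterations
      conv[k] <- opt$converged
    }
    list(beta = beta, trajs = trajs, iters = iters, conv = conv)
  })
  objective <- sum(vapply(res$trajs, function(tr) tr[length(tr)], 0))
  new_fit(res$beta, res$intercept, "sgl",
          list(lambda = lambda, alpha = alpha),
          list(objective = objective, trajectory = res$trajs,
               iterations = max(res$iters), converged = all(res$conv)))
}

#' Fit the jointly input/output-structured lasso over the full matrix
#'
#' Minimizes
#' `(1/2) ||Y - X B||_F^2 + lambda1 ||B||_1 +
#'  lambda2 sum_k sum_g ||b_k^g||_2 + lambda3 sum_j sum_h ||b_h^j||_2`
#' where `b_k^g` is the block of column k belonging to input group g and
#' `b_h^j` the block of row j belonging to output group h, so whole
#' feature-group and trait-group blocks can be zeroed jointly. Solved by a
#' monotone accelerated proximal-gradient loop; the prox of the triple
#' penalty is applied as the sequential composition of the three shrinkage
#' operators (exact for each pair of nested terms), with an
#' objective-decrease safeguard at every step.
#'
#' @inheritParams fit_lasso
#' @param G Named integer vector: feature -> input group.
#' @param H Named integer vector: trait -> output group.
#' @param lambda1,lambda2,lambda3 Nonnegative penalty levels (entry-wise,
#'   input-group, output-group).
#' @return An `irnet_fit`.
#' @export
fit_siol <- function(X, Y, G, H, lambda1, lambda2, lambda3, tol = 1e-7,
                     maxit = 10000, beta_init = NULL) {
  if (lambda1 < 0 || lambda2 < 0 || lambda3 < 0) stop("penalties must be >= 0")
  Y <- as.matrix(Y)
  gG <- check_groups(G, colnames(X))
  gH <- check_groups(H, colnames(Y))
  G_index <- split(seq_along(gG), gG)
  H_index <- split(seq_along(gH), gH)
  if (any(lengths(G_index) == 0) || any(lengths(H_index) == 0)) {
    stop("empty group in G or H")
  }
  res <- center_fit(X, Y, function(Xc, Yc) {
    J <- ncol(Xc)
    K <- ncol(Yc)
    XtX <- crossprod(Xc)
    XtY <- crossprod(Xc, Yc)
    L <- max(eigen(XtX, symmetric = TRUE, only.values = TRUE)$values)
    grad_f <- function(B) XtX %*% B - XtY
    f_smooth <- function(B) 0.5 * sum((Yc - Xc %*% B)^2)
    penalty_val <- function(B) {
      p <- lambda1 * sum(abs(B))
      for (rows in G_index) {
        p <- p + lambda2 * sum(sqrt(colSums(B[rows, , drop = FALSE]^2)))
      }
      for (cols in H_index) {
        p <- p + lambda3 * sum(sqrt(rowSums(B[, cols, drop = FALSE]^2)))
      }
      p
    }
    prox <- function(V, tau) {
      U <- soft_threshold(V, tau * lambda1)
      if (lambda2 > 0) {
        for (rows in G_index) {
          nrms <- sqrt(colSums(U[rows, , drop = FALSE]^2))
          scl <- ifelse(nrms > tau * lambda2, 1 - tau * lambda2 / nrms, 0)
          U[rows, ] <- sweep(U[rows, , drop = FALSE], 2, scl, `*`)
        }
      }
      if (lambda3 > 0) {
        for (cols in H_index) {
          nrms <- sqrt(rowSums(U[, cols, drop = FALSE]^2))
          scl <- ifelse(nrms > tau * lambda3, 1 - tau * lambda3 / nrms, 0)
          U[, cols] <- U[, cols, drop = FALSE] * scl
        }
      }
      U
    }
    B0 <- if (is.null(beta_init)) matrix(0, J, K) else beta_init
    opt <- mfista(B0, grad_f, f_smooth, penalty_val, prox, L, tol, maxit)
    beta <- opt$x
    dimnames(beta) <- list(colnames(X), colnames(Y))
    list(beta = beta, opt = opt)
  })
  opt <- res$opt
  new_fit(res$beta, res$intercept, "siol",
          list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
          list(objective = opt$trajectory[length(opt$trajectory)],
               trajectory = list(opt$trajectory),
               iterations = opt$iterations, converged = opt$converged))
}

#' Predicted values and mean squared error on held-out data
#'
#' `MSE_k = mean_i (Y_ik - b0_k - x_i' b_k)^2`, then averaged over traits.
#'
#' @param fit An `irnet_fit`.
#' @param X_test,Y_test Held-out feature / trait matrices sharing variable
#'   ids with the fit.
#' @return List with `per_trait` (named vector) and `mean`.
#' @export
evaluate_mse <- function(fit, X_test, Y_test) {
  Y_test <- as.matrix(Y_test)
  if (!is.null(colnames(X_test)) && !is.null(rownames(fit$beta))) {
    if (!setequal(colnames(X_test), rownames(fit$beta))) {
      stop("feature ids of X_test do not match the fit")
    }
    X_test <- X_test[, rownames(fit$beta), drop = FALSE]
  }
  if (ncol(X_test) != nrow(fit$beta) || ncol(Y_test) != ncol(fit$beta)) {
    stop("dimension mismatch between fit and test matrices")
  }
  pred <- sweep(X_test %*% fit$beta, 2, fit$intercept, `+`)
  per_trait <- colMeans((Y_test - pred)^2)
  list(per_trait = per_trait, mean = mean(per_trait))
}

#' Select a penalty level by k-fold cross-validation
#'
#' Grid search over a geometric ladder from `lambda_max` (the smallest level
#' driving all coefficients to zero) down to
#' `lambda_min_fraction * lambda_max`, minimizing mean held-out MSE. For the
#' lasso the default fraction is 0.01 over 30 points; for the sparse group
#' lasso the fraction is 0.8 (its conventional short path) over 10 points.
#'
#' @param method `"lasso"` or `"sgl"`.
#' @param X,Y Standardized training matrices.
#' @param folds Number of CV folds (>= 2).
#' @param seed Seed for the random fold assignment (required).
#' @param groups Feature groups (required for `"sgl"`).
#' @param alpha SGL mixing parameter.
#' @param n_lambda Grid size.
#' @param lambda_min_fraction Ratio of smallest to largest grid value.
#' @param tol,maxit Solver controls (a looser tolerance is fine for CV).
#' @return List with `best_lambda`, `table` (lambda, cv_mse) and the method.
#' @export
select_lambda_cv <- function(method = c("lasso", "sgl"), X, Y, folds = 5,
                             seed, groups = NULL, alpha = 0.1,
                             n_lambda = NULL, lambda_min_fraction = NULL,
                             tol = 1e-6, maxit = 5000) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (folds < 2) stop("folds must be >= 2")
  if (n < folds) stop("fewer samples than folds")
  if (missing(seed)) stop("a seed for the fold assignment is required")
  Yc <- sweep(Y, 2, colMeans(Y))
  Xc <- sweep(X, 2, colMeans(X))
  if (method == "lasso") {
    lambda_max <- 2 * max(abs(crossprod(Xc, Yc)))
    if (is.null(lambda_min_fraction)) lambda_min_fraction <- 0.01
    if (is.null(n_lambda)) n_lambda <- 30
  } else {
    if (is.null(groups)) stop("groups are required for sgl")
    g <- check_groups(groups, colnames(X))
    lambda_max <- sgl_lambda_max(Xc, Yc, split(seq_along(g), g), alpha)
    if (is.null(lambda_min_fraction)) lambda_min_fraction <- 0.8
    if (is.null(n_lambda)) n_lambda <- 10
  }
  grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_fraction),
                  length.out = n_lambda))
  fold_of <- local({
    set.seed(seed)
    sample(rep(seq_len(folds), length.out = n))
  })
  cv_mse <- matrix(NA_real_, n_lambda, folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    warm <- NULL
    for (i in seq_along(grid)) {
      fit <- if (method == "lasso") {
        fit_lasso(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], grid[i],
                  tol = tol, maxit = maxit, beta_init = warm)
      } else {
        fit_sgl(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], groups,
                grid[i], alpha, tol = tol, maxit = maxit, beta_init = warm)
      }
      warm <- fit$beta
      cv_mse[i, f] <- evaluate_mse(fit, X[!tr, , drop = FALSE],
                                   Y[!tr, , drop = FALSE])$mean
    }
  }
  tab <- data.frame(lambda = grid, cv_mse = rowMeans(cv_mse))
  best <- which.min(tab$cv_mse)
  list(method = method, best_lambda = grid[best], table = tab,
       alpha = if (method == "sgl") alpha else NULL)
}

#' Initial fused-lasso penalty from a preliminary sparse fit
#'
#' The starting penalty is the median absolute value of the nonzero
#' coefficients of a preliminary (lasso) fit multiplied by the number of
#' traits; the starting fusion level is 1. The conventional half/base/double
#' exploration grid around both is returned alongside.
#'
#' @param beta Coefficient matrix (or `irnet_fit`) with >= 1 nonzero entry.
#' @param K Number of expression traits.
#' @return List with `lambda`, `gamma`, and multiplier grids
#'   `lambda_grid`, `gamma_grid`.
#' @export
gflasso_lambda_heuristic <- function(beta, K) {
  if (inherits(beta, "irnet_fit")) beta <- beta$beta
  nz <- abs(beta[beta != 0])
  if (length(nz) == 0) stop("all-zero coefficient matrix; cannot set lambda")
  list(lambda = median(nz) * K, gamma = 1,
       lambda_grid = c(0.5, 1, 2), gamma_grid = c(0.5, 1, 2))
}

#' Default penalty configuration used across the pipeline
#'
#' SGL mixing `alpha = 0.1` and path fraction 0.8; the joint solver's
#' penalties at 0.1 / 0.3 / 0.2 (mid-range of the reported tuned intervals);
#' trait-graph correlation threshold 0.7; 20 clustering groups.
#'
#' @return Named list of per-method defaults.
#' @export
penalty_defaults <- function() {
  list(lasso = list(lambda_min_fraction = 0.01, n_lambda = 30),
       gflasso = list(gamma = 1, cor_threshold = 0.7),
       sgl = list(alpha = 0.1, lambda_min_fraction = 0.8, n_lambda = 10),
       siol = list(lambda1 = 0.1, lambda2 = 0.3, lambda3 = 0.2),
       n_groups = 20)
}

#' Ranking quality of |beta| against a known coefficient support
#'
#' Area under the ROC curve of the pooled `|beta|` values as a score for the
#' true nonzero entries (ties, e.g. exact zeros, get half credit via
#' mid-ranks).
#'
#' @param beta Coefficient matrix (or `irnet_fit`).
#' @param support Logical matrix of the same shape, `TRUE` at true nonzeros.
#' @return AUC in `[0, 1]`.
#' @export
support_auc <- function(beta, support) {
  if (inherits(beta, "irnet_fit")) beta <- beta$beta
  stopifnot(identical(dim(beta), dim(support)))
  s <- abs(as.vector(beta))
  y <- as.vector(support)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) stop("support must contain both classes")
  r <- rank(s)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
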