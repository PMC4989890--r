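#' Printed objective functions of the four penalized regressions
#'
#' These evaluate, exactly as written in the model definitions, the
#' objectives the solvers minimize (after profiling out intercepts by
#' centring, so `X` and `Y` here are the centred matrices). They are exported
#' so that fits can be audited and compared against independent numerical
#' minimizers.
#'
#' Loss scalings differ deliberately between methods: the lasso objective has
#' no sample-size factor, the sparse group lasso carries `1/(2n)`, and the
#' jointly structured objective carries `1/2`. Reduction identities between
#' methods therefore involve the corresponding rescaling of the penalty
#' level.
#'
#' @param beta Coefficient vector (single trait) or J x K matrix.
#' @param X Centred feature matrix (n x J).
#' @param y,Y Centred trait vector / matrix.
#' @param lambda L1 penalty level.
#' @return Objective value (single number).
#' @name objectives
NULL

#' @rdname objectives
#' @export
lasso_objective <- function(beta, X, y, lambda) {
  beta <- as.matrix(beta)
  y <- as.matrix(y)
  r <- y - X %*% beta
  sum(r^2) + lambda * sum(abs(beta))
}

#' @rdname objectives
#' @param graph A [build_trait_graph()] result (or list with `$edges`).
#' @param gamma Fusion penalty level.
#' @export
gflasso_objective <- function(beta, X, Y, graph, lambda, gamma) {
  B <- as.matrix(beta)
  Y <- as.matrix(Y)
  r <- Y - X %*% B
  obj <- sum(r^2) + lambda * sum(abs(B))
  e <- graph$edges
  if (!is.null(e) && nrow(e)) {
    mi <- match(e$a, colnames(Y))
    li <- match(e$b, colnames(Y))
    for (k in seq_len(nrow(e))) {
      obj <- obj + gamma * abs(e$r[k]) *
        sum(abs(B[, mi[k]] - sign(e$r[k]) * B[, li[k]]))
    }
  }
  obj
}

#' @rdname objectives
#' @param groups Named integer vector: feature -> group.
#' @param alpha Convex mix of lasso (`alpha = 1`) and group-lasso
#'   (`alpha = 0`) penalties.
#' @export
sgl_objective <- function(beta, X, y, groups, lambda, alpha) {
  B <- as.matrix(beta)
  y <- as.matrix(y)
  n <- nrow(X)
  g <- as.integer(groups)
  obj <- sum((y - X %*% B)^2) / (2 * n) + alpha * lambda * sum(abs(B))
  for (l in unique(g)) {
    rows <- which(g == l)
    pl <- length(rows)
    for (k in seq_len(ncol(B))) {
      obj <- obj + (1 - alpha) * lambda * sqrt(pl) *
        sqrt(sum(B[rows, k]^2))
    }
  }
  obj
}

#' @rdname objectives
#' @param G Named integer vector: feature -> input group.
#' @param H Named integer vector: trait -> output group.
#' @param lambda1,lambda2,lambda3 Entry-wise, input-group and output-group
#'   penalty levels.
#' @export
siol_objective <- function(beta, X, Y, G, H, lambda1, lambda2, lambda3) {
  B <- as.matrix(beta)
  Y <- as.matrix(Y)
  obj <- 0.5 * sum((Y - X %*% B)^2) + lambda1 * sum(abs(B))
  gG <- as.integer(G)
  gH <- as.integer(H)
  for (g in unique(gG)) {
    rows <- which(gG == g)
    obj <- obj + lambda2 * sum(sqrt(colSums(B[rows, , drop = FALSE]^2)))
  }
  for (h in unique(gH)) {
    cols <- which(gH == h)
    obj <- obj + lambda3 * sum(sqrt(rowSums(B[, cols, drop = FALSE]^2)))
  }
  obj
}
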