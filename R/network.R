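#' Similarity network from a regression coefficient matrix
#'
#' Nodes are features (rows of B, used as-is) or traits (columns of B, i.e.
#' the transpose). Each node's coefficient vector is compared by Euclidean
#' distance after the coefficient weights are normalized (per-dimension
#' standardization across nodes; dimensions with zero spread contribute
#' nothing). Affinities use the K-nearest-neighbour scaled exponential
#' kernel
#' `W(i,j) = exp(-d^2(i,j) / (alpha * eps_ij))`,
#' `eps_ij = (mean d(i, KNN_i) + mean d(j, KNN_j) + d(i,j)) / 3`,
#' so the bandwidth adapts to each pair's local neighbourhood scale.
#' `W(i,i) = 1` and all entries lie in (0, 1].
#'
#' @param B Coefficient matrix (J x K) or an `irnet_fit`.
#' @param side `"feature"` (rows of B) or `"trait"` (columns of B).
#' @param K Number of nearest neighbours for the local scale (>= 1).
#' @param alpha Kernel width multiplier (> 0); grid-searched in 0.3-0.8.
#' @param normalize Standardize coefficient dimensions first (default TRUE).
#' @return Symmetric affinity matrix with node dimnames and attributes
#'   `side`, `K`, `alpha`.
#' @export
coefficient_affinity <- function(B, side = c("feature", "trait"), K = 20,
                                 alpha = 0.5, normalize = TRUE) {
  side <- match.arg(side)
  if (inherits(B, "irnet_fit")) B <- B$beta
  stopifnot(is.matrix(B))
  if (!all(is.finite(B))) stop("coefficient matrix has non-finite entries")
  if (K < 1) stop("K must be >= 1")
  if (alpha <= 0) stop("alpha must be > 0")
  V <- if (side == "feature") B else t(B)
  N <- nrow(V)
  if (N < 3) stop("need at least 3 nodes")
  zero_nodes <- rowSums(V != 0) == 0
  if (sum(zero_nodes) > N / 2) {
    stop("degenerate coefficient matrix: more than half the nodes have all-zero vectors")
  }
  if (normalize) {
    mu <- colMeans(V)
    sdev <- apply(V, 2, sd)
    keep <- sdev > 0
    V <- sweep(V, 2, mu)
    V[, keep] <- sweep(V[, keep, drop = FALSE], 2, sdev[keep], `/`)
    V[, !keep] <- 0
  }
  D <- as.matrix(dist(V))
  Kn <- min(K, N - 1)
  # mean distance of each node to its K nearest neighbours (self excluded)
  Tn <- vapply(seq_len(N), function(i) {
    mean(sort(D[i, -i])[seq_len(Kn)])
  }, 0)
  Eps <- (outer(Tn, Tn, `+`) + D) / 3
  W <- exp(-D^2 / (alpha * Eps))
  # coincident vectors (d = 0) have affinity exp(0) = 1 even when the local
  # scale collapses to zero
  W[D == 0] <- 1
  diag(W) <- 1
  W <- (W + t(W)) / 2
  ids <- rownames(V)
  if (is.null(ids)) ids <- paste0("n", seq_len(N))
  dimnames(W) <- list(ids, ids)
  attr(W, "side") <- side
  attr(W, "K") <- K
  attr(W, "alpha") <- alpha
  # the (normalized) node vectors travel with the network so that
  # permutation null models can rebuild it through the same kernel
  attr(W, "vectors") <- V
  W
}

# rebuild an affinity network after permuting its node vectors
# (each dimension shuffled independently across nodes); the stored vectors
# are already in node-by-dimension orientation, so no further transposition
permute_affinity <- function(W) {
  V <- attr(W, "vectors")
  Vp <- apply(V, 2, sample)
  rownames(Vp) <- rownames(V)
  out <- coefficient_affinity(Vp, side = "feature",
                              K = attr(W, "K"), alpha = attr(W, "alpha"),
                              normalize = FALSE)
  attr(out, "side") <- attr(W, "side")
  out
}

#' Row-stochastic kernel and KNN local affinity of a similarity matrix
#'
#' The full kernel is `P = D^-1 W` with `D = diag(rowSums(W))`, so every row
#' of P sums to one. The local affinity S keeps, per row, only the K largest
#' off-diagonal affinities: these are rescaled to sum to 1/2, the diagonal
#' carries the remaining 1/2 self-weight (set `self_weight = FALSE` to
#' renormalize the neighbours to 1 with a zero diagonal instead). S encodes
#' the trusted local neighbourhood through which similarity diffuses during
#' fusion.
#'
#' @param W Symmetric nonnegative affinity matrix.
#' @param K Number of nearest neighbours kept per row.
#' @param self_weight Keep the 1/2 diagonal self-weight convention.
#' @return List with `P`, `S`, `K`.
#' @export
normalize_kernel <- function(W, K = 20, self_weight = TRUE) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  N <- nrow(W)
  rs <- rowSums(W)
  if (any(rs <= 0)) stop("zero row sum in affinity matrix")
  P <- W / rs
  Kn <- min(K, N - 1)
  S <- matrix(0, N, N, dimnames = dimnames(W))
  for (i in seq_len(N)) {
    off <- W[i, ]
    off[i] <- -Inf
    # ties broken by node order for determinism
    sel <- order(off, seq_len(N), decreasing = c(TRUE, FALSE), method = "radix")[seq_len(Kn)]
    wsum <- sum(W[i, sel])
    if (wsum <= 0) stop("zero neighbour weight sum at row ", i)
    if (self_weight) {
      S[i, sel] <- W[i, sel] / (2 * wsum)
      S[i, i] <- 0.5
    } else {
      S[i, sel] <- W[i, sel] / wsum
    }
  }
  list(P = P, S = S, K = K)
}
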