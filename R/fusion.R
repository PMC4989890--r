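#' Fuse several similarity networks by iterative cross-diffusion
#'
#' Each network's row-stochastic status matrix P is repeatedly updated
#' through the local (KNN) affinity of its own network and the average
#' status of the other networks:
#' `P^(v) <- S^(v) %*% (mean of the other P) %*% t(S^(v))`,
#' followed by symmetrization and row renormalization (which keeps every
#' iterate row-stochastic). With two networks this is exactly the printed
#' two-matrix update; the average over the other m-1 status matrices is the
#' standard generalization for m > 2. After `t` iterations the fused
#' network is the average of the m status matrices. Similarities supported
#' across networks are propagated and reinforced; weights supported by no
#' network fade.
#'
#' @param networks List of >= 2 symmetric affinity matrices on identical
#'   node sets (same order).
#' @param K Neighbours for the local affinity S.
#' @param t Number of diffusion iterations (default 20).
#' @param self_weight Passed to [normalize_kernel()].
#' @param trace Keep the per-iteration status matrices (attribute
#'   `"trace"`, a list of length `t` of lists of m matrices); for
#'   diagnostics on small problems.
#' @return Fused symmetric matrix (rows approximately stochastic up to the
#'   final symmetrization), with the common dimnames.
#' @export
snf_fuse <- function(networks, K = 20, t = 20, self_weight = TRUE,
                     trace = FALSE) {
  stopifnot(is.list(networks), length(networks) >= 2, t >= 1)
  m <- length(networks)
  ids <- rownames(networks[[1]])
  for (v in seq_len(m)) {
    W <- networks[[v]]
    if (!is.matrix(W) || nrow(W) != ncol(W)) stop("network ", v, " is not square")
    if (!is.null(ids) && !identical(rownames(W), ids)) {
      diffs <- union(setdiff(rownames(W), ids), setdiff(ids, rownames(W)))
      stop("node-set mismatch in network ", v,
           if (length(diffs)) paste0(": ", paste(head(diffs, 5), collapse = ", "))
           else " (same ids, different order)")
    }
    if (nrow(W) != nrow(networks[[1]])) stop("networks differ in size")
  }
  kernels <- lapply(networks, normalize_kernel, K = K, self_weight = self_weight)
  P <- lapply(kernels, `[[`, "P")
  S <- lapply(kernels, `[[`, "S")
  tr_list <- if (trace) vector("list", t) else NULL
  for (iter in seq_len(t)) {
    P_new <- vector("list", m)
    for (v in seq_len(m)) {
      Pbar <- Reduce(`+`, P[-v]) / (m - 1)
      Q <- S[[v]] %*% Pbar %*% t(S[[v]])
      Q <- (Q + t(Q)) / 2
      P_new[[v]] <- Q / rowSums(Q)
    }
    P <- P_new
    if (trace) tr_list[[iter]] <- P
  }
  Pc <- Reduce(`+`, P) / m
  Pc <- (Pc + t(Pc)) / 2
  dimnames(Pc) <- dimnames(networks[[1]])
  # keep the construction so permutation null models can re-run it
  attr(Pc, "fusion") <- list(networks = networks, K = K, t = t,
                             self_weight = self_weight)
  if (trace) attr(Pc, "trace") <- tr_list
  Pc
}

#' Consensus score of a fused network against its inputs
#'
#' `f(W, w_f) = mean_i SIM(w_f, w_i) + sum_{i<j} (1 - SIM(w_i, w_j)) / C(N,2)`
#' where SIM is the Pearson correlation of the vectorized off-diagonal
#' upper triangles. The first term rewards a fused network that agrees with
#' every input; the second is larger when the inputs disagree among
#' themselves (so consensus is most valuable). Equals exactly 1 when the
#' fused network and all inputs are identical.
#'
#' @param fused Fused matrix.
#' @param networks List of input affinity matrices (same shape).
#' @return List with `value`, `sim_to_fused`, `pairwise_sim`.
#' @export
consensus_score <- function(fused, networks) {
  N <- length(networks)
  stopifnot(N >= 2)
  ut <- upper.tri(fused)
  vecs <- lapply(networks, function(W) {
    stopifnot(identical(dim(W), dim(fused)))
    W[ut]
  })
  fv <- fused[ut]
  if (sd(fv) == 0) stop("SIM undefined: fused network is constant")
  for (v in vecs) if (sd(v) == 0) stop("SIM undefined: constant input network")
  sims <- vapply(vecs, function(v) cor(fv, v), 0)
  pair <- combn(N, 2)
  psim <- apply(pair, 2, function(ij) cor(vecs[[ij[1]]], vecs[[ij[2]]]))
  value <- mean(sims) + sum(1 - psim) / choose(N, 2)
  list(value = value, sim_to_fused = sims, pairwise_sim = psim)
}

#' Grid search of the affinity parameters (K, alpha) by consensus score
#'
#' For every combination on the grid, the per-method affinities are rebuilt
#' from the coefficient matrices, fused, and scored with
#' [consensus_score()]; the argmax is returned (ties broken toward smaller
#' K, then smaller alpha). The conventional search ranges are K in 2..20 and
#' alpha in 0.3..0.8.
#'
#' @param B_list List of coefficient matrices (or `irnet_fit`s), one per
#'   regression method.
#' @param side `"feature"` or `"trait"`.
#' @param K_range Integer vector of candidate K.
#' @param alpha_range Numeric vector of candidate alpha.
#' @param t Fusion iterations.
#' @return List with `K`, `alpha`, `score`, and the full `table`
#'   (K, alpha, score; NA where a cell failed).
#' @export
select_k_alpha <- function(B_list, side = "feature", K_range = 2:20,
                           alpha_range = seq(0.3, 0.8, by = 0.1), t = 20) {
  stopifnot(length(K_range) >= 1, length(alpha_range) >= 1)
  grid <- expand.grid(K = K_range, alpha = alpha_range)
  grid <- grid[order(grid$K, grid$alpha), , drop = FALSE]
  rownames(grid) <- NULL
  grid$score <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sc <- tryCatch({
      Ws <- lapply(B_list, coefficient_affinity, side = side,
                   K = grid$K[i], alpha = grid$alpha[i])
      fused <- snf_fuse(Ws, K = grid$K[i], t = t)
      consensus_score(fused, Ws)$value
    }, error = function(e) NA_real_)
    grid$score[i] <- sc
  }
  if (all(is.na(grid$score))) stop("all (K, alpha) grid cells failed")
  best <- which.max(grid$score)  # grid sorted by (K, alpha): first max wins ties
  list(K = grid$K[best], alpha = grid$alpha[best], score = grid$score[best],
       table = grid)
}
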