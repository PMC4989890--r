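toy_affinities <- function(m = 2, N = 6, d = 4, seed = 1, K = 2) {
  set.seed(seed)
  lapply(seq_len(m), function(i) {
    V <- matrix(rnorm(N * d), N, d,
                dimnames = list(paste0("n", seq_len(N)), paste0("t", seq_len(d))))
    coefficient_affinity(V, "feature", K = K, alpha = 0.5)
  })
}

test_that("identical inputs stay identical and match the direct iteration", {
  W <- toy_affinities(1, N = 5, seed = 2, K = 2)[[1]]
  fused <- snf_fuse(list(W, W), K = 2, t = 3, trace = TRUE)
  # with identical inputs every status matrix stays identical, so the fused
  # network equals the single-network diffusion iterate computed directly
  k <- normalize_kernel(W, K = 2)
  P <- k$P
  for (i in 1:3) {
    Q <- k$S %*% P %*% t(k$S)
    Q <- (Q + t(Q)) / 2
    P <- Q / rowSums(Q)
  }
  expected <- (P + t(P)) / 2
  expect_equal(unclass(fused)[, ], expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  for (iter in attr(fused, "trace")) {
    expect_equal(iter[[1]], iter[[2]], tolerance = 1e-14)
  }
})

test_that("a single fusion step matches explicit matrix products", {
  nets <- toy_affinities(2, N = 4, seed = 3, K = 2)
  fused <- snf_fuse(nets, K = 2, t = 1)
  k1 <- normalize_kernel(nets[[1]], K = 2)
  k2 <- normalize_kernel(nets[[2]], K = 2)
  upd <- function(S, P) {
    Q <- S %*% P %*% t(S)
    Q <- (Q + t(Q)) / 2
    Q / rowSums(Q)
  }
  P1 <- upd(k1$S, k2$P)
  P2 <- upd(k2$S, k1$P)
  expected <- (P1 + P2) / 2
  expected <- (expected + t(expected)) / 2
  expect_equal(unclass(fused)[, ], expected, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("every fusion iteration stays row-stochastic", {
  nets <- toy_affinities(3, N = 8, seed = 4, K = 3)
  fused <- snf_fuse(nets, K = 3, t = 6, trace = TRUE)
  for (iter in attr(fused, "trace")) {
    for (P in iter) {
      expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    }
  }
})

test_that("fusion is invariant to network order and equivariant to node order", {
  nets <- toy_affinities(3, N = 7, seed = 5, K = 2)
  f1 <- snf_fuse(nets, K = 2, t = 4)
  f2 <- snf_fuse(nets[c(3, 1, 2)], K = 2, t = 4)
  expect_equal(unclass(f1)[, ], unclass(f2)[, ], tolerance = 1e-12)
  perm <- sample(7)
  netsp <- lapply(nets, function(W) {
    Wp <- W[perm, perm]
    Wp
  })
  fp <- snf_fuse(netsp, K = 2, t = 4)
  expect_equal(unclass(fp)[rownames(f1), colnames(f1)], unclass(f1)[, ],
               tolerance = 1e-12)
})

test_that("fusion rejects mismatched node sets with a helpful message", {
  nets <- toy_affinities(2, N = 5, seed = 6)
  rownames(nets[[2]]) <- colnames(nets[[2]]) <- paste0("x", 1:5)
  expect_error(snf_fuse(nets, K = 2, t = 2), "node-set mismatch")
})

test_that("consensus score is exact on identical networks and permutation-symmetric", {
  nets <- toy_affinities(3, N = 6, seed = 7)
  W <- nets[[1]]
  expect_equal(consensus_score(W, list(W, W, W))$value, 1, tolerance = 1e-12)
  cs1 <- consensus_score(nets[[1]], nets)
  cs2 <- consensus_score(nets[[1]], nets[c(2, 3, 1)])
  expect_equal(cs1$value, cs2$value, tolerance = 1e-12)
  expect_error(consensus_score(matrix(1, 6, 6), nets), "SIM undefined")
})

test_that("consensus score matches term-by-term arithmetic on two networks", {
  nets <- toy_affinities(2, N = 5, seed = 8)
  fused <- snf_fuse(nets, K = 2, t = 2)
  cs <- consensus_score(fused, nets)
  off <- upper.tri(fused)
  s1 <- cor(fused[off], nets[[1]][off])
  s2 <- cor(fused[off], nets[[2]][off])
  s12 <- cor(nets[[1]][off], nets[[2]][off])
  expect_equal(cs$value, mean(c(s1, s2)) + (1 - s12) / 1, tolerance = 1e-12)
})

test_that("(K, alpha) grid search returns the exhaustive argmax with tie rules", {
  set.seed(9)
  B_list <- lapply(1:2, function(i) {
    matrix(rnorm(6 * 4), 6, 4,
           dimnames = list(paste0("f", 1:6), paste0("t", 1:4)))
  })
  sel <- select_k_alpha(B_list, side = "feature", K_range = c(2, 3),
                        alpha_range = c(0.3, 0.8), t = 3)
  expect_identical(nrow(sel$table), 4L)
  # independent exhaustive re-evaluation
  best <- -Inf
  for (K in c(2, 3)) for (a in c(0.3, 0.8)) {
    Ws <- lapply(B_list, coefficient_affinity, side = "feature", K = K, alpha = a)
    sc <- consensus_score(snf_fuse(Ws, K = K, t = 3), Ws)$value
    if (sc > best + 1e-12) {
      best <- sc
      pick <- c(K, a)
    }
  }
  expect_equal(c(sel$K, sel$alpha), pick)
  expect_equal(sel$score, best, tolerance = 1e-12)
  one <- select_k_alpha(B_list, K_range = 3, alpha_range = 0.5, t = 2)
  expect_identical(nrow(one$table), 1L)
  expect_equal(one$K, 3)
})

test_that("fusion propagates planted edges and suppresses universal noise", {
  # an edge strong in exactly one of three networks gains rank after fusion
  N <- 20
  d <- 6
  set.seed(10)
  base <- matrix(rnorm(N * d), N, d,
                 dimnames = list(sprintf("n%02d", 1:N), paste0("t", 1:d)))
  nets <- lapply(1:3, function(i) {
    V <- base + matrix(rnorm(N * d, sd = 1), N, d)
    if (i == 1) V[2, ] <- V[1, ] + rnorm(d, sd = 0.05)  # plant pair (1,2)
    coefficient_affinity(V, "feature", K = 4, alpha = 0.5)
  })
  fused <- snf_fuse(nets, K = 4, t = 10)
  off <- upper.tri(fused)
  rank_of_pair <- function(M) {
    r <- rank(M[off])
    idx <- which(row(M) == 1 & col(M) == 2)
    r[match(idx, which(off))] / sum(off)
  }
  input_ranks <- vapply(nets, rank_of_pair, 0)
  expect_gt(rank_of_pair(fused), mean(input_ranks))
  # an edge weak in all inputs ends below the fused median
  weak <- which.min(nets[[1]][off] + nets[[2]][off] + nets[[3]][off])
  expect_lt(fused[off][weak], median(fused[off]))
})
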