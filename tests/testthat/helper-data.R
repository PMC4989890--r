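# Small labelled matrices and toy fits used across tests.

toy_matrix <- function(n, p, seed = 1, prefix = "v") {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("s%02d", seq_len(n)),
                         sprintf("%s%02d", prefix, seq_len(p))))
}

# standardized X and a response built from the first features
toy_regression <- function(n = 30, J = 6, K = 2, seed = 1, sd = 0.5) {
  set.seed(seed)
  X <- standardize(toy_matrix(n, J, seed = seed, prefix = "f"))
  B <- matrix(0, J, K)
  B[1, ] <- 2
  B[2, 1] <- -1.5
  Y <- X %*% B + matrix(rnorm(n * K, sd = sd), n, K)
  dimnames(Y) <- list(rownames(X), sprintf("t%02d", seq_len(K)))
  list(X = X, Y = Y, B = B)
}

# design with X'X = n I (orthonormal columns scaled to sd-1 columns not
# needed; soft-threshold closed form only requires the Gram identity)
orthonormal_design <- function(n = 24, J = 5, seed = 3) {
  set.seed(seed)
  M <- scale(matrix(rnorm(n * n), n, n), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))[, seq_len(J), drop = FALSE]
  X <- sqrt(n) * Q   # mean-zero columns with X'X = n I
  colnames(X) <- sprintf("f%02d", seq_len(J))
  rownames(X) <- sprintf("s%02d", seq_len(n))
  X
}

empty_trait_graph <- function(trait_ids) {
  structure(list(edges = data.frame(a = character(0), b = character(0),
                                    r = numeric(0), w = numeric(0)),
                 threshold = 0.7, trait_ids = trait_ids),
            class = "trait_graph")
}

# two-block node vectors whose affinities separate cleanly: the within-block
# spread is small relative to the between-centre distance so within-block
# affinities are uniformly high and background affinities near zero
planted_block_vectors <- function(N = 20, d = 8, seed = 1, spread = 0.1) {
  set.seed(seed)
  blk <- rep(1:2, each = N / 2)
  centers <- rbind(rnorm(d, 3), rnorm(d, -3))
  V <- centers[blk, ] + matrix(rnorm(N * d, sd = spread), N, d)
  dimnames(V) <- list(sprintf("n%02d", seq_len(N)), sprintf("c%02d", seq_len(d)))
  list(V = V, blocks = blk)
}
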