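#' Simulation scenario for planted structured-regression data
#'
#' Describes a synthetic paired dataset: a feature matrix with correlated
#' feature groups, a sparse coefficient matrix whose support is aligned
#' with those groups and shared within trait blocks, and Gaussian noise
#' correlated within trait blocks. The default mirrors the scale of a
#' typical per-cancer methylation/expression dataset at reduced size.
#'
#' @param n Samples.
#' @param J Features.
#' @param K Traits.
#' @param n_feature_groups Feature groups (clusters of correlated columns).
#' @param n_trait_blocks Trait blocks (correlated output clusters).
#' @param support_frac Fraction of nonzero entries in the coefficient
#'   matrix, in (0, 1).
#' @param effect_range Range of |beta| for planted effects.
#' @param trait_cor Within-block correlation of the trait noise (the shared
#'   coefficient columns add further within-block trait correlation).
#' @param feature_cor Within-group correlation of the feature columns.
#' @param sigma Noise standard deviation (> 0).
#' @param seed Seed for [generate_scenario()] (required there).
#' @return Object of class `sim_scenario`.
#' @export
simulation_scenario <- function(n, J, K, n_feature_groups, n_trait_blocks,
                                support_frac, effect_range = c(0.5, 1.5),
                                trait_cor = 0.8, feature_cor = 0.5,
                                sigma = 0.5, seed = NULL) {
  sc <- list(n = n, J = J, K = K, n_feature_groups = n_feature_groups,
             n_trait_blocks = n_trait_blocks, support_frac = support_frac,
             effect_range = effect_range, trait_cor = trait_cor,
             feature_cor = feature_cor, sigma = sigma, seed = seed)
  counts <- c(n, J, K, n_feature_groups, n_trait_blocks)
  if (any(counts < 1)) stop("all scenario counts must be >= 1")
  if (!(support_frac > 0 && support_frac < 1)) {
    stop("support_frac must be in (0, 1)")
  }
  if (sigma <= 0) stop("sigma must be > 0")
  if (n_feature_groups > J) stop("more feature groups than features")
  if (n_trait_blocks > K) stop("more trait blocks than traits")
  if (length(effect_range) != 2 || effect_range[1] > effect_range[2] ||
      effect_range[1] < 0) {
    stop("effect_range must be an increasing nonnegative pair")
  }
  if (abs(trait_cor) >= 1 || abs(feature_cor) >= 1) {
    stop("correlations must lie in (-1, 1)")
  }
  structure(sc, class = "sim_scenario")
}

#' Default simulation scenario
#'
#' n = 100 samples, J = 200 features in 10 groups, K = 50 traits in 5
#' blocks, 5% coefficient support, effect sizes |beta| in [0.5, 1.5],
#' within-block trait correlation 0.8, noise SD 0.5.
#'
#' @param seed Seed stored in the scenario (required before generating).
#' @return A `sim_scenario`.
#' @export
default_scenario <- function(seed = NULL) {
  simulation_scenario(n = 100, J = 200, K = 50, n_feature_groups = 10,
                      n_trait_blocks = 5, support_frac = 0.05,
                      effect_range = c(0.5, 1.5), trait_cor = 0.8,
                      feature_cor = 0.5, sigma = 0.5, seed = seed)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("sim_scenario: n =", x$n, ", J =", x$J, "(", x$n_feature_groups,
      "groups ), K =", x$K, "(", x$n_trait_blocks, "blocks ), support",
      x$support_frac, ", sigma", x$sigma, "\n")
  invisible(x)
}

#' Generate a planted structured dataset from a scenario
#'
#' Features are equicorrelated within each group (a shared Gaussian group
#' factor). Every trait block is assigned a round-robin subset of the
#' feature groups; each trait in a block shares the block's support and
#' effect values, so within-block traits carry a common signal, on top of
#' block-correlated Gaussian noise. `Y = X B + E`, `E ~ N(0, sigma^2)` with
#' within-block noise correlation `trait_cor`. Both matrices are
#' standardized on output (the returned `B` is rescaled to the standardized
#' scale so that `Y ~ X B` still holds).
#'
#' @param scenario A `sim_scenario`; its `seed` must be set.
#' @return List with `X`, `Y` (standardized), `B` (J x K true coefficients
#'   on the standardized scale), `support` (logical J x K), `groups`
#'   (feature -> group), `blocks` (trait -> block), `trait_graph` (the true
#'   block structure's within-block edges with empirical correlations), and
#'   `scenario`.
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.null(scenario$seed)) stop("scenario$seed must be set")
  sc <- scenario
  if (sc$support_frac * sc$J * sc$K < 1) {
    stop("infeasible support: fraction * J * K < 1")
  }
  set.seed(sc$seed)
  sample_ids <- sprintf("s%03d", seq_len(sc$n))
  feature_ids <- sprintf("f%03d", seq_len(sc$J))
  trait_ids <- sprintf("t%03d", seq_len(sc$K))
  groups <- setNames(rep(seq_len(sc$n_feature_groups), length.out = sc$J)[
    order(rep(seq_len(sc$n_feature_groups), length.out = sc$J))], feature_ids)
  blocks <- setNames(rep(seq_len(sc$n_trait_blocks), length.out = sc$K)[
    order(rep(seq_len(sc$n_trait_blocks), length.out = sc$K))], trait_ids)

  # feature matrix: shared group factor -> equicorrelated columns
  rho_f <- sc$feature_cor
  Fg <- matrix(rnorm(sc$n * sc$n_feature_groups), sc$n)
  X <- matrix(rnorm(sc$n * sc$J), sc$n)
  for (j in seq_len(sc$J)) {
    X[, j] <- sqrt(rho_f) * Fg[, groups[j]] + sqrt(1 - rho_f) * X[, j]
  }
  dimnames(X) <- list(sample_ids, feature_ids)

  # sparse coefficients: per block, a shared support drawn from its groups
  per_trait <- max(1L, round(sc$support_frac * sc$J))
  group_of_block <- split(seq_len(sc$n_feature_groups),
                          rep(seq_len(sc$n_trait_blocks),
                              length.out = sc$n_feature_groups))
  B <- matrix(0, sc$J, sc$K, dimnames = list(feature_ids, trait_ids))
  for (b in seq_len(sc$n_trait_blocks)) {
    pool <- which(groups %in% group_of_block[[b]])
    sel <- sample(pool, min(per_trait, length(pool)))
    effects <- sample(c(-1, 1), length(sel), replace = TRUE) *
      runif(length(sel), sc$effect_range[1], sc$effect_range[2])
    B[sel, which(blocks == b)] <- effects
  }

  # block-correlated Gaussian noise
  rho_t <- sc$trait_cor
  Eb <- matrix(rnorm(sc$n * sc$n_trait_blocks), sc$n)
  E <- matrix(rnorm(sc$n * sc$K), sc$n)
  for (k in seq_len(sc$K)) {
    E[, k] <- sc$sigma * (sqrt(rho_t) * Eb[, blocks[k]] +
                            sqrt(1 - rho_t) * E[, k])
  }
  Y <- X %*% B + E
  dimnames(Y) <- list(sample_ids, trait_ids)

  sd_x <- apply(X, 2, sd)
  sd_y <- apply(Y, 2, sd)
  Xs <- standardize(X)
  Ys <- standardize(Y)
  B_std <- sweep(sweep(B, 1, sd_x, `*`), 2, sd_y, `/`)

  # trait graph from the true block structure, with empirical correlations
  R <- cor(Ys)
  edges <- do.call(rbind, lapply(seq_len(sc$n_trait_blocks), function(b) {
    tr <- names(blocks)[blocks == b]
    if (length(tr) < 2) return(NULL)
    cmb <- t(combn(tr, 2))
    data.frame(a = cmb[, 1], b = cmb[, 2],
               r = R[cbind(cmb[, 1], cmb[, 2])],
               w = abs(R[cbind(cmb[, 1], cmb[, 2])]),
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  graph <- structure(list(edges = edges, threshold = 0, trait_ids = trait_ids),
                     class = "trait_graph")

  list(X = Xs, Y = Ys, B = B_std, support = B != 0, groups = groups,
       blocks = blocks, trait_graph = graph, scenario = sc)
}
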