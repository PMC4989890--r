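#' Topological summary of a thresholded network
#'
#' Reports the properties conventionally tabulated for association
#' networks: node count, density `2E / (N(N-1))`, diameter of the largest
#' connected component, clustering coefficient (mean local transitivity
#' over nodes of degree >= 2; the global triangle-ratio variant is reported
#' alongside), mean degree `2E / N`, component count, and the scale-freeness
#' R-squared of the degree distribution when defined.
#'
#' @param edges An `edge_set` from [filter_edges()] (or a data.frame with
#'   columns `a`, `b`).
#' @return List of named properties.
#' @export
network_properties <- function(edges) {
  ed <- if (inherits(edges, "edge_set")) edges$edges else edges
  if (is.null(ed) || nrow(ed) == 0) stop("empty edge set")
  g <- igraph::graph_from_data_frame(ed[, c("a", "b")], directed = FALSE)
  N <- igraph::vcount(g)
  E <- igraph::ecount(g)
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  local_cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  eligible <- deg >= 2
  clustering <- if (any(eligible)) mean(local_cc[eligible]) else NA_real_
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  r2 <- tryCatch(degree_distribution_r2(edges), error = function(e) NA_real_)
  list(n_nodes = N,
       n_edges = E,
       density = 2 * E / (N * (N - 1)),
       diameter = igraph::diameter(giant, unconnected = FALSE),
       clustering_coefficient = clustering,
       clustering_global = igraph::transitivity(g, type = "global"),
       average_neighbors = 2 * E / N,
       connected_components = comp$no,
       degree_r2 = r2)
}

#' Scale-freeness R-squared of a degree distribution
#'
#' Least-squares fit of `log10(frequency)` on `log10(degree)` over the
#' distinct observed degrees (unbinned); returns the coefficient of
#' determination of that fit. A value near 1 indicates power-law-like
#' (scale-free) topology. Requires at least 3 distinct positive degrees.
#'
#' @param edges An `edge_set` or data.frame with columns `a`, `b`.
#' @return R-squared in [0, 1].
#' @export
degree_distribution_r2 <- function(edges) {
  ed <- if (inherits(edges, "edge_set")) edges$edges else edges
  if (is.null(ed) || nrow(ed) == 0) stop("empty edge set")
  deg <- table(c(ed$a, ed$b))
  freq <- table(as.integer(deg))
  d <- as.integer(names(freq))
  f <- as.integer(freq)
  ok <- d > 0 & f > 0
  if (sum(ok) < 3) stop("R^2 undefined: fewer than 3 distinct degrees")
  ly <- log10(f[ok])
  fit <- lm(ly ~ log10(d[ok]))
  tss <- sum((ly - mean(ly))^2)
  if (tss == 0) stop("R^2 undefined: constant log-frequency")
  1 - sum(fit$residuals^2) / tss
}

#' Bonferroni-thresholded correlation network baseline
#'
#' All-pairs Pearson correlation tests between the columns of a data matrix
#' (t statistic on n - 2 degrees of freedom); an edge is kept when its
#' p-value is below `p_threshold` divided by the number of possible pairs.
#' Edge weights are |r|. This is the conventional correlation-network
#' baseline the regression networks are compared against; it works on the
#' data matrix directly, not on regression coefficients.
#'
#' @param M Numeric matrix, samples by variables (n >= 4).
#' @param p_threshold Per-family significance level before the Bonferroni
#'   division (default 0.01).
#' @return An `edge_set`.
#' @export
correlation_network <- function(M, p_threshold = 0.01) {
  stopifnot(is.matrix(M))
  n <- nrow(M)
  if (n < 4) stop("need at least 4 samples")
  sds <- apply(M, 2, sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0), " constant column(s)")
    M <- M[, sds > 0, drop = FALSE]
  }
  N <- ncol(M)
  if (N < 2) stop("need at least 2 non-constant variables")
  ids <- colnames(M)
  if (is.null(ids)) ids <- paste0("v", seq_len(N))
  R <- cor(M)
  rr <- pmin(pmax(R, -1 + 1e-15), 1 - 1e-15)
  tstat <- rr * sqrt((n - 2) / (1 - rr^2))
  pval <- 2 * pt(-abs(tstat), df = n - 2)
  cut <- p_threshold / (N * (N - 1) / 2)
  keep <- which(upper.tri(R) & pval < cut, arr.ind = TRUE)
  edges <- data.frame(a = ids[keep[, 1]], b = ids[keep[, 2]],
                      w = abs(R[keep]), stringsAsFactors = FALSE)
  if (nrow(edges)) edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$a, edges$b)))
  comp <- integer(0)
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("a", "b")],
                                       directed = FALSE, vertices = nodes)
    comp <- igraph::components(g)$membership
  }
  structure(list(edges = edges, nodes = nodes,
                 n_isolated = N - length(nodes),
                 components = comp, cutoff = NA_real_),
            class = "edge_set")
}

#' Overlap of the top-k strongest coefficients across methods
#'
#' For each coefficient matrix, the k (feature, trait) pairs with largest
#' |beta| are collected (ties at the boundary broken by lexicographic
#' (feature, trait) order, deterministically); the features appearing in
#' those pairs form each method's top set. All 2-way and higher-order
#' intersection sizes are reported, along with the count of features
#' identified by at least three methods.
#'
#' @param B_list Named list of coefficient matrices (or `irnet_fit`s) over
#'   identical feature/trait ids.
#' @param k Number of top pairs per method.
#' @return List with `sets` (per-method feature vectors), `pairs`
#'   (per-method data.frames of the top pairs), `intersections` (named
#'   sizes for every combination of >= 2 methods), `at_least_3`, `k`.
#' @export
top_k_overlap <- function(B_list, k = 200) {
  stopifnot(is.list(B_list), length(B_list) >= 2, k >= 1)
  B_list <- lapply(B_list, function(B) if (inherits(B, "irnet_fit")) B$beta else B)
  ref <- B_list[[1]]
  for (B in B_list) {
    if (!identical(dim(B), dim(ref)) ||
        !identical(dimnames(B), dimnames(ref))) {
      stop("coefficient matrices must share feature and trait ids")
    }
  }
  if (k > length(ref)) stop("k exceeds the number of coefficients")
  nm <- names(B_list)
  if (is.null(nm)) nm <- paste0("method", seq_along(B_list))
  top_pairs <- function(B) {
    fid <- rownames(B)[row(B)]
    tid <- colnames(B)[col(B)]
    ord <- order(-abs(as.vector(B)), fid, tid)
    idx <- ord[seq_len(k)]
    data.frame(feature = fid[idx], trait = tid[idx],
               beta = as.vector(B)[idx], stringsAsFactors = FALSE)
  }
  pairs <- lapply(B_list, top_pairs)
  sets <- lapply(pairs, function(p) unique(p$feature))
  names(pairs) <- names(sets) <- nm
  m <- length(sets)
  inter <- list()
  for (size in 2:m) {
    for (cmb in as.data.frame(combn(m, size))) {
      key <- paste(nm[cmb], collapse = "&")
      inter[[key]] <- length(Reduce(intersect, sets[cmb]))
    }
  }
  counts <- table(unlist(lapply(sets, unique)))
  list(sets = sets, pairs = pairs, intersections = unlist(inter),
       at_least_3 = sum(counts >= 3), k = k)
}
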