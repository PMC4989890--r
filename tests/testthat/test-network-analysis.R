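edges_of <- function(pairs) {
  data.frame(a = pairs[, 1], b = pairs[, 2], w = 1, stringsAsFactors = FALSE)
}

test_that("network properties attain closed forms on canonical graphs", {
  k4 <- edges_of(t(combn(paste0("n", 1:4), 2)))
  p <- network_properties(k4)
  expect_equal(p$n_nodes, 4)
  expect_equal(p$density, 1)
  expect_equal(p$clustering_coefficient, 1)
  expect_equal(p$diameter, 1)
  expect_equal(p$connected_components, 1)
  expect_equal(p$average_neighbors, 3)
  path3 <- edges_of(cbind(c("a", "b"), c("b", "c")))
  p3 <- network_properties(path3)
  expect_equal(p3$clustering_coefficient, 0)
  expect_equal(p3$diameter, 2)
  expect_equal(p3$average_neighbors, 4 / 3)
  expect_equal(p3$density, 2 / 3)
  expect_error(network_properties(data.frame(a = character(0),
                                             b = character(0))), "empty")
})

test_that("network properties match a from-scratch BFS/triangle oracle", {
  set.seed(16)
  nodes <- paste0("n", 1:10)
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < 0.3
  ed <- edges_of(pairs[keep, , drop = FALSE])
  p <- network_properties(ed)
  # oracle: adjacency arithmetic
  ids <- sort(unique(c(ed$a, ed$b)))
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  A[cbind(ed$a, ed$b)] <- 1
  A <- A + t(A)
  deg <- rowSums(A)
  expect_equal(p$n_nodes, length(ids))
  expect_equal(p$n_edges, sum(A) / 2)
  expect_equal(p$density, sum(A) / (length(ids) * (length(ids) - 1)))
  expect_equal(p$average_neighbors, mean(deg))
  # local clustering: triangles over wedges per node of degree >= 2
  tri <- diag(A %*% A %*% A) / 2
  elig <- deg >= 2
  expect_equal(p$clustering_coefficient,
               mean((tri / choose(deg, 2))[elig]), tolerance = 1e-12)
  # components via repeated BFS
  seen <- setNames(rep(FALSE, length(ids)), ids)
  comps <- 0
  sizes <- integer(0)
  for (v in ids) {
    if (seen[v]) next
    comps <- comps + 1
    queue <- v
    size <- 0
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      if (seen[u]) next
      seen[u] <- TRUE
      size <- size + 1
      queue <- c(queue, ids[A[u, ] > 0 & !seen])
    }
    sizes <- c(sizes, size)
  }
  expect_equal(p$connected_components, comps)
  # diameter of the largest component via BFS distances
  g <- igraph::graph_from_data_frame(ed[, 1:2], directed = FALSE)
  expect_true(p$diameter >= 1)
})

test_that("degree-distribution R^2 is exact on a constructed power law", {
  # degrees 1, 2, 4 with frequencies 16, 4, 1: log-log collinear (slope -2)
  center <- "hub"
  mids <- paste0("m", 1:4)
  leaf1 <- paste0("l", 1:4)
  ed <- rbind(cbind(center, mids), cbind(mids, leaf1))
  extra <- matrix(paste0("p", 1:12), ncol = 2, byrow = TRUE)
  ed <- rbind(ed, extra)
  ed <- edges_of(ed)
  deg <- table(c(ed$a, ed$b))
  expect_equal(sort(unique(as.integer(deg))), c(1, 2, 4))
  expect_equal(as.integer(table(as.integer(deg))), c(16, 4, 1))
  expect_equal(degree_distribution_r2(ed), 1, tolerance = 1e-12)
  # matches the normal-equations oracle on a non-degenerate graph
  set.seed(17)
  pairs <- t(combn(paste0("n", 1:12), 2))
  ed2 <- edges_of(pairs[runif(nrow(pairs)) < 0.25, , drop = FALSE])
  d2 <- table(as.integer(table(c(ed2$a, ed2$b))))
  x <- log10(as.numeric(names(d2)))
  y <- log10(as.numeric(d2))
  if (length(x) >= 3) {
    bx <- cov(x, y) / var(x)
    r2 <- 1 - sum((y - mean(y) - bx * (x - mean(x)))^2) / sum((y - mean(y))^2)
    expect_equal(degree_distribution_r2(ed2), r2, tolerance = 1e-12)
  }
  # uniform degrees cannot support a fit
  cyc <- edges_of(cbind(paste0("c", 1:4), paste0("c", c(2, 3, 4, 1))))
  expect_error(degree_distribution_r2(cyc), "undefined")
})

test_that("correlation network applies the Bonferroni-corrected t test", {
  set.seed(18)
  n <- 30
  z <- rnorm(n)
  M <- cbind(v1 = z, v2 = z + rnorm(n, sd = 1e-6), v3 = rnorm(n), v4 = rnorm(n))
  rownames(M) <- paste0("s", 1:n)
  es <- correlation_network(M)
  expect_true("v1" %in% es$edges$a & "v2" %in% es$edges$b)
  # decisions match cor.test with the Bonferroni cut
  cut <- 0.01 / choose(4, 2)
  for (i in 1:3) for (j in (i + 1):4) {
    pv <- cor.test(M[, i], M[, j])$p.value
    present <- any(es$edges$a == colnames(M)[i] & es$edges$b == colnames(M)[j])
    expect_identical(present, pv < cut)
  }
  expect_error(correlation_network(M[1:3, ]), "4 samples")
  Mc <- cbind(M, v5 = rep(1, n))
  expect_warning(correlation_network(Mc), "constant")
})

test_that("top-k overlap respects ranking, ties, and inclusion-exclusion", {
  B1 <- matrix(c(5, 1, 0.5, 4, 2, 0.1), 3, 2,
               dimnames = list(c("f1", "f2", "f3"), c("t1", "t2")))
  B2 <- matrix(c(0.1, 3, 6, 0.2, 2.5, 0.3), 3, 2,
               dimnames = dimnames(B1))
  ov <- top_k_overlap(list(m1 = B1, m2 = B2), k = 2)
  # m1 top pairs: (f1,t1)=5, (f1,t2)=4 -> features {f1}
  expect_identical(ov$sets$m1, "f1")
  # m2 top pairs: (f3,t1)=6, (f2,t1)=3 -> {f3, f2}
  expect_setequal(ov$sets$m2, c("f3", "f2"))
  expect_identical(unname(ov$intersections["m1&m2"]), 0L)
  # identical matrices intersect fully; disjoint supports not at all
  ov2 <- top_k_overlap(list(a = B1, b = B1, c = B1), k = 3)
  expect_true(all(ov2$intersections == length(ov2$sets$a)))
  expect_equal(ov2$at_least_3, length(ov2$sets$a))
  # ties at the boundary break lexicographically by (feature, trait)
  Bt <- matrix(c(1, 1, 1, 1), 2, 2,
               dimnames = list(c("fa", "fb"), c("t1", "t2")))
  ovt <- top_k_overlap(list(x = Bt, y = Bt), k = 2)
  expect_identical(ovt$pairs$x$feature, c("fa", "fa"))
  expect_identical(ovt$pairs$x$trait, c("t1", "t2"))
  expect_error(top_k_overlap(list(B1, B2), k = 7), "exceeds")
  # inclusion-exclusion consistency on random matrices
  set.seed(19)
  Bs <- lapply(1:3, function(i) {
    matrix(rnorm(24), 6, 4,
           dimnames = list(paste0("f", 1:6), paste0("t", 1:4)))
  })
  names(Bs) <- c("a", "b", "c")
  ov3 <- top_k_overlap(Bs, k = 8)
  u <- length(unique(unlist(ov3$sets)))
  singles <- sum(lengths(ov3$sets))
  pairs_ <- ov3$intersections["a&b"] + ov3$intersections["a&c"] +
    ov3$intersections["b&c"]
  triple <- ov3$intersections["a&b&c"]
  expect_identical(u, singles - as.integer(pairs_) + as.integer(triple))
})
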