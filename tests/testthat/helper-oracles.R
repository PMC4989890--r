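# Independent brute-force minimizer for small (d <= 4) nonsmooth objectives:
# a coarse grid scan followed by Nelder-Mead refinement from the best grid
# points. Used to audit the solvers' objective values.
brute_minimize <- function(obj, d, lower = -2, upper = 2, step = 0.25,
                           n_refine = 3) {
  pts <- as.matrix(expand.grid(rep(list(seq(lower, upper, by = step)), d)))
  vals <- apply(pts, 1, obj)
  starts <- pts[order(vals)[seq_len(n_refine)], , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ], obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o2 <- optim(o$par, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o2$value)
  }
  best
}

# rank-based AUC, written independently of support_auc
oracle_auc <- function(score, truth) {
  pos <- score[truth]
  neg <- score[!truth]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
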