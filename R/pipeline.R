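#' Fit all four regression methods with their standard tuning procedures
#'
#' Applies, on one paired dataset: the lasso with its penalty chosen by
#' k-fold cross-validation; the graph-guided fused lasso started from the
#' median-nonzero-coefficient heuristic and explored over the half/base/
#' double lambda-gamma grid on a held-out validation quarter; the sparse
#' group lasso (alpha = 0.1) cross-validated over its short geometric path
#' (down to 0.8 of lambda_max); and the jointly structured solver with its
#' penalty triple at the 1:3:2 ratio of the standard tuned values, scaled
#' by a validation scan. Structure priors (trait graph at |r| >= 0.7,
#' feature/trait groups by Ward clustering) are built from the data itself.
#'
#' @param X,Y Standardized training matrices.
#' @param seed Seed driving fold assignment and the validation split.
#' @param n_groups Clustering groups for features and traits (default 20).
#' @param cor_threshold Trait-graph correlation threshold (default 0.7).
#' @param folds CV folds.
#' @param tol,maxit Final-fit solver controls.
#' @param tune_maxit Iteration cap during tuning fits.
#' @return Named list of `irnet_fit`s (`lasso`, `gflasso`, `sgl`, `siol`)
#'   plus `priors` (graph and groups) and `tuning` records.
#' @export
fit_all_methods <- function(X, Y, seed, n_groups = 20, cor_threshold = 0.7,
                            folds = 5, tol = 1e-6, maxit = 4000,
                            tune_maxit = 2000, sgl_min_fraction = 0.02,
                            sgl_n_lambda = 12) {
  check_paired(X, Y)
  graph <- build_trait_graph(Y, cor_threshold)
  Gf <- cluster_features(X, min(n_groups, ncol(X)))
  Ht <- cluster_features(Y, min(n_groups, ncol(Y)))

  cv <- select_lambda_cv("lasso", X, Y, folds = folds, seed = seed,
                         tol = tol * 10, maxit = tune_maxit)
  lasso <- fit_lasso(X, Y, cv$best_lambda, tol = tol, maxit = maxit)

  n <- nrow(X)
  val <- local({
    set.seed(seed + 1)
    sample(n, max(2, round(n / 4)))
  })
  Xtr <- X[-val, , drop = FALSE]
  Ytr <- Y[-val, , drop = FALSE]
  Xv <- X[val, , drop = FALSE]
  Yv <- Y[val, , drop = FALSE]

  # coordinate exploration around the heuristic start: lambda first at
  # fixed gamma, then gamma at the chosen lambda, scored on validation MSE
  heur <- gflasso_lambda_heuristic(lasso, ncol(Y))
  mult <- c(0.25, 0.5, 1, 2, 4)
  try_gfl <- function(lam, gam, warm) {
    f <- fit_gflasso(Xtr, Ytr, graph, lam, gam, tol = tol * 10,
                     maxit = tune_maxit, beta_init = warm)
    list(mse = evaluate_mse(f, Xv, Yv)$mean, beta = f$beta)
  }
  gfl_grid <- data.frame(lambda = numeric(0), gamma = numeric(0),
                         val_mse = numeric(0))
  warm <- NULL
  lam_best <- heur$lambda
  best_mse <- Inf
  for (m_ in mult) {
    r <- try_gfl(heur$lambda * m_, heur$gamma, warm)
    warm <- r$beta
    gfl_grid[nrow(gfl_grid) + 1, ] <- c(heur$lambda * m_, heur$gamma, r$mse)
    if (r$mse < best_mse) {
      best_mse <- r$mse
      lam_best <- heur$lambda * m_
    }
  }
  gam_best <- heur$gamma
  for (m_ in setdiff(mult, 1)) {
    r <- try_gfl(lam_best, heur$gamma * m_, warm)
    warm <- r$beta
    gfl_grid[nrow(gfl_grid) + 1, ] <- c(lam_best, heur$gamma * m_, r$mse)
    if (r$mse < best_mse) {
      best_mse <- r$mse
      gam_best <- heur$gamma * m_
    }
  }
  gfl <- fit_gflasso(X, Y, graph, lam_best, gam_best, tol = tol,
                     maxit = maxit)

  defs <- penalty_defaults()
  cvs <- select_lambda_cv("sgl", X, Y, folds = folds, seed = seed,
                          groups = Gf, alpha = defs$sgl$alpha,
                          n_lambda = sgl_n_lambda,
                          lambda_min_fraction = sgl_min_fraction,
                          tol = tol * 10, maxit = tune_maxit)
  sgl <- fit_sgl(X, Y, Gf, cvs$best_lambda, defs$sgl$alpha,
                 tol = tol, maxit = maxit)

  # per-dataset tuning of the penalty triple: first a common scale at the
  # standard 1:3:2 ratio (anchored at the entry-wise all-zero threshold),
  # then the weight of the two group terms at the chosen scale
  Xc <- sweep(Xtr, 2, colMeans(Xtr))
  Yc <- sweep(Ytr, 2, colMeans(Ytr))
  l1max <- max(abs(crossprod(Xc, Yc)))
  ratio <- c(defs$siol$lambda1, defs$siol$lambda2, defs$siol$lambda3) /
    defs$siol$lambda1
  try_siol <- function(l1, l2, l3, warm) {
    f <- fit_siol(Xtr, Ytr, Gf, Ht, l1, l2, l3, tol = tol * 10,
                  maxit = tune_maxit, beta_init = warm)
    list(mse = evaluate_mse(f, Xv, Yv)$mean, beta = f$beta)
  }
  siol_tab <- expand.grid(scale = l1max * c(0.00125, 0.0025, 0.005,
                                            0.01, 0.02, 0.04),
                          gmult = c(0, 0.5, 1, 2))
  siol_tab$val_mse <- NA_real_
  siol_tab <- siol_tab[order(-siol_tab$scale, siol_tab$gmult), ]
  warm <- NULL
  for (i in seq_len(nrow(siol_tab))) {
    s <- siol_tab$scale[i]
    gm <- siol_tab$gmult[i]
    r <- try_siol(s * ratio[1], gm * s * ratio[2], gm * s * ratio[3], warm)
    warm <- r$beta
    siol_tab$val_mse[i] <- r$mse
  }
  ibest <- which.min(siol_tab$val_mse)
  sbest <- siol_tab$scale[ibest]
  gbest <- siol_tab$gmult[ibest]
  siol <- fit_siol(X, Y, Gf, Ht, sbest * ratio[1], gbest * sbest * ratio[2],
                   gbest * sbest * ratio[3], tol = tol, maxit = maxit)

  list(lasso = lasso, gflasso = gfl, sgl = sgl, siol = siol,
       priors = list(graph = graph, feature_groups = Gf, trait_groups = Ht),
       tuning = list(lasso_cv = cv$table, gflasso_grid = gfl_grid,
                     sgl_cv = cvs$table, siol_scan = siol_tab))
}

#' Train/test comparison of the four regression methods
#'
#' Generates a scenario dataset, splits samples 2/3 train, 1/3 test, fits
#' all four methods on the training part with their tuning procedures, and
#' reports per-method mean test MSE (smaller is better).
#'
#' @param scenario A `sim_scenario` with its seed set.
#' @param train_frac Training fraction (default 2/3).
#' @param ... Passed to [fit_all_methods()].
#' @return List with `mse` (named vector over methods), `fits`, `data`,
#'   `train` (row indices).
#' @export
compare_methods <- function(scenario, train_frac = 2 / 3, ...) {
  dat <- generate_scenario(scenario)
  n <- nrow(dat$X)
  train <- local({
    set.seed(scenario$seed + 5)
    sort(sample(n, round(train_frac * n)))
  })
  Xtr <- dat$X[train, , drop = FALSE]
  Ytr <- dat$Y[train, , drop = FALSE]
  Xte <- dat$X[-train, , drop = FALSE]
  Yte <- dat$Y[-train, , drop = FALSE]
  fits <- fit_all_methods(Xtr, Ytr, seed = scenario$seed + 7, ...)
  methods <- c("lasso", "gflasso", "sgl", "siol")
  mse <- vapply(methods, function(m) evaluate_mse(fits[[m]], Xte, Yte)$mean, 0)
  list(mse = mse, fits = fits, data = dat, train = train)
}

pipeline_defaults <- function() {
  list(seed = NULL, out_dir = NULL, scenario = NULL,
       x_path = NULL, y_path = NULL, sep = "\t",
       K = 20, alpha = 0.5, t = 20, n_perm = 100,
       n_groups = 20, cor_threshold = 0.7, folds = 5,
       grid_search = FALSE, tol = 1e-6, maxit = 4000, tune_maxit = 800)
}

#' Run the full integrative regression network pipeline
#'
#' Stages, in order: load (or simulate) the paired matrices; fit the four
#' regressions with their tuning procedures; build feature-side and
#' trait-side affinity networks from each coefficient matrix; fuse the four
#' networks per side; find the permutation cutoff for each individual and
#' fused network; filter the fused networks and summarize their topology.
#' Every intermediate is written under `out_dir` along with the resolved
#' configuration.
#'
#' Sub-seeds are derived from the master seed by fixed offsets (simulation:
#' seed; tuning: seed + 7; permutations: seed + 1000 * stage index), so
#' stages are independently reproducible.
#'
#' @param config Named list (or path to a YAML file) with keys among:
#'   `seed` (required), `out_dir`, `scenario` (a `sim_scenario` or list of
#'   its arguments) or `x_path`/`y_path` (delimited matrices), `sep`, `K`,
#'   `alpha`, `t`, `n_perm`, `n_groups`, `cor_threshold`, `folds`,
#'   `grid_search` (select K/alpha by consensus score), `tol`, `maxit`,
#'   `tune_maxit`. Unknown keys are rejected.
#' @return Invisible list with `fits`, `networks`, `fused`, `cutoffs`,
#'   `edge_sets`, `reports`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("config$seed is required")
  out <- cfg$out_dir
  persist <- !is.null(out)
  if (persist && !dir.exists(out)) dir.create(out, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dat <- stage("data", {
    if (!is.null(cfg$scenario)) {
      sc <- cfg$scenario
      if (!inherits(sc, "sim_scenario")) {
        sc$seed <- sc$seed %||% cfg$seed
        sc <- do.call(simulation_scenario, sc)
      }
      if (is.null(sc$seed)) sc$seed <- cfg$seed
      generate_scenario(sc)
    } else {
      if (is.null(cfg$x_path) || is.null(cfg$y_path)) {
        stop("either a scenario or x_path/y_path must be given")
      }
      if (!file.exists(cfg$x_path)) stop("missing input: ", cfg$x_path)
      if (!file.exists(cfg$y_path)) stop("missing input: ", cfg$y_path)
      X <- standardize(read_matrix(cfg$x_path, cfg$sep))
      Y <- standardize(read_matrix(cfg$y_path, cfg$sep))
      check_paired(X, Y)
      list(X = X, Y = Y)
    }
  })

  fits <- stage("fit", fit_all_methods(
    dat$X, dat$Y, seed = cfg$seed + 7, n_groups = cfg$n_groups,
    cor_threshold = cfg$cor_threshold, folds = cfg$folds, tol = cfg$tol,
    maxit = cfg$maxit, tune_maxit = cfg$tune_maxit))
  methods <- c("lasso", "gflasso", "sgl", "siol")

  params <- list(feature = list(K = cfg$K, alpha = cfg$alpha),
                 trait = list(K = cfg$K, alpha = cfg$alpha))
  if (isTRUE(cfg$grid_search)) {
    for (side in c("feature", "trait")) {
      sel <- stage("grid_search", select_k_alpha(
        lapply(fits[methods], `[[`, "beta"), side = side, t = cfg$t))
      params[[side]] <- list(K = sel$K, alpha = sel$alpha)
    }
  }

  networks <- stage("network", {
    res <- list()
    for (side in c("feature", "trait")) {
      res[[side]] <- lapply(fits[methods], function(f) {
        coefficient_affinity(f$beta, side = side, K = params[[side]]$K,
                             alpha = params[[side]]$alpha)
      })
    }
    res
  })

  fused <- stage("fuse", lapply(networks, function(ws) {
    snf_fuse(ws, K = params[[attr(ws[[1]], "side")]]$K, t = cfg$t)
  }))

  cutoffs <- stage("cutoff", {
    res <- list()
    si <- 0
    for (side in c("feature", "trait")) {
      side_res <- list()
      for (m in methods) {
        si <- si + 1
        side_res[[m]] <- find_cutoff(networks[[side]][[m]],
                                     n_perm = cfg$n_perm,
                                     seed = cfg$seed + 1000 * si)
      }
      si <- si + 1
      side_res$fused <- find_cutoff(fused[[side]], n_perm = cfg$n_perm,
                                    seed = cfg$seed + 1000 * si)
      res[[side]] <- side_res
    }
    res
  })

  edge_sets <- stage("filter", lapply(c(feature = "feature", trait = "trait"),
                                      function(side) {
    filter_edges(fused[[side]], cutoffs[[side]]$fused$cutoff)
  }))

  reports <- stage("analyze", lapply(c(feature = "feature", trait = "trait"),
                                     function(side) {
    counts <- c(vapply(methods, function(m) {
      nrow(filter_edges(networks[[side]][[m]],
                        cutoffs[[side]][[m]]$cutoff)$edges)
    }, 0L), fused = nrow(edge_sets[[side]]$edges))
    props <- tryCatch(network_properties(edge_sets[[side]]),
                      error = function(e) NULL)
    list(post_cutoff_edge_counts = as.list(counts),
         cutoffs = lapply(cutoffs[[side]], `[[`, "cutoff"),
         fused_properties = props,
         affinity_params = params[[side]])
  }))

  if (persist) {
    stage("persist", {
      for (m in methods) {
        write_matrix(fits[[m]]$beta, file.path(out, paste0("coef_", m, ".tsv")))
        for (side in c("feature", "trait")) {
          write_matrix(networks[[side]][[m]],
                       file.path(out, paste0("affinity_", m, "_", side, ".tsv")))
        }
      }
      for (side in c("feature", "trait")) {
        write_matrix(fused[[side]], file.path(out, paste0("fused_", side, ".tsv")))
        write_edge_list(edge_sets[[side]],
                        file.path(out, paste0("edges_fused_", side, ".tsv")))
        write_sif(edge_sets[[side]],
                  file.path(out, paste0("edges_fused_", side, ".sif")))
        jsonlite::write_json(reports[[side]],
                             file.path(out, paste0("report_", side, ".json")),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
      cfg_out <- cfg
      cfg_out$scenario <- if (!is.null(cfg$scenario)) unclass(dat$scenario)
      yaml::write_yaml(cfg_out, file.path(out, "config_resolved.yaml"))
    })
  }

  invisible(list(data = dat, fits = fits, networks = networks, fused = fused,
                 cutoffs = cutoffs, edge_sets = edge_sets, reports = reports,
                 config = cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
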