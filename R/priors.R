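#' Build the trait correlation graph consumed by the fused-lasso penalty
#'
#' Connects every pair of traits whose absolute Pearson correlation reaches
#' the threshold. The signed correlation r is kept (it sets the sign with
#' which coefficients are fused) and the fusion weight is f(r) = |r|, which
#' is therefore always at least the threshold.
#'
#' @param Y Standardized trait matrix (samples by traits, colnames required).
#' @param threshold Absolute-correlation threshold in (0, 1]; default 0.7.
#' @return An object of class `trait_graph`: list with `edges` (data.frame
#'   `a`, `b`, `r`, `w`), `threshold`, `trait_ids`.
#' @export
build_trait_graph <- function(Y, threshold = 0.7) {
  stopifnot(is.matrix(Y))
  if (ncol(Y) < 2) stop("need at least 2 traits to build a trait graph")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  ids <- colnames(Y)
  if (is.null(ids)) ids <- paste0("t", seq_len(ncol(Y)))
  R <- cor(Y)
  keep <- which(abs(R) >= threshold & upper.tri(R), arr.ind = TRUE)
  edges <- data.frame(a = ids[keep[, 1]], b = ids[keep[, 2]],
                      r = R[keep], w = abs(R[keep]),
                      stringsAsFactors = FALSE)
  if (nrow(edges)) edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, threshold = threshold, trait_ids = ids),
            class = "trait_graph")
}

#' @export
print.trait_graph <- function(x, ...) {
  cat("trait_graph:", nrow(x$edges), "edges over", length(x$trait_ids),
      "traits (|r| >=", x$threshold, ")\n")
  invisible(x)
}

#' Partition variables into groups by hierarchical clustering
#'
#' Column vectors are clustered by Euclidean distance with Ward linkage
#' (`hclust` method `"ward.D2"`) and the tree is cut at `n_groups` clusters.
#' Used to define the feature groups of the sparse group lasso and, applied
#' to the trait matrix, the trait groups of the jointly structured solver.
#'
#' @param X Standardized matrix whose columns are the variables to group.
#' @param n_groups Number of groups (1..ncol(X)); the pipeline default is 20.
#' @return Named integer vector mapping each variable to a group in
#'   `1..n_groups`.
#' @export
cluster_features <- function(X, n_groups = 20) {
  stopifnot(is.matrix(X))
  J <- ncol(X)
  if (n_groups < 1) stop("n_groups must be >= 1")
  if (n_groups > J) stop("n_groups exceeds the number of variables")
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("v", seq_len(J))
  if (n_groups == J) return(setNames(seq_len(J), ids))
  hc <- hclust(dist(t(X)), method = "ward.D2")
  setNames(as.integer(cutree(hc, k = n_groups)), ids)
}

#' Validate a group assignment against a set of variable ids
#'
#' @param groups Named integer vector (variable -> group).
#' @param ids Character vector of variable ids the groups must partition.
#' @return The assignment re-ordered to `ids`, with dense group indices.
#' @keywords internal
check_groups <- function(groups, ids) {
  unknown <- setdiff(names(groups), ids)
  if (length(unknown)) {
    stop("group assignment references unknown variables: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  missing <- setdiff(ids, names(groups))
  if (length(missing)) {
    stop("variables without a group: ", paste(head(missing, 5), collapse = ", "))
  }
  g <- groups[ids]
  lev <- sort(unique(g))
  setNames(match(g, lev), ids)
}

#' Read / write group assignments as 2-column TSV
#'
#' @param path File path.
#' @param sep Field delimiter.
#' @return `read_groups` returns a named integer vector; `write_groups`
#'   returns `path` invisibly.
#' @export
read_groups <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("group file needs 2 columns (id, group): ", path)
  setNames(as.integer(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_groups
#' @param groups Named integer vector (variable -> group).
#' @export
write_groups <- function(groups, path, sep = "\t") {
  df <- data.frame(id = names(groups), group = as.integer(groups))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
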