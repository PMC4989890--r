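#' Read a sample-by-variable numeric matrix from delimited text
#'
#' The expected layout is a header row of variable labels and a first column
#' of sample labels, tab-delimited by default. Duplicate labels, ragged rows,
#' missing or non-numeric cells are rejected: downstream regression assumes a
#' complete numeric matrix.
#'
#' @param path Path to the delimited text file.
#' @param sep Field delimiter, `"\t"` (default) or `","`.
#' @return A numeric matrix with sample rownames and variable colnames.
#' @export
read_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = sep, header = TRUE, row.names = NULL,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs a label column plus >=1 value column: ", path)
  labels <- as.character(df[[1]])
  if (anyDuplicated(labels)) stop("duplicate row labels in ", path)
  if (anyDuplicated(colnames(df)[-1])) stop("duplicate column labels in ", path)
  vals <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(labels, colnames(df)[-1]))
  for (j in seq_len(ncol(vals))) {
    col <- vals[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop("non-numeric or missing cell in ", path, " at data row ", bad[1],
           ", column '", colnames(df)[-1][j], "'")
    }
    m[, j] <- num
  }
  m
}

#' Write a labelled numeric matrix as delimited text
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param sep Field delimiter.
#' @param label Name for the row-label column header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, sep = "\t", label = "id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- label
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weighted edge list (node_a, node_b, weight TSV)
#'
#' @param path Path to a 3-column delimited file with a header row.
#' @param sep Field delimiter.
#' @return A data.frame with columns `a`, `b`, `w`.
#' @export
read_edge_list <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("edge list needs 3 columns (node_a, node_b, weight): ", path)
  out <- data.frame(a = as.character(df[[1]]), b = as.character(df[[2]]),
                    w = as.numeric(df[[3]]), stringsAsFactors = FALSE)
  if (anyNA(out$w)) stop("non-numeric weight in ", path)
  out
}

#' Write a weighted edge list
#'
#' @param edges Data.frame with columns `a`, `b`, `w` (an [filter_edges()]
#'   result's `$edges` component works directly).
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, sep = "\t") {
  if (inherits(edges, "edge_set")) edges <- edges$edges
  df <- data.frame(node_a = edges$a, node_b = edges$b, weight = edges$w)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export edges in Cytoscape SIF format
#'
#' One line per edge, `"node_a <relation> node_b"`, for import into network
#' viewers.
#'
#' @param edges Data.frame with columns `a`, `b` (weights ignored) or an
#'   [filter_edges()] result.
#' @param path Output path.
#' @param relation Interaction type string placed between the node labels.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path, relation = "aff") {
  if (inherits(edges, "edge_set")) edges <- edges$edges
  writeLines(paste(edges$a, relation, edges$b), path)
  invisible(path)
}

#' Standardize matrix columns to mean zero, unit standard deviation
#'
#' Each column is centred and scaled by its sample standard deviation
#' (denominator n - 1). This is the preprocessing applied to both the feature
#' and the trait matrix before any regression, so that features measured on
#' different scales contribute without bias.
#'
#' @param m Numeric matrix (samples in rows).
#' @return The standardized matrix, same dimnames.
#' @export
standardize <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (anyNA(m)) stop("missing values are not allowed")
  sds <- apply(m, 2, sd)
  if (any(sds <= 0 | !is.finite(sds))) {
    bad <- colnames(m)[which(sds <= 0 | !is.finite(sds))[1]]
    if (is.null(bad)) bad <- which(sds <= 0)[1]
    stop("constant column cannot be standardized: ", bad)
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Collapse probe-level values to gene-level features by averaging
#'
#' Probe columns mapping to the same gene are replaced by their per-sample
#' arithmetic mean, giving one column per gene. Genes are ordered
#' lexicographically. A probe must map to exactly one gene.
#'
#' @param probes Numeric matrix, samples by probes, with probe colnames.
#' @param probe_to_gene Named character vector mapping probe label to gene
#'   label; must cover every probe column.
#' @return Samples-by-genes numeric matrix.
#' @export
average_probes_to_genes <- function(probes, probe_to_gene) {
  stopifnot(is.matrix(probes), !is.null(colnames(probes)))
  if (length(probe_to_gene) == 0) stop("no probes mapped")
  missing <- setdiff(colnames(probes), names(probe_to_gene))
  if (length(missing)) {
    stop("probes without a gene mapping: ", paste(head(missing, 5), collapse = ", "))
  }
  genes <- sort(unique(unname(probe_to_gene[colnames(probes)])))
  out <- matrix(NA_real_, nrow(probes), length(genes),
                dimnames = list(rownames(probes), genes))
  for (g in genes) {
    cols <- colnames(probes)[probe_to_gene[colnames(probes)] == g]
    out[, g] <- rowMeans(probes[, cols, drop = FALSE])
  }
  out
}

#' Restrict matrices to their common variables
#'
#' Each matrix is reduced to the intersection of all column label sets, in a
#' common (lexicographic) order, so that per-variable results are comparable
#' across datasets.
#'
#' @param mats List of >= 2 labelled numeric matrices.
#' @return List of matrices restricted to the shared columns.
#' @export
intersect_common <- function(mats) {
  stopifnot(is.list(mats), length(mats) >= 2)
  common <- Reduce(intersect, lapply(mats, colnames))
  if (length(common) == 0) stop("no common variables across matrices")
  common <- sort(common)
  lapply(mats, function(m) m[, common, drop = FALSE])
}

#' Check that two matrices are a paired feature/trait dataset
#'
#' @param X,Y Numeric matrices over the same samples, in the same row order.
#' @return Invisibly `TRUE`; errors otherwise.
#' @keywords internal
check_paired <- function(X, Y) {
  if (nrow(X) != nrow(Y)) stop("X and Y have different sample counts")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y))) {
    stop("X and Y sample ids differ in content or order")
  }
  invisible(TRUE)
}
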