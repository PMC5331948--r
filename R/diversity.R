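#' Presence/absence matrix of TE families
#'
#' Reduces a simulation result (or a raw copies matrix) to a species x
#' family logical incidence matrix: the emergent summary of the TE flow on
#' which beta-diversity is computed.
#'
#' @param result a `sim_result` from [run_to_htt_count()], or a species x
#'   family numeric matrix of copy counts.
#' @param min_copies minimal copy count for a family to be scored present
#'   (default 1).
#' @return a logical species x family matrix with id dimnames.
#' @examples
#' m <- matrix(c(0, 5, 1, 0), 2, 2)
#' presence_matrix(m)
#' @export
presence_matrix <- function(result, min_copies = 1L) {
  copies <- if (inherits(result, "sim_result")) result$copies else result
  stopifnot(is.matrix(copies), min_copies >= 1)
  p <- copies >= min_copies
  if (is.null(dimnames(p)))
    dimnames(p) <- list(species = seq_len(nrow(p)), family = seq_len(ncol(p)))
  p
}

#' Jaccard beta-diversity matrix
#'
#' Computes the pairwise TE beta-diversity between species: entry (i, j) is
#' the Jaccard distance `1 - |F_i intersect F_j| / |F_i union F_j|` between
#' the family sets of species i and j, so 0 means identical TE content and 1
#' means no shared family. Two species with no families at all are scored 0
#' (identically TE-free genomes); one empty vs one non-empty genome scores 1.
#'
#' @param p a logical species x family matrix (see [presence_matrix()]).
#' @return a symmetric species x species numeric matrix in `[0, 1]` with a
#'   zero diagonal, of class `matrix` with attribute `"measure" =
#'   "jaccard_distance"`.
#' @examples
#' p <- rbind(a = c(TRUE, TRUE, FALSE), b = c(FALSE, TRUE, TRUE))
#' beta_matrix(p)["a", "b"]  # 1 - 1/3
#' @export
beta_matrix <- function(p) {
  stopifnot(is.matrix(p), nrow(p) >= 2)
  m <- matrix(as.numeric(p), nrow(p), ncol(p))
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  union <- outer(sizes, sizes, "+") - inter
  beta <- ifelse(union > 0, 1 - inter / union, 0)
  diag(beta) <- 0
  ids <- if (!is.null(rownames(p))) rownames(p) else seq_len(nrow(p))
  dimnames(beta) <- list(ids, ids)
  attr(beta, "measure") <- "jaccard_distance"
  beta
}

#' Order species by hierarchical clustering of the beta-matrix
#'
#' Reproduces the heatmap ordering used to reveal blocks of species with
#' similar TE content: agglomerative clustering (average linkage by default)
#' on the beta-matrix taken as a distance, plus a block assignment obtained
#' by cutting the dendrogram into `n_blocks` groups. When `n_blocks` is
#' `NULL` the cut is placed at the largest gap between consecutive merge
#' heights.
#'
#' @param beta a beta-diversity matrix from [beta_matrix()].
#' @param n_blocks number of blocks, or `NULL` for the automatic cut.
#' @param method linkage passed to [stats::hclust()] (default "average").
#' @return a list with `order` (leaf order of species indices), `blocks`
#'   (integer block label per species, in input order), `n_blocks`, and the
#'   `hclust` object.
#' @examples
#' b <- rbind(c(0, 0, 1), c(0, 0, 1), c(1, 1, 0))
#' cluster_order(b, n_blocks = 2)$blocks
#' @export
cluster_order <- function(beta, n_blocks = NULL, method = "average") {
  stopifnot(is.matrix(beta), nrow(beta) == ncol(beta), nrow(beta) >= 2)
  n <- nrow(beta)
  d <- as.dist(beta)
  if (max(d) - min(d) < .Machine$double.eps^0.5) {
    warning("all pairwise beta values are equal; returning a single block")
    return(list(order = seq_len(n), blocks = rep(1L, n), n_blocks = 1L,
                hclust = NULL))
  }
  hc <- hclust(d, method = method)
  if (is.null(n_blocks)) {
    h <- hc$height
    n_blocks <- if (length(h) > 1) n - which.max(diff(h)) else 2L
  }
  n_blocks <- max(1L, min(as.integer(n_blocks), n))
  blocks <- cutree(hc, k = n_blocks)
  list(order = hc$order, blocks = as.integer(blocks),
       n_blocks = n_blocks, hclust = hc)
}

#' Read/write presence and beta matrices as TSV
#'
#' Matrices are stored as tab-separated tables with a header row and a
#' leading id column, so they round-trip exactly. `write_beta_phylip` also
#' emits the square distance-matrix dialect used by phylip-style tools (a
#' line with the species count, then one row per species: id followed by
#' distances).
#'
#' @param m the matrix (logical presence or numeric beta).
#' @param file path.
#' @return the writers return `file` invisibly; the readers return the
#'   matrix.
#' @export
write_matrix_tsv <- function(m, file) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_matrix_tsv
#' @export
read_presence_tsv <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE]) > 0
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname write_matrix_tsv
#' @export
read_beta_tsv <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  attr(m, "measure") <- "jaccard_distance"
  m
}

#' @rdname write_matrix_tsv
#' @export
write_beta_phylip <- function(m, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(sprintf("%-10s", rownames(m)[i]),
                       sprintf("%.6f", m[i, ])), collapse = " "), con)
  }
  invisible(file)
}
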