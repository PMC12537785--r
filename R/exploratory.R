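#' Principal component analysis of standardized fold changes
#'
#' Samples are observations, genes are features. Features are standardized
#' (zero mean, unit population variance) before the decomposition, so all
#' genes contribute on an equal scale. Component signs are fixed by making
#' each component's largest-magnitude loading positive, which makes the
#' result deterministic.
#'
#' @param fc genes x samples fold-change matrix.
#' @param n_components number of components to return (default
#'   `min(dim)`).
#' @return object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (genes x components), `explained` (variance fractions,
#'   non-increasing), and the standardized matrix used.
#' @export
run_pca <- function(fc, n_components = NULL) {
  x <- standardize(t(fc))              # samples x genes
  max_comp <- min(dim(x))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp)
    stop("n_components exceeds min(dim) = ", max_comp, call. = FALSE)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- pc$rotation[, k, drop = FALSE]
  scores <- pc$x[, k, drop = FALSE]
  # sign convention: largest-|loading| entry positive
  for (j in k) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  ev <- pc$sdev^2
  structure(list(scores = scores, loadings = rot,
                 explained = (ev / sum(ev))[k],
                 standardized = x,
                 full_rotation = pc$rotation, full_scores = pc$x),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d samples x %d genes, %d components\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores)))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 5)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Group-mean fold-change matrix for heatmap plotting
#'
#' Restricts the fold-change matrix to a gene subset, averages within
#' (group, timepoint) blocks, and orders rows by hierarchical clustering
#' on correlation distance (single genes are returned unclustered).
#' Columns are grouped by adjuvant group, then timepoint. The computation
#' is a pure function of its inputs, so rendering is reproducible; pass
#' the matrix to [plot_heatmap()] or any heatmap engine.
#'
#' @param fc genes x post-dose-samples fold-change matrix.
#' @param gene_subset genes to display (subset of rownames(fc)).
#' @param meta sample metadata.
#' @return list with `matrix` (genes x group:timepoint means, rows in
#'   cluster order), `row_order`, `col_order`.
#' @export
heatmap_matrix <- function(fc, gene_subset, meta) {
  if (length(gene_subset) == 0) stop("gene subset is empty", call. = FALSE)
  miss <- setdiff(gene_subset, rownames(fc))
  if (length(miss) > 0)
    stop("gene(s) absent from fold-change matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  idx <- match(colnames(fc), meta$sample_id)
  m <- meta[idx, ]
  groups <- levels(droplevels(m$group))
  tps <- as.character(unique(m$timepoint))
  cols <- as.vector(t(outer(groups, tps, paste, sep = ":")))
  mat <- sapply(cols, function(cl) {
    parts <- strsplit(cl, ":", fixed = TRUE)[[1]]
    i <- which(as.character(m$group) == parts[1] &
                 as.character(m$timepoint) == parts[2])
    rowMeans(fc[gene_subset, i, drop = FALSE])
  })
  if (length(gene_subset) == 1) {
    mat <- matrix(mat, nrow = 1, dimnames = list(gene_subset, cols))
    return(list(matrix = mat, row_order = gene_subset, col_order = cols))
  }
  cl <- cluster_saliency(mat)
  list(matrix = mat[cl$order, , drop = FALSE], row_order = cl$order,
       col_order = cols)
}

#' Render a heatmap matrix
#'
#' Base-graphics rendering of a [heatmap_matrix()] result (row/column
#' order already decided there). Kept separate from the matrix computation
#' so tests assert on numbers, not pixels.
#'
#' @param hm a [heatmap_matrix()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot_heatmap <- function(hm, ...) {
  m <- hm$matrix
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  xlab = "", ylab = "", axes = FALSE, ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.5)
  invisible(hm)
}
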