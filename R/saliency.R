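#' Weight-product saliency of a trained network
#'
#' Computes per-class effective gene weights by multiplying the trained
#' weight matrices across layers with the ReLU taken into account: every
#' negative weight is clamped to zero before the product, so
#' \deqn{W_{r,s} = \sum_q \max(0, W2_{s,q}) \, \max(0, W1_{q,r})}
#' for gene r and class s. Biases are excluded. The result is non-negative
#' by construction and focuses the analysis on genes that positively
#' contribute to a class score.
#'
#' @param m a trained `mlp`.
#' @return genes x classes `saliency_matrix` (raw scale), gene and class
#'   names carried over from the model.
#' @export
compute_saliency <- function(m) {
  stopifnot(inherits(m, "mlp"))
  if (!isTRUE(m$trained)) stop("model is untrained", call. = FALSE)
  if (ncol(m$W2) != nrow(m$W1))
    stop("inconsistent weight shapes", call. = FALSE)
  s <- t(pmax(m$W2, 0) %*% pmax(m$W1, 0))
  rownames(s) <- m$feature_names
  colnames(s) <- m$output_names
  structure(s, normalization = "raw", class = c("saliency_matrix", "matrix"))
}

#' Min-max normalize a saliency matrix to [0, 1]
#'
#' Global scaling over the whole matrix: 0 is the lowest weight anywhere,
#' 1 the highest. Scale-invariant (multiplying the raw matrix by any
#' positive constant gives the same result) and idempotent on matrices
#' already attaining both bounds.
#'
#' @param s a raw `saliency_matrix`.
#' @return the normalized matrix (normalization `"minmax01"`).
#' @export
normalize01 <- function(s) {
  lo <- min(s); hi <- max(s)
  if (hi <= lo) stop("constant saliency matrix cannot be normalized",
                     call. = FALSE)
  out <- (s - lo) / (hi - lo)
  attr(out, "normalization") <- "minmax01"
  class(out) <- c("saliency_matrix", "matrix")
  out
}

#' Hierarchically cluster saliency gene profiles
#'
#' Agglomerative clustering of gene rows using correlation distance
#' `d = 1 - Pearson r` and average linkage. Zero-variance rows (no
#' correlation defined) are assigned the maximal distance 2 to every other
#' row and logged.
#'
#' @param s genes x classes saliency matrix with at least 2 genes.
#' @return list with `order` (leaf order, gene names), `hclust` (the
#'   linkage object) and `degenerate` (zero-variance genes).
#' @export
cluster_saliency <- function(s) {
  if (nrow(s) < 2) stop("need at least 2 genes to cluster", call. = FALSE)
  x <- unclass(s)
  v <- apply(x, 1, stats::var)
  degenerate <- rownames(x)[v == 0]
  d <- matrix(2, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
  ok <- v > 0
  if (sum(ok) >= 2) {
    r <- stats::cor(t(x[ok, , drop = FALSE]))
    d[ok, ok] <- 1 - r
  }
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(order = rownames(x)[hc$order], hclust = hc, degenerate = degenerate)
}

#' Rank genes by mean normalized saliency
#'
#' Orders genes by their mean normalized weight across classes and selects
#' the `n` highest (top set) and `n` lowest (bottom set). Ties are broken
#' lexicographically by gene symbol.
#'
#' @param s a normalized saliency matrix (see [normalize01()]).
#' @param n size of each selected set, default 100.
#' @return an object of class `gene_ranking`: `ranked` (all genes, best
#'   first), `mean_weight`, `top_set`, `bottom_set`, `n`.
#' @export
rank_genes <- function(s, n = 100L) {
  if (nrow(s) < 2 * n)
    stop("need at least ", 2 * n, " genes to select disjoint top/bottom ",
         n, call. = FALSE)
  mw <- rowMeans(s)
  ord <- order(-mw, rownames(s))
  ranked <- rownames(s)[ord]
  structure(list(ranked = ranked,
                 mean_weight = mw[ord],
                 top_set = ranked[seq_len(n)],
                 bottom_set = rev(ranked)[seq_len(n)],
                 n = as.integer(n)),
            class = "gene_ranking")
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(sprintf("gene ranking: %d genes, top/bottom sets of %d\n",
              length(x$ranked), x$n))
  cat("  top:", paste(utils::head(x$top_set, 5), collapse = ", "), "...\n")
  invisible(x)
}

#' Inter-group correlation of fold changes over ranked gene sets
#'
#' For every pair of adjuvant groups and every post-dose timepoint,
#' computes the Pearson correlation between the two groups' mean
#' fold-change vectors restricted to the top gene set and, separately, the
#' bottom gene set. Two-sided p-values use the exact t-transform with
#' n - 2 degrees of freedom (n = genes in the set); pairs with p < 0.05
#' are flagged as significant.
#'
#' @param fc genes x post-dose-samples fold-change matrix.
#' @param meta sample metadata.
#' @param ranking a [rank_genes()] result.
#' @return data.frame with columns `set`, `timepoint`, `group_a`,
#'   `group_b`, `r`, `p_value`, `significant`.
#' @export
intergroup_correlation <- function(fc, meta, ranking) {
  stopifnot(inherits(ranking, "gene_ranking"))
  genes <- c(ranking$top_set, ranking$bottom_set)
  miss <- setdiff(genes, rownames(fc))
  if (length(miss) > 0)
    stop("ranked gene(s) absent from fold-change matrix: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  idx <- match(colnames(fc), meta$sample_id)
  m <- meta[idx, ]
  groups <- levels(droplevels(m$group))
  tps <- unique(as.character(m$timepoint))
  sets <- list(top = ranking$top_set, bottom = ranking$bottom_set)
  out <- list()
  for (set_name in names(sets)) {
    g_set <- sets[[set_name]]
    for (tp in tps) {
      means <- sapply(groups, function(g) {
        cols <- which(m$group == g & m$timepoint == tp)
        if (length(cols) == 0) return(rep(NA_real_, length(g_set)))
        rowMeans(fc[g_set, cols, drop = FALSE])
      })
      for (i in seq_along(groups)) for (j in seq_along(groups)) {
        if (j <= i) next
        a <- means[, i]; b <- means[, j]
        if (anyNA(a) || anyNA(b)) next    # group without samples: skip pair
        ct <- stats::cor.test(a, b, method = "pearson")
        out[[length(out) + 1]] <- data.frame(
          set = set_name, timepoint = tp,
          group_a = groups[i], group_b = groups[j],
          r = unname(ct$estimate), p_value = ct$p.value,
          significant = ct$p.value < 0.05, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Gene-set membership of the top/bottom saliency sets
#'
#' Counts the overlap of each named gene set with the top and bottom
#' ranked sets and reports a hypergeometric enrichment p-value (upper
#' tail) against the ranking's gene universe. Empty gene sets are skipped
#' with a warning. No external services are queried; gene sets come from a
#' local list (e.g. read with [read_gmt()]).
#'
#' @param ranking a [rank_genes()] result.
#' @param gene_sets named list of symbol vectors.
#' @return data.frame: set name, set size (in universe), overlap with top
#'   and bottom sets, hypergeometric p for each.
#' @export
pathway_membership_summary <- function(ranking, gene_sets) {
  stopifnot(inherits(ranking, "gene_ranking"))
  universe <- ranking$ranked
  n <- ranking$n
  rows <- list()
  for (nm in names(gene_sets)) {
    gs <- intersect(gene_sets[[nm]], universe)
    if (length(gs) == 0) {
      warning("gene set '", nm, "' has no genes in the universe; skipped",
              call. = FALSE)
      next
    }
    hyper_p <- function(hit) stats::phyper(hit - 1, length(gs),
                                           length(universe) - length(gs),
                                           n, lower.tail = FALSE)
    top_hit <- length(intersect(gs, ranking$top_set))
    bot_hit <- length(intersect(gs, ranking$bottom_set))
    rows[[nm]] <- data.frame(set = nm, set_size = length(gs),
                             top_overlap = top_hit, top_p = hyper_p(top_hit),
                             bottom_overlap = bot_hit,
                             bottom_p = hyper_p(bot_hit),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average saliency across cross-validation fold models
#'
#' Computes normalized saliency per fold model and the elementwise mean;
#' the per-fold matrices are retained so fold-to-fold stability (e.g. mean
#' pairwise rank correlation) can be inspected.
#'
#' @param models list of trained `mlp` fold models sharing feature and
#'   class names.
#' @return list with `mean` (genes x classes) and `per_fold` (list of
#'   normalized matrices).
#' @export
saliency_across_folds <- function(models) {
  per_fold <- lapply(models, function(m) normalize01(compute_saliency(m)))
  mean_mat <- Reduce(`+`, lapply(per_fold, unclass)) / length(per_fold)
  list(mean = mean_mat, per_fold = per_fold)
}
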