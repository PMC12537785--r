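#' Log10-transform an FPKM matrix
#'
#' Applies the elementwise transform `t = log10(x + pseudo) + pseudo`. The
#' pseudo-count (default 0.01) avoids taking the log of zero; log10 keeps
#' up- and down-regulation symmetric on the transformed scale. The trailing
#' `+ pseudo` only shifts the scale and is retained for fidelity with the
#' downstream filter threshold.
#'
#' @param expr genes x samples matrix of non-negative FPKM values.
#' @param pseudo positive pseudo-count, default 0.01.
#' @return matrix of the same shape, with attributes `pseudo` and no others
#'   modified.
#' @examples
#' transform_fpkm(matrix(c(0, 0.99, 99.99), 3, 1,
#'                dimnames = list(paste0("g", 1:3), "s1")))
#' @export
transform_fpkm <- function(expr, pseudo = 0.01) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expr must be a numeric matrix", call. = FALSE)
  if (pseudo <= 0) stop("pseudo must be positive", call. = FALSE)
  neg <- which(expr < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    g <- rownames(expr)[neg[1, 1]]; s <- colnames(expr)[neg[1, 2]]
    stop(sprintf("negative FPKM value at gene %s, sample %s",
                 if (is.null(g)) neg[1, 1] else g,
                 if (is.null(s)) neg[1, 2] else s), call. = FALSE)
  }
  out <- log10(expr + pseudo) + pseudo
  attr(out, "pseudo") <- pseudo
  out
}

# (group, timepoint) condition label per sample, in the order of `samples`
.condition_of <- function(samples, meta) {
  idx <- match(samples, meta$sample_id)
  if (anyNA(idx)) {
    stop("sample(s) absent from metadata: ",
         paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  interaction(meta$group[idx], meta$timepoint[idx], drop = TRUE)
}

#' Filter low-intensity genes
#'
#' A gene is retained iff there is at least one condition — a (group,
#' timepoint) combination — in which all of its samples have transformed
#' values at or above the threshold. This is the "above background in all
#' replicates of at least one condition" retention rule, applied at the
#' gene level so that removal counts are well-defined.
#'
#' @param t transformed genes x samples matrix (see [transform_fpkm()]).
#' @param meta sample metadata with `sample_id`, `group`, `timepoint`.
#' @param threshold retention threshold on the transformed scale,
#'   default -1.
#' @return the retained submatrix, with an attribute `report`: a list with
#'   `n_in`, `n_retained`, `n_removed` and the removed gene ids.
#' @export
filter_low_intensity <- function(t, meta, threshold = -1) {
  cond <- .condition_of(colnames(t), meta)
  keep <- vapply(seq_len(nrow(t)), function(i) {
    ok <- tapply(t[i, ] >= threshold, cond, all)
    any(ok, na.rm = TRUE)
  }, logical(1))
  out <- t[keep, , drop = FALSE]
  attr(out, "pseudo") <- attr(t, "pseudo")
  attr(out, "report") <- list(stage = "low_intensity_filter",
                              threshold = threshold,
                              n_in = nrow(t), n_retained = sum(keep),
                              n_removed = sum(!keep),
                              removed = rownames(t)[!keep])
  out
}

#' Map gene identifiers to human ortholog symbols
#'
#' Renames rows from source gene ids to their human ortholog symbols and
#' drops genes without an entry in the map. When several source genes map
#' to the same symbol, the source row with the highest mean transformed
#' value is kept and the collision is logged in the report.
#'
#' @param t transformed genes x samples matrix.
#' @param map data.frame with columns `source_id` and `human_symbol`; each
#'   source id maps to at most one symbol.
#' @return matrix with human symbols as rownames and attribute `report`
#'   (`n_in`, `n_retained`, `n_removed`, dropped ids, collisions).
#' @export
map_orthologs <- function(t, map) {
  if (is.null(map) || nrow(map) == 0)
    stop("ortholog map is empty", call. = FALSE)
  if (!all(c("source_id", "human_symbol") %in% names(map)))
    stop("map needs columns source_id and human_symbol", call. = FALSE)
  if (anyDuplicated(map$source_id))
    stop("each source_id may map to at most one symbol", call. = FALSE)
  sym <- map$human_symbol[match(rownames(t), map$source_id)]
  unmapped <- rownames(t)[is.na(sym)]
  keep <- !is.na(sym)
  tt <- t[keep, , drop = FALSE]
  sym <- sym[keep]

  collisions <- list()
  if (anyDuplicated(sym)) {
    means <- rowMeans(tt)
    ord <- order(sym, -means)       # within symbol, highest mean first
    tt <- tt[ord, , drop = FALSE]; sym <- sym[ord]; means <- means[ord]
    dup <- duplicated(sym)
    for (s in unique(sym[dup])) {
      rows <- which(sym == s)
      collisions[[s]] <- list(kept = rownames(tt)[rows[1]],
                              dropped = rownames(tt)[rows[-1]])
    }
    tt <- tt[!dup, , drop = FALSE]; sym <- sym[!dup]
  }
  rownames(tt) <- sym
  attr(tt, "pseudo") <- attr(t, "pseudo")
  attr(tt, "report") <- list(stage = "ortholog_mapping",
                             n_in = nrow(t), n_retained = nrow(tt),
                             n_removed = nrow(t) - nrow(tt),
                             unmapped = unmapped, collisions = collisions)
  tt
}

#' Restrict a matrix to an immune gene panel
#'
#' Keeps only the genes in `panel`, in panel order. Panel symbols absent
#' from the data are reported in a warning, not fatal; zero overlap is an
#' error.
#'
#' @param t transformed genes x samples matrix (human symbols as rownames).
#' @param panel character vector of gene symbols.
#' @return submatrix in panel order with attribute `report`.
#' @export
select_panel <- function(t, panel) {
  if (length(panel) == 0) stop("panel is empty", call. = FALSE)
  present <- panel[panel %in% rownames(t)]
  missing <- setdiff(panel, present)
  if (length(present) == 0)
    stop("no overlap between panel and data", call. = FALSE)
  if (length(missing) > 0)
    warning("panel symbol(s) absent from data: ",
            paste(missing, collapse = ", "), call. = FALSE)
  out <- t[present, , drop = FALSE]
  attr(out, "pseudo") <- attr(t, "pseudo")
  attr(out, "report") <- list(stage = "panel_selection",
                              n_in = nrow(t), n_retained = nrow(out),
                              n_removed = nrow(t) - nrow(out),
                              panel_missing = missing)
  out
}

#' Per-animal baseline fold change
#'
#' For every post-dose sample (day 1 and day 7), subtracts the same
#' animal's pre-dose value from the matching dose, giving log10 fold
#' changes relative to each animal's own baseline. Only post-dose columns
#' appear in the output.
#'
#' @param t transformed genes x samples matrix.
#' @param meta sample metadata.
#' @return genes x post-dose-samples matrix of fold changes.
#' @export
fold_change <- function(t, meta) {
  idx <- match(colnames(t), meta$sample_id)
  if (anyNA(idx))
    stop("sample(s) absent from metadata: ",
         paste(colnames(t)[is.na(idx)], collapse = ", "), call. = FALSE)
  m <- meta[idx, ]
  is_pre <- m$timepoint == "pre"
  pre_key <- paste(m$animal_id, m$dose, sep = "|")
  pre_col <- stats::setNames(which(is_pre), pre_key[is_pre])
  post <- which(!is_pre)
  base <- pre_col[pre_key[post]]
  if (anyNA(base)) {
    bad <- unique(m$animal_id[post[is.na(base)]])
    stop("missing pre-dose baseline for animal(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- t[, post, drop = FALSE] - t[, base, drop = FALSE]
  colnames(out) <- colnames(t)[post]
  out
}

#' Fit a feature standardizer
#'
#' Records per-feature (column) mean and population standard deviation
#' (divide-by-n), for fitting on training folds and applying to held-out
#' folds without leakage.
#'
#' @param x samples x features matrix, at least 2 rows.
#' @return an object of class `standardizer` with `center` and `scale`.
#' @seealso [std_apply()], [standardize()]
#' @export
std_fit <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2)
    stop("need a matrix with at least 2 samples (rows)", call. = FALSE)
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))
  structure(list(center = center, scale = scale), class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' Constant features (zero population sd in the fit) map to all-zero
#' columns rather than dividing by zero.
#'
#' @param fit a `standardizer` from [std_fit()].
#' @param x samples x features matrix with the same feature count/order.
#' @return standardized matrix.
#' @export
std_apply <- function(fit, x) {
  stopifnot(inherits(fit, "standardizer"))
  if (ncol(x) != length(fit$center))
    stop("feature count does not match the fitted standardizer",
         call. = FALSE)
  s <- ifelse(fit$scale > 0, fit$scale, 1)
  out <- sweep(sweep(x, 2, fit$center), 2, s, "/")
  out[, fit$scale == 0] <- 0
  out
}

#' Standardize features to zero mean and unit variance
#'
#' Convenience wrapper: fits on `x` and applies to `x`. Each feature
#' (column) ends with mean 0 and population sd 1; constant features become
#' all-zero.
#'
#' @inheritParams std_fit
#' @return standardized matrix with attribute `standardizer` (the fit).
#' @export
standardize <- function(x) {
  fit <- std_fit(x)
  out <- std_apply(fit, x)
  attr(out, "standardizer") <- fit
  out
}

#' Run the full preprocessing chain
#'
#' transform -> low-intensity filter -> ortholog mapping -> panel selection
#' -> per-animal baseline fold change. Stage reports are collected so that
#' gene-count bookkeeping (`n_in == n_retained + n_removed` at every stage)
#' can be checked on any run.
#'
#' @param expr genes x samples FPKM matrix.
#' @param meta sample metadata.
#' @param ortholog_map data.frame `source_id`, `human_symbol`.
#' @param panel character vector of panel symbols.
#' @param pseudo pseudo-count for [transform_fpkm()].
#' @param threshold threshold for [filter_low_intensity()].
#' @return list with `transformed` (panel-selected transformed matrix),
#'   `fold_change` (genes x post-dose samples), and `reports` (one entry
#'   per filtering stage).
#' @export
preprocess_expression <- function(expr, meta, ortholog_map, panel,
                                  pseudo = 0.01, threshold = -1) {
  t0 <- transform_fpkm(expr, pseudo)
  t1 <- filter_low_intensity(t0, meta, threshold)
  t2 <- map_orthologs(t1, ortholog_map)
  t3 <- select_panel(t2, panel)
  fc <- fold_change(t3, meta)
  list(transformed = t3, fold_change = fc,
       reports = list(filter = attr(t1, "report"),
                      orthologs = attr(t2, "report"),
                      panel = attr(t3, "report")))
}
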