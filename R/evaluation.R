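#' Balanced, stratified fold assignment with undersampling
#'
#' Majority classes are first randomly undersampled to the minority class
#' size, so that every class contributes an equal number of instances to
#' both training and testing; the discarded instance ids are recorded.
#' The balanced instances are then assigned to `k` folds, stratified by
#' class, reproducibly under `seed`.
#'
#' @param labels factor (or coercible) of class labels, named by instance
#'   id; unnamed labels are given integer ids.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return list with `fold` (named integer vector in 1..k over the kept
#'   instances), `discarded` (ids removed by undersampling), `class_size`
#'   (the common per-class size after balancing).
#' @export
make_balanced_folds <- function(labels, k = 10L, seed = 1L) {
  y <- factor(labels)
  ids <- names(labels)
  if (is.null(ids)) ids <- as.character(seq_along(y))
  if (anyDuplicated(ids)) stop("instance ids must be unique", call. = FALSE)
  sizes <- table(y)
  m <- min(sizes)
  if (m < k)
    stop("minority class has ", m, " instances; need at least k = ", k,
         call. = FALSE)
  set.seed(seed)
  keep <- unlist(lapply(levels(y), function(cl) {
    i <- which(y == cl)
    if (length(i) > m) sort(sample(i, m)) else i
  }), use.names = FALSE)
  discarded <- ids[setdiff(seq_along(y), keep)]

  fold <- integer(length(keep))
  names(fold) <- ids[keep]
  yk <- y[keep]
  for (cl in levels(y)) {
    i <- which(yk == cl)
    # spread each class across folds as evenly as possible, random order
    f <- rep_len(seq_len(k), length(i))
    fold[i] <- sample(f)
  }
  list(fold = fold, discarded = discarded, class_size = as.integer(m))
}

#' Build classification instances from fold changes
#'
#' Each post-dose fold-change column — one (animal, dose, timepoint)
#' combination — is one instance, labeled by the animal's adjuvant group.
#' The alternative mode concatenates the day-1 and day-7 vectors of each
#' (animal, dose) into a single instance.
#'
#' @param fc genes x post-dose-samples fold-change matrix.
#' @param meta sample metadata.
#' @param mode `"per_sample"` (default) or `"concat"`.
#' @return list with `x` (instances x features), `labels` (factor, named by
#'   instance id), and `meta` (one row per instance).
#' @export
build_instances <- function(fc, meta, mode = c("per_sample", "concat")) {
  mode <- match.arg(mode)
  idx <- match(colnames(fc), meta$sample_id)
  if (anyNA(idx)) stop("fold-change sample(s) absent from metadata",
                       call. = FALSE)
  m <- meta[idx, ]
  if (mode == "per_sample") {
    x <- t(fc)
    labels <- stats::setNames(factor(m$group, levels = levels(meta$group)),
                              m$sample_id)
    return(list(x = x, labels = labels, meta = m))
  }
  key <- paste(m$animal_id, m$dose, sep = "_d")
  d1 <- which(m$timepoint == "day1"); d7 <- which(m$timepoint == "day7")
  k1 <- key[d1]; k7 <- key[d7]
  common <- intersect(k1, k7)
  x <- cbind(t(fc[, d1[match(common, k1)], drop = FALSE]),
             t(fc[, d7[match(common, k7)], drop = FALSE]))
  colnames(x) <- c(paste0(rownames(fc), "_day1"), paste0(rownames(fc), "_day7"))
  rownames(x) <- common
  mi <- m[d1[match(common, k1)], ]
  labels <- stats::setNames(factor(mi$group, levels = levels(meta$group)),
                            common)
  list(x = x, labels = labels, meta = mi)
}

#' Cross-validate a classifier over pre-assigned folds
#'
#' For each fold, trains a fresh classifier (via `model_factory`) on the
#' remaining folds and predicts the held-out instances; held-out
#' predictions from all folds are pooled into one confusion matrix, which
#' equals the sample-weighted average of per-fold results. Any
#' standardization must be fitted inside the factory on the training data
#' only (the packaged [mlp_factory()] does this).
#'
#' @param x instances x features matrix with instance ids as rownames.
#' @param labels factor named by instance id.
#' @param folds a fold assignment from [make_balanced_folds()].
#' @param model_factory function(x_train, y_train) returning an object with
#'   a `predict(object, x, type = "class")`-compatible method, e.g.
#'   [mlp_factory()] or [forest_factory()].
#' @return list with `confusion` (true x predicted counts), `metrics`
#'   (from [compute_metrics()]), `per_fold_accuracy`, `predictions`
#'   (named factor), `models` (one per fold) and `skipped_classes`.
#' @export
cross_validate_classifier <- function(x, labels, folds, model_factory) {
  fold <- folds$fold
  ids <- names(fold)
  if (!all(ids %in% rownames(x)))
    stop("fold ids missing from instance matrix", call. = FALSE)
  y <- labels[ids]
  classes <- levels(y)
  preds <- factor(rep(NA_character_, length(ids)), levels = classes)
  names(preds) <- ids
  models <- list()
  skipped <- list()
  per_fold <- numeric(max(fold))
  for (f in sort(unique(fold))) {
    tr <- ids[fold != f]; te <- ids[fold == f]
    y_tr <- droplevels(y[tr])
    miss <- setdiff(classes, levels(y_tr))
    if (length(miss) > 0) {
      warning("fold ", f, " training data lacks class(es): ",
              paste(miss, collapse = ", "), call. = FALSE)
      skipped[[as.character(f)]] <- miss
    }
    fit <- model_factory(x[tr, , drop = FALSE], y[tr])
    p <- predict(fit, x[te, , drop = FALSE], type = "class")
    preds[te] <- as.character(p)
    models[[f]] <- fit
    per_fold[f] <- mean(as.character(p) == as.character(y[te]))
  }
  cm <- table(true = y, predicted = preds)
  list(confusion = unclass(cm), metrics = compute_metrics(unclass(cm)),
       per_fold_accuracy = per_fold, predictions = preds, models = models,
       skipped_classes = skipped)
}

#' Model factories for cross-validation
#'
#' `mlp_factory()` yields fresh fully connected networks ([mlp()]);
#' `forest_factory()` yields random-forest classifiers (the comparison
#' arm), with a documented tree count and per-fit seed.
#'
#' @param hidden,epochs,learn_rate,batch_size,seed passed to [mlp()].
#' @return a `function(x_train, y_train)` for
#'   [cross_validate_classifier()].
#' @export
mlp_factory <- function(hidden = 100L, epochs = 300L, learn_rate = 0.01,
                        batch_size = 16L, seed = 1L) {
  force(hidden); force(epochs); force(learn_rate); force(batch_size)
  force(seed)
  function(x_train, y_train) {
    mlp(x_train, y_train, hidden = hidden, epochs = epochs,
        learn_rate = learn_rate, batch_size = batch_size, seed = seed)
  }
}

#' @rdname mlp_factory
#' @param ntree number of trees in the ensemble.
#' @param ... further arguments to [randomForest::randomForest()] (e.g.
#'   `maxnodes` for shallow trees).
#' @export
forest_factory <- function(ntree = 500L, seed = 1L, ...) {
  force(ntree); force(seed)
  dots <- list(...)
  function(x_train, y_train) {
    if (nlevels(droplevels(factor(y_train))) < 2)
      stop("random forest needs at least two classes in training data",
           call. = FALSE)
    set.seed(seed)
    do.call(randomForest::randomForest,
            c(list(x = x_train, y = factor(y_train), ntree = ntree), dots))
  }
}

#' Confusion-matrix metrics per class
#'
#' For each class k: TPR (recall) = TP/(TP+FN), FNR = FN/(TP+FN),
#' precision = TP/(TP+FP), FDR = FP/(TP+FP), F1 = harmonic mean of
#' precision and recall; overall accuracy = sum(TP)/total. Ratios with a
#' zero denominator (a class never seen, or never predicted) are reported
#' as `NaN` and flagged, never coerced to zero.
#'
#' @param cm square counts matrix, rows = true class, columns = predicted.
#' @return list with `per_class` data.frame (TP, FN, FP, TPR, FNR,
#'   precision, FDR, F1, defined flags) and `accuracy`.
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm))
    stop("confusion matrix must be square", call. = FALSE)
  if (sum(cm) == 0) stop("confusion matrix is empty", call. = FALSE)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tpr <- tp / (tp + fn)
  fnr <- fn / (tp + fn)
  prec <- tp / (tp + fp)
  fdr <- fp / (tp + fp)
  f1 <- 2 * prec * tpr / (prec + tpr)
  per_class <- data.frame(
    class = classes, TP = as.numeric(tp), FN = as.numeric(fn),
    FP = as.numeric(fp),
    TPR = as.numeric(tpr), FNR = as.numeric(fnr),
    precision = as.numeric(prec), FDR = as.numeric(fdr), F1 = as.numeric(f1),
    recall_defined = (tp + fn) > 0, precision_defined = (tp + fp) > 0,
    stringsAsFactors = FALSE)
  rownames(per_class) <- NULL
  list(per_class = per_class, accuracy = sum(tp) / sum(cm))
}

#' Subtract day-0 baseline antibody levels
#'
#' Subtracts each animal's week-0 titer from its week-12 and week-36
#' titers, per HPV type; week-0 rows are removed from the output. Applying
#' the function to an already-subtracted table (no week-0 rows) is an
#' error.
#'
#' @param titers data.frame `animal_id`, `hpv_type`, `week`, `value`.
#' @return the baseline-subtracted table (weeks 12 and 36 only).
#' @export
subtract_titer_baseline <- function(titers) {
  need <- c("animal_id", "hpv_type", "week", "value")
  if (!all(need %in% names(titers)))
    stop("titer table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  base <- titers[titers$week == 0, ]
  if (nrow(base) == 0)
    stop("no week-0 baseline rows present (already subtracted?)",
         call. = FALSE)
  post <- titers[titers$week != 0, ]
  key <- function(d) paste(d$animal_id, d$hpv_type, sep = "|")
  b <- stats::setNames(base$value, key(base))
  idx <- key(post)
  if (anyNA(b[idx])) {
    bad <- unique(idx[is.na(b[idx])])
    stop("missing week-0 baseline for (animal, type): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  post$value <- post$value - as.numeric(b[idx])
  rownames(post) <- NULL
  post
}

# long titer table -> animals x (type, week) wide matrix
titer_wide <- function(titers) {
  key <- paste0("HPV", titers$hpv_type, "_w", titers$week)
  animals <- unique(titers$animal_id)
  cols <- unique(key)
  out <- matrix(NA_real_, length(animals), length(cols),
                dimnames = list(animals, cols))
  out[cbind(match(titers$animal_id, animals), match(key, cols))] <-
    titers$value
  out
}

#' Assess titer predictions against ground truth
#'
#' Joins predicted and true titers on (animal, type, week) and reports
#' pooled RMSE and Pearson r, plus box-plot-ready per-(type, week, group)
#' summaries (mean, quartiles) for predicted and true values side by side.
#'
#' @param pred,truth data.frames `animal_id`, `hpv_type`, `week`, `value`.
#' @param meta optional sample metadata supplying each animal's group; when
#'   omitted the per-group breakdown pools all animals.
#' @return list with `rmse`, `pearson_r`, `n`, and `by_group` data.frame.
#' @export
evaluate_titer_predictions <- function(pred, truth, meta = NULL) {
  key <- function(d) paste(d$animal_id, d$hpv_type, d$week, sep = "|")
  kp <- key(pred); kt <- key(truth)
  miss <- setdiff(kt, kp)
  if (length(miss) > 0)
    stop("prediction missing (animal, type, week) key(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...", call. = FALSE)
  p <- pred$value[match(kt, kp)]
  y <- truth$value
  rmse <- sqrt(mean((p - y)^2))
  r <- if (stats::sd(p) > 0 && stats::sd(y) > 0) stats::cor(p, y) else NA_real_

  grp <- if (!is.null(meta)) {
    g <- meta$group[match(truth$animal_id, meta$animal_id)]
    as.character(g)
  } else rep("all", nrow(truth))
  f <- interaction(truth$hpv_type, truth$week, grp, drop = TRUE)
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  rows <- lapply(levels(f), function(lv) {
    i <- f == lv
    parts <- strsplit(lv, ".", fixed = TRUE)[[1]]
    qp <- qs(p[i]); qy <- qs(y[i])
    data.frame(hpv_type = parts[1], week = parts[2], group = parts[3],
               n = sum(i),
               true_mean = mean(y[i]), true_q1 = qy[1], true_median = qy[2],
               true_q3 = qy[3],
               pred_mean = mean(p[i]), pred_q1 = qp[1], pred_median = qp[2],
               pred_q3 = qp[3], stringsAsFactors = FALSE)
  })
  list(rmse = rmse, pearson_r = r, n = nrow(truth),
       by_group = do.call(rbind, rows))
}

#' Cross-validated titer regression
#'
#' Regression instances are animals: the day-1-after-dose-1 fold-change
#' vector predicts all 18 outputs (9 HPV types x weeks 12 and 36,
#' baseline-subtracted). Folds are stratified by adjuvant group; a fresh
#' linear-head network is trained per fold and held-out predictions are
#' pooled.
#'
#' @param fc genes x post-dose-samples fold-change matrix.
#' @param meta sample metadata.
#' @param titers raw titer table (week 0/12/36); baseline is subtracted
#'   internally.
#' @param k number of folds.
#' @param seed integer seed (fold assignment and model training).
#' @param hidden,epochs,learn_rate,batch_size passed to [mlp()].
#' @return list with `predictions`/`truth` (long tables), `evaluation`
#'   (from [evaluate_titer_predictions()]), `models`, `folds`.
#' @export
cross_validate_titer <- function(fc, meta, titers, k = 5L, seed = 1L,
                                 hidden = 100L, epochs = 1500L,
                                 learn_rate = 0.02, batch_size = 16L) {
  d1 <- meta[meta$dose == 1L & meta$timepoint == "day1", ]
  cols <- intersect(d1$sample_id, colnames(fc))
  if (length(cols) == 0)
    stop("no day-1-after-dose-1 samples in the fold-change matrix",
         call. = FALSE)
  d1 <- d1[match(cols, d1$sample_id), ]
  x <- t(fc[, cols, drop = FALSE])
  rownames(x) <- d1$animal_id

  yt <- subtract_titer_baseline(titers)
  Y <- titer_wide(yt)
  animals <- intersect(rownames(x), rownames(Y))
  x <- x[animals, , drop = FALSE]; Y <- Y[animals, , drop = FALSE]

  grp <- stats::setNames(d1$group[match(animals, d1$animal_id)], animals)
  folds <- make_balanced_folds(grp, k = k, seed = seed)
  fold <- folds$fold
  # undersampling is not wanted for regression: keep every animal, assign
  # any discarded ones round-robin to existing folds
  if (length(folds$discarded) > 0) {
    set.seed(seed + 1L)
    extra <- stats::setNames(sample(rep_len(seq_len(k),
                                            length(folds$discarded))),
                             folds$discarded)
    fold <- c(fold, extra)[animals]
  } else fold <- fold[animals]

  pred <- matrix(NA_real_, nrow(x), ncol(Y), dimnames = dimnames(Y))
  models <- list()
  for (f in sort(unique(fold))) {
    tr <- animals[fold != f]; te <- animals[fold == f]
    fit <- mlp(x[tr, , drop = FALSE], Y[tr, , drop = FALSE], hidden = hidden,
               epochs = epochs, learn_rate = learn_rate,
               batch_size = batch_size, seed = seed + f)
    pred[te, ] <- predict_titers(fit, x[te, , drop = FALSE])
    models[[f]] <- fit
  }
  pl <- data.frame(
    animal_id = rep(rownames(pred), ncol(pred)),
    hpv_type = rep(sub("^HPV(\\d+)_w\\d+$", "\\1", colnames(pred)),
                   each = nrow(pred)),
    week = as.integer(rep(sub("^HPV\\d+_w(\\d+)$", "\\1", colnames(pred)),
                          each = nrow(pred))),
    value = as.vector(pred), stringsAsFactors = FALSE)
  tl <- yt[yt$animal_id %in% animals, ]
  tl$hpv_type <- as.character(tl$hpv_type)
  list(predictions = pl, truth = tl,
       evaluation = evaluate_titer_predictions(pl, tl, meta),
       models = models, folds = list(fold = fold, k = k, seed = seed))
}
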