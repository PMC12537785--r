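#' Initialize a single-hidden-layer fully connected network
#'
#' The network has one hidden layer of ReLU units and either a softmax
#' classification head or a linear regression head. Weights are drawn
#' uniformly on (-1, 1) scaled by 1/sqrt(fan-in), biases start at zero;
#' the draw is seeded so the same seed yields bit-identical weights.
#'
#' @param n_features input dimension.
#' @param n_hidden hidden layer width (default 100).
#' @param n_outputs number of classes (softmax) or regression targets.
#' @param head `"softmax"` or `"linear"`.
#' @param seed integer seed for the weight draw.
#' @param feature_names,output_names optional dimension names.
#' @return an (untrained) object of class `mlp` with weight matrices
#'   `W1` (n_hidden x n_features), `b1`, `W2` (n_outputs x n_hidden), `b2`.
#' @export
mlp_init <- function(n_features, n_hidden = 100L, n_outputs, head,
                     seed = 1L, feature_names = NULL, output_names = NULL) {
  if (n_features < 1 || n_hidden < 1 || n_outputs < 1)
    stop("all network dimensions must be positive", call. = FALSE)
  head <- match.arg(head, c("softmax", "linear"))
  set.seed(seed)
  W1 <- matrix(stats::runif(n_hidden * n_features, -1, 1) / sqrt(n_features),
               n_hidden, n_features)
  W2 <- matrix(stats::runif(n_outputs * n_hidden, -1, 1) / sqrt(n_hidden),
               n_outputs, n_hidden)
  structure(list(W1 = W1, b1 = numeric(n_hidden),
                 W2 = W2, b2 = numeric(n_outputs),
                 head = head,
                 feature_names = feature_names, output_names = output_names,
                 x_std = NULL, y_center = NULL, y_scale = NULL,
                 history = NULL, trained = FALSE,
                 config = list(seed = as.integer(seed))),
            class = "mlp")
}

# align newdata columns to the model's feature names (orderless features)
.align_features <- function(m, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!is.null(m$feature_names) && !is.null(colnames(x))) {
    if (!setequal(colnames(x), m$feature_names) ||
        ncol(x) != length(m$feature_names))
      stop("feature names of input do not match the model", call. = FALSE)
    x <- x[, m$feature_names, drop = FALSE]
  }
  if (ncol(x) != ncol(m$W1))
    stop("input has ", ncol(x), " features; model expects ", ncol(m$W1),
         call. = FALSE)
  x
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass through an mlp
#'
#' Computes the network output for one or more input vectors. A softmax
#' head returns class probabilities (rows summing to 1); a linear head
#' returns unbounded reals on the model's training scale. If the model
#' carries a fitted input standardizer (from training), it is applied; if
#' both the model and `x` carry feature names, columns are aligned by name
#' first, so feature order is immaterial.
#'
#' @param m an `mlp`.
#' @param x numeric vector or samples x features matrix.
#' @return samples x outputs matrix.
#' @export
mlp_forward <- function(m, x) {
  stopifnot(inherits(m, "mlp"))
  x <- .align_features(m, x)
  if (!is.null(m$x_std)) x <- std_apply(m$x_std, x)
  a1 <- pmax(x %*% t(m$W1) + rep(m$b1, each = nrow(x)), 0)
  z2 <- a1 %*% t(m$W2) + rep(m$b2, each = nrow(x))
  out <- switch(m$head, softmax = .softmax_rows(z2), linear = z2)
  colnames(out) <- m$output_names
  out
}

# loss and analytic gradients for one batch; y is one-hot (softmax) or the
# target matrix (linear), x already standardized
.mlp_grad <- function(m, x, y) {
  n <- nrow(x)
  z1 <- x %*% t(m$W1) + rep(m$b1, each = n)
  a1 <- pmax(z1, 0)
  z2 <- a1 %*% t(m$W2) + rep(m$b2, each = n)
  if (m$head == "softmax") {
    p <- .softmax_rows(z2)
    loss <- -mean(log(pmax(rowSums(p * y), 1e-300)))
    dz2 <- (p - y) / n
  } else {
    r <- z2 - y
    loss <- mean(r^2)
    dz2 <- 2 * r / length(r)
  }
  da1 <- dz2 %*% m$W2
  dz1 <- da1 * (z1 > 0)
  list(loss = loss,
       gW1 = t(dz1) %*% x, gb1 = colSums(dz1),
       gW2 = t(dz2) %*% a1, gb2 = colSums(dz2))
}

#' Fit a fully connected network to expression profiles
#'
#' The package's central fitting function. Trains a single-hidden-layer
#' ReLU network by seeded mini-batch gradient descent: cross-entropy loss
#' with a softmax head when `y` is a factor (adjuvant-group
#' classification), mean squared error with a linear head when `y` is a
#' numeric matrix (antibody-titer regression). No early stopping, dropout
#' or weight decay is applied.
#'
#' Inputs are standardized internally (mean 0, population sd 1, fitted on
#' the training data only) and, for the linear head, targets are scaled the
#' same way during optimisation and predictions are returned on the
#' original scale. The per-epoch loss is recorded on the internal
#' (standardized) scale.
#'
#' @param x samples x features numeric matrix; column names become the
#'   model's feature names.
#' @param y factor of class labels, or samples x targets numeric matrix.
#' @param hidden hidden-layer width, default 100.
#' @param epochs full passes over the training data, default 300.
#' @param learn_rate gradient-descent step size, default 0.01.
#' @param batch_size mini-batch size, default 16.
#' @param seed integer seed (weight init and batch shuffling).
#' @param standardize_x standardize inputs internally (default TRUE).
#' @param scale_y scale regression targets internally (default TRUE).
#' @return a trained `mlp` with `history` (per-epoch loss), training
#'   `fitted` values, and the fitting configuration.
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' y <- factor(ifelse(x[, 1] + x[, 2] > 0, "up", "down"))
#' fit <- mlp(x, y, hidden = 8, epochs = 50, seed = 1)
#' mean(predict(fit, x, type = "class") == y)
#' @export
mlp <- function(x, y, hidden = 100L, epochs = 300L, learn_rate = 0.01,
                batch_size = 16L, seed = 1L, standardize_x = TRUE,
                scale_y = TRUE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  n <- nrow(x)
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    if (length(y) != n) stop("x and y sizes differ", call. = FALSE)
    head <- "softmax"
    classes <- levels(y)
    Y <- matrix(0, n, length(classes))
    Y[cbind(seq_len(n), as.integer(y))] <- 1
    out_names <- classes
  } else {
    if (is.null(dim(y))) y <- matrix(y, ncol = 1)
    if (nrow(y) != n) stop("x and y sizes differ", call. = FALSE)
    head <- "linear"
    Y <- y
    out_names <- colnames(y)
    if (is.null(out_names)) out_names <- paste0("t", seq_len(ncol(y)))
  }

  m <- mlp_init(ncol(x), hidden, ncol(Y), head, seed = seed,
                feature_names = colnames(x), output_names = out_names)
  if (standardize_x) {
    m$x_std <- std_fit(x)
    xs <- std_apply(m$x_std, x)
  } else xs <- x
  if (head == "linear" && scale_y) {
    m$y_center <- colMeans(Y)
    sc <- sqrt(colMeans(sweep(Y, 2, m$y_center)^2))
    m$y_scale <- ifelse(sc > 0, sc, 1)
    Ys <- sweep(sweep(Y, 2, m$y_center), 2, m$y_scale, "/")
  } else Ys <- Y
  dimnames(xs) <- NULL                # keep gradient updates name-free
  dimnames(Ys) <- NULL

  history <- numeric(epochs)
  if (epochs > 0) {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        g <- .mlp_grad(m, xs[idx, , drop = FALSE], Ys[idx, , drop = FALSE])
        if (!is.finite(g$loss))
          stop("training diverged: non-finite loss at epoch ", ep,
               "; reduce learn_rate", call. = FALSE)
        m$W1 <- m$W1 - learn_rate * g$gW1
        m$b1 <- m$b1 - learn_rate * g$gb1
        m$W2 <- m$W2 - learn_rate * g$gW2
        m$b2 <- m$b2 - learn_rate * g$gb2
        ep_loss <- ep_loss + g$loss; nb <- nb + 1
      }
      history[ep] <- ep_loss / nb
    }
  }
  m$history <- history
  m$trained <- TRUE
  m$config <- list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                   learn_rate = learn_rate, batch_size = as.integer(batch_size),
                   seed = as.integer(seed), standardize_x = standardize_x,
                   scale_y = scale_y)
  m$y <- if (head == "softmax") y else Y
  m$fitted <- predict(m, x, type = if (head == "softmax") "prob" else "response")
  m
}

# undo internal target scaling
.unscale_y <- function(m, z) {
  if (is.null(m$y_center)) return(z)
  sweep(sweep(z, 2, m$y_scale, "*"), 2, m$y_center, "+")
}

#' Predict from a fitted mlp
#'
#' @param object a fitted `mlp`.
#' @param newdata samples x features matrix (columns aligned by name when
#'   named).
#' @param type `"response"` (probabilities or regression values on the
#'   original target scale), `"class"` (softmax head only; factor of
#'   predicted labels), or `"prob"` (alias of response for softmax).
#' @param ... unused.
#' @return matrix, or factor for `type = "class"`.
#' @export
predict.mlp <- function(object, newdata, type = c("response", "class", "prob"),
                        ...) {
  type <- match.arg(type)
  out <- mlp_forward(object, newdata)
  if (object$head == "linear") {
    if (type == "class") stop("type = 'class' needs a softmax head",
                              call. = FALSE)
    return(.unscale_y(object, out))
  }
  if (type == "class")
    return(factor(object$output_names[max.col(out, ties.method = "first")],
                  levels = object$output_names))
  out
}

#' Predict antibody titers from day-1 fold changes
#'
#' Thin wrapper around [predict.mlp()] for a linear-head model trained on
#' titer targets: checks the head and feature names and returns the
#' predicted titer matrix with its (HPV type, week) column labels, on the
#' baseline-subtracted scale the model was trained on.
#'
#' @param m a fitted linear-head `mlp`.
#' @param day1_foldchange animals x genes matrix of day-1 fold changes.
#' @return animals x (type, week) matrix of predicted titers.
#' @export
predict_titers <- function(m, day1_foldchange) {
  stopifnot(inherits(m, "mlp"))
  if (m$head != "linear")
    stop("titer prediction needs a linear-head model", call. = FALSE)
  predict(m, day1_foldchange, type = "response")
}

#' @export
print.mlp <- function(x, ...) {
  cat(sprintf("Fully connected network (%s head)\n",
              x$head))
  cat(sprintf("  layers: %d -> %d (ReLU) -> %d\n",
              ncol(x$W1), nrow(x$W1), nrow(x$W2)))
  if (x$trained && length(x$history))
    cat(sprintf("  trained %d epochs, final loss %.6g\n",
                length(x$history), x$history[length(x$history)]))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.mlp <- function(object, ...) {
  out <- list(head = object$head,
              n_features = ncol(object$W1),
              n_hidden = nrow(object$W1),
              n_outputs = nrow(object$W2),
              config = object$config,
              final_loss = if (length(object$history))
                object$history[length(object$history)] else NA_real_)
  if (object$trained && !is.null(object$fitted)) {
    if (object$head == "softmax") {
      cls <- factor(object$output_names[max.col(object$fitted,
                                                ties.method = "first")],
                    levels = object$output_names)
      out$training_accuracy <- mean(cls == object$y)
    } else {
      out$training_rmse <- sqrt(mean((object$fitted - object$y)^2))
    }
  }
  class(out) <- "summary.mlp"
  out
}

#' @export
print.summary.mlp <- function(x, ...) {
  cat(sprintf("mlp: %d -> %d -> %d, %s head\n",
              x$n_features, x$n_hidden, x$n_outputs, x$head))
  cat(sprintf("  epochs %d, learn_rate %g, batch %d, seed %d\n",
              x$config$epochs, x$config$learn_rate, x$config$batch_size,
              x$config$seed))
  if (!is.null(x$training_accuracy))
    cat(sprintf("  training accuracy: %.3f\n", x$training_accuracy))
  if (!is.null(x$training_rmse))
    cat(sprintf("  training RMSE: %.4g\n", x$training_rmse))
  invisible(x)
}

#' @export
coef.mlp <- function(object, ...) {
  list(W1 = object$W1, b1 = object$b1, W2 = object$W2, b2 = object$b2)
}

#' @export
residuals.mlp <- function(object, ...) {
  if (object$head != "linear")
    stop("residuals are defined for the linear (regression) head",
         call. = FALSE)
  object$y - object$fitted
}

#' Plot the training loss curve
#'
#' @param x a fitted `mlp`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mlp <- function(x, ...) {
  if (!length(x$history)) stop("no training history to plot", call. = FALSE)
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "epoch", ylab = "mean batch loss", ...)
  invisible(x)
}

#' Save / load an mlp as JSON
#'
#' Serializes shapes, names, head, configuration and full-precision weight
#' arrays to a single JSON file; `load_mlp()` restores a numerically
#' identical model.
#'
#' @param m a fitted `mlp`.
#' @param path file path.
#' @return `save_mlp()` the path, invisibly; `load_mlp()` the model.
#' @export
save_mlp <- function(m, path) {
  stopifnot(inherits(m, "mlp"))
  obj <- list(
    head = m$head, dims = c(ncol(m$W1), nrow(m$W1), nrow(m$W2)),
    feature_names = m$feature_names, output_names = m$output_names,
    W1 = m$W1, b1 = m$b1, W2 = m$W2, b2 = m$b2,
    x_center = if (!is.null(m$x_std)) m$x_std$center,
    x_scale = if (!is.null(m$x_std)) m$x_std$scale,
    y_center = m$y_center, y_scale = m$y_scale,
    history = m$history, trained = m$trained, config = m$config)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- mlp_init(o$dims[1], o$dims[2], o$dims[3], o$head,
                seed = o$config$seed,
                feature_names = o$feature_names, output_names = o$output_names)
  m$W1 <- matrix(o$W1, nrow = o$dims[2]); m$b1 <- as.numeric(o$b1)
  m$W2 <- matrix(o$W2, nrow = o$dims[3]); m$b2 <- as.numeric(o$b2)
  if (!is.null(o$x_center))
    m$x_std <- structure(list(center = stats::setNames(as.numeric(o$x_center),
                                                       o$feature_names),
                              scale = stats::setNames(as.numeric(o$x_scale),
                                                      o$feature_names)),
                         class = "standardizer")
  m$y_center <- o$y_center; m$y_scale <- o$y_scale
  m$history <- as.numeric(o$history); m$trained <- isTRUE(o$trained)
  m$config <- o$config
  m
}
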