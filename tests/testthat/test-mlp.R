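test_that("initialization is shaped, seeded and validated", {
  m <- mlp_init(1184L, 100L, 8L, "softmax", seed = 1L)
  expect_equal(dim(m$W1), c(100L, 1184L))
  expect_equal(dim(m$W2), c(8L, 100L))
  expect_identical(m$W1, mlp_init(1184L, 100L, 8L, "softmax", seed = 1L)$W1)
  expect_false(identical(m$W1,
                         mlp_init(1184L, 100L, 8L, "softmax", seed = 2L)$W1))
  expect_silent(mlp_init(5L, 1L, 2L, "linear"))      # degenerate width ok
  expect_error(mlp_init(5L, 0L, 2L, "linear"), "positive")
  expect_error(mlp_init(5L, 3L, 2L, "probit"), "arg")
})

test_that("forward pass matches hand evaluation of ReLU plus head", {
  m <- manual_mlp(W1 = diag(2), b1 = c(0, 0), W2 = diag(2), b2 = c(0, 0),
                  head = "softmax")
  p <- mlp_forward(m, c(1, -1))
  expect_equal(as.vector(p), c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-12)

  m0 <- manual_mlp(matrix(0, 2, 2), c(0, 0), matrix(0, 2, 2), c(0, 0))
  expect_equal(as.vector(mlp_forward(m0, c(3.2, -9))), c(0.5, 0.5))

  ml <- manual_mlp(diag(2), c(0, 0), matrix(c(1, 1), 1, 2), 0,
                   head = "linear")
  expect_equal(as.vector(mlp_forward(ml, c(2, 3))), 5)
  expect_error(mlp_forward(ml, c(1, 2, 3)), "features")
})

test_that("softmax output is a probability vector and feature order is immaterial", {
  set.seed(4)
  m <- mlp_init(6L, 5L, 3L, "softmax", seed = 4L,
                feature_names = paste0("g", 1:6))
  m$trained <- TRUE
  x <- matrix(rnorm(30), 5, 6, dimnames = list(NULL, paste0("g", 1:6)))
  p <- mlp_forward(m, x)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
  perm <- sample(6)
  expect_equal(mlp_forward(m, x[, perm]), p, tolerance = 1e-12)
  bad <- x; colnames(bad)[1] <- "other"
  expect_error(mlp_forward(m, bad), "feature names")
})

test_that("training separates a linearly separable toy problem", {
  set.seed(10)
  x <- rbind(matrix(rnorm(20, mean = 2), 10, 2),
             matrix(rnorm(20, mean = -2), 10, 2))
  y <- factor(rep(c("a", "b"), each = 10))
  fit <- mlp(x, y, hidden = 10L, epochs = 500L, seed = 3L)
  expect_equal(mean(predict(fit, x, type = "class") == y), 1)
  expect_length(fit$history, 500L)
  expect_lt(mean(tail(fit$history, 10)), mean(head(fit$history, 10)))
})

test_that("zero epochs leave the initialized weights untouched", {
  set.seed(2)
  x <- matrix(rnorm(40), 20, 2)
  y <- factor(rep(1:2, 10))
  fit <- mlp(x, y, hidden = 4L, epochs = 0L, seed = 9L)
  init <- mlp_init(2L, 4L, 2L, "softmax", seed = 9L)
  expect_identical(fit$W1, init$W1)
  expect_identical(fit$W2, init$W2)
})

test_that("regression head fits noiseless linear targets to high precision", {
  set.seed(5)
  x <- matrix(rnorm(120), 40, 3)
  B <- matrix(c(1, -2, 0.5, 0.3, 1, -1), 2, 3)
  y <- x %*% t(B)
  fit <- mlp(x, y, hidden = 30L, epochs = 2000L, learn_rate = 0.05,
             batch_size = 8L, seed = 2L)
  pred <- predict(fit, x)
  rmse <- sqrt(mean((pred - y)^2))
  expect_lt(rmse, 1e-2 * sd(y))
})

test_that("training is reproducible and diverging configurations abort", {
  set.seed(6)
  x <- matrix(rnorm(60), 30, 2)
  y <- factor(rep(1:2, 15))
  f1 <- mlp(x, y, hidden = 6L, epochs = 40L, seed = 5L)
  f2 <- mlp(x, y, hidden = 6L, epochs = 40L, seed = 5L)
  expect_identical(f1$W1, f2$W1)
  expect_identical(f1$history, f2$history)
  yr <- matrix(rnorm(30) * 1e6, 30, 1)
  expect_error(mlp(x, yr, epochs = 50L, learn_rate = 1e6, scale_y = FALSE,
                   seed = 1L),
               "diverged")
})

test_that("analytic gradients match central finite differences", {
  for (head in c("softmax", "linear")) {
    set.seed(7)
    m <- mlp_init(4L, 3L, 2L, head, seed = 7L)
    x <- matrix(rnorm(20), 5, 4)
    y <- if (head == "softmax") {
      yy <- matrix(0, 5, 2); yy[cbind(1:5, sample(1:2, 5, TRUE))] <- 1; yy
    } else matrix(rnorm(10), 5, 2)
    g <- adjuvantnet:::.mlp_grad(m, x, y)
    h <- 1e-6
    num_grad <- function(get, set) {
      w <- get(m)
      gn <- if (is.matrix(w)) array(0, dim = dim(w)) else numeric(length(w))
      for (i in seq_along(w)) {
        mp <- m; mm <- m
        wp <- w; wp[i] <- wp[i] + h
        wm <- w; wm[i] <- wm[i] - h
        mp <- set(mp, wp); mm <- set(mm, wm)
        gn[i] <- (adjuvantnet:::.mlp_grad(mp, x, y)$loss -
                    adjuvantnet:::.mlp_grad(mm, x, y)$loss) / (2 * h)
      }
      gn
    }
    checks <- list(
      list(a = g$gW1, n = num_grad(function(m) m$W1,
                                   function(m, w) { m$W1 <- w; m })),
      list(a = g$gW2, n = num_grad(function(m) m$W2,
                                   function(m, w) { m$W2 <- w; m })),
      list(a = g$gb1, n = num_grad(function(m) m$b1,
                                   function(m, w) { m$b1 <- w; m })),
      list(a = g$gb2, n = num_grad(function(m) m$b2,
                                   function(m, w) { m$b2 <- w; m })))
    for (ck in checks) {
      denom <- pmax(abs(ck$n), 1e-3)
      expect_lt(max(abs(as.vector(ck$a) - as.vector(ck$n)) / denom), 1e-5)
    }
  }
})

test_that("JSON serialization round-trips a trained model losslessly", {
  set.seed(8)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("gA", "gB", "gC")))
  y <- factor(rep(1:2, 10))
  fit <- mlp(x, y, hidden = 5L, epochs = 30L, seed = 4L)
  path <- tempfile(fileext = ".json")
  save_mlp(fit, path)
  back <- load_mlp(path)
  expect_equal(back$W1, fit$W1)
  expect_equal(back$W2, fit$W2)
  expect_equal(back$b1, fit$b1)
  expect_equal(back$b2, fit$b2)
  expect_equal(predict(back, x, type = "prob"), predict(fit, x, type = "prob"))
  unlink(path)
})

test_that("a network embedding the generative coefficients reproduces titers", {
  s <- small_study()
  tm <- s$titer_model
  drivers <- tm$driver_genes
  B <- tm$coefficients
  nd <- length(drivers)
  # [I; -I] hidden layer + [B, -B] output layer computes Bx exactly through
  # the ReLU for any sign of x
  m <- manual_mlp(W1 = rbind(diag(nd), -diag(nd)), b1 = rep(0, 2 * nd),
                  W2 = cbind(B, -B), b2 = rep(0, 9),
                  head = "linear", feature_names = drivers,
                  output_names = rownames(B))
  titers0 <- generate_titers(s$meta, s$expr,
                             titer_model(drivers, coefficients = B,
                                         dose_boost = 0, titer_noise_sd = 0,
                                         seed = 31L))
  post <- subtract_titer_baseline(titers0)
  animals <- unique(s$meta$animal_id)
  x <- t(log10(s$expr[drivers, paste0(animals, "_d1_day1")] + 0.01) + 0.01)
  rownames(x) <- animals
  pred <- predict_titers(m, x)
  w12 <- post[post$week == 12, ]
  for (i in seq_len(nrow(w12))) {
    expect_equal(w12$value[i],
                 pred[w12$animal_id[i], paste0("HPV", w12$hpv_type[i])],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # zero input returns the learned bias (here zero)
  expect_equal(as.vector(predict_titers(m, matrix(0, 1, nd,
                                                  dimnames = list(NULL, drivers)))),
               rep(0, 9))
  expect_error(predict_titers(manual_mlp(diag(2), c(0, 0), diag(2), c(0, 0)),
                              matrix(0, 1, 2)), "linear")
})

test_that("model methods summarise, extract and plot without error", {
  set.seed(9)
  x <- matrix(rnorm(80), 40, 2)
  y <- factor(rep(c("u", "v"), 20))
  fit <- mlp(x, y, hidden = 4L, epochs = 60L, seed = 6L)
  expect_output(print(fit), "softmax")
  sm <- summary(fit)
  expect_true(sm$training_accuracy >= 0.5)
  expect_named(coef(fit), c("W1", "b1", "W2", "b2"))
  yr <- matrix(x[, 1] + 0.1 * rnorm(40), 40, 1)
  rfit <- mlp(x, yr, hidden = 4L, epochs = 200L, seed = 6L)
  expect_equal(dim(residuals(rfit)), c(40L, 1L))
  expect_error(residuals(fit), "linear")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
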