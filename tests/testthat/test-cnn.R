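make_sep_slice <- function(n = 24, seed = 1) {
  # threshold-separable phantom: bright disk on dark background
  set.seed(seed)
  x <- matrix(0.2, n, n) + matrix(rnorm(n * n, 0, 0.02), n, n)
  cx <- (n + 1) / 2
  d2 <- outer((1:n - cx)^2, (1:n - cx)^2, "+")
  x[d2 < (n / 4)^2] <- 0.8 + rnorm(sum(d2 < (n / 4)^2), 0, 0.02)
  y <- (d2 < (n / 4)^2) * 1L
  list(x = pmin(pmax(x, 0), 1), y = y)
}

test_that("model construction enforces the architecture ranges and output contracts", {
  expect_error(cnn_spec(n_conv_layers = 5), "1..4")
  expect_error(cnn_spec(filters_per_layer = 3), "5..20")
  model <- build_cnn(cnn_spec(n_conv_layers = 2, filters_per_layer = 8,
                              n_classes = 2), seed = 1)
  fwd <- cnn_forward(model, matrix(runif(32 * 32), 32, 32))
  expect_equal(dim(fwd$P), c(32, 32))
  expect_true(all(fwd$P > 0 & fwd$P < 1))
  m9 <- build_cnn(cnn_spec(n_conv_layers = 2, filters_per_layer = 6,
                           n_classes = 9), seed = 1)
  f9 <- cnn_forward(m9, matrix(runif(40 * 40), 40, 40))
  expect_equal(dim(f9$P), c(40, 40, 9))
  sums <- apply(f9$P, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("parameter count is independent of the ROI size", {
  model <- build_cnn(cnn_spec(n_conv_layers = 3, filters_per_layer = 7,
                              n_classes = 9), seed = 2)
  n_par <- cnn_n_params(model)
  # layer arithmetic oracle: conv (9*cin+1)*F, specialized (9*F+1)*F,
  # head (L*F+1)*S
  Fh <- 7; L <- 3; S <- 9
  expected <- (9 * 1 + 1) * Fh + (L - 1) * (9 * Fh + 1) * Fh +
    L * (9 * Fh + 1) * Fh + (L * Fh + 1) * S
  expect_equal(n_par, expected)
  # doubling the ROI changes activations, not parameters
  f1 <- cnn_forward(model, matrix(runif(24^2), 24, 24))
  f2 <- cnn_forward(model, matrix(runif(48^2), 48, 48))
  expect_equal(dim(f2$P)[1:2], c(48, 48))
  expect_equal(cnn_n_params(model), n_par)
})

test_that("analytic gradients match finite differences", {
  set.seed(5)
  x <- matrix(runif(8 * 8), 8, 8)
  for (mode in c("cbce", "bfl")) {
    nc <- if (mode == "cbce") 2L else 9L
    model <- build_cnn(cnn_spec(n_conv_layers = 1, filters_per_layer = 5,
                                n_classes = nc), seed = 3)
    Y <- if (mode == "cbce") matrix(rbinom(64, 1, 0.4), 8, 8)
    else {
      lab <- matrix(sample.int(9, 64, replace = TRUE), 8, 8)
      oh <- array(0, c(8, 8, 9)); for (k in 1:9) oh[, , k] <- lab == k
      oh
    }
    lossfun <- function(model) {
      fwd <- cnn_forward(model, x)
      if (mode == "cbce") class_balanced_cross_entropy(fwd$P, Y)
      else balanced_focal_loss(fwd$P, Y, gamma = 2)
    }
    fwd <- cnn_forward(model, x)
    dz <- if (mode == "cbce")
      array(rhinoflow:::cbce_logit_grad(fwd$P, Y), c(8, 8, 1))
    else rhinoflow:::bfl_logit_grad(fwd$P, Y, gamma = 2)
    gr <- cnn_backward(model, fwd, dz)
    h <- 1e-5
    # a few weights from each parameter group
    checks <- list(
      list(get = function(m) m$params$conv[[1]]$W[3, 2],
           set = function(m, v) { m$params$conv[[1]]$W[3, 2] <- v; m },
           g = gr$conv[[1]]$dW[3, 2]),
      list(get = function(m) m$params$spec_conv[[1]]$W[10, 4],
           set = function(m, v) { m$params$spec_conv[[1]]$W[10, 4] <- v; m },
           g = gr$spec_conv[[1]]$dW[10, 4]),
      list(get = function(m) m$params$head$W[2, 1],
           set = function(m, v) { m$params$head$W[2, 1] <- v; m },
           g = gr$head$dW[2, 1]),
      list(get = function(m) m$params$conv[[1]]$b[1],
           set = function(m, v) { m$params$conv[[1]]$b[1] <- v; m },
           g = gr$conv[[1]]$db[1]))
    for (ck in checks) {
      v0 <- ck$get(model)
      num <- (lossfun(ck$set(model, v0 + h)) -
                lossfun(ck$set(model, v0 - h))) / (2 * h)
      expect_equal(ck$g, num, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic and learns a separable slice", {
  sl <- make_sep_slice()
  ds <- slice_dataset(list(sl$x), list(sl$y), n_classes = 2L)
  model <- build_cnn(cnn_spec(n_conv_layers = 1, filters_per_layer = 6,
                              n_classes = 2), seed = 7)
  tr1 <- train_cnn(model, ds, loss_config("cbce"), max_iter = 300, seed = 9)
  tr2 <- train_cnn(model, ds, loss_config("cbce"), max_iter = 300, seed = 9)
  expect_identical(tr1$history$cost, tr2$history$cost)
  pred <- predict_segmentation(tr1$model, sl$x)
  expect_gt(mean(pred[, , 1] == sl$y), 0.99)
  expect_true(all(is.finite(tr1$history$cost)))
})

test_that("a zero learning rate freezes the cost and triggers the
          convergence rule after the patience window", {
  sl <- make_sep_slice()
  ds <- slice_dataset(list(sl$x), list(sl$y), n_classes = 2L)
  spec <- cnn_spec(n_conv_layers = 1, filters_per_layer = 5, n_classes = 2,
                   learning_rate = 0)
  model <- build_cnn(spec, seed = 7)
  tr <- train_cnn(model, ds, loss_config("cbce"), max_iter = 200, seed = 1)
  expect_true(tr$converged)
  expect_lte(tr$convergence_iteration, 40)
  expect_equal(var(tr$history$cost), 0)
})

test_that("prediction handles ROI windows and breaks argmax ties low", {
  model <- build_cnn(cnn_spec(n_conv_layers = 1, filters_per_layer = 5,
                              n_classes = 9), seed = 1)
  # zero out the head: uniform probabilities, ties resolve to class 0
  model$params$head$W[] <- 0
  model$params$head$b[] <- 0
  vol <- array(runif(20 * 20 * 3), c(20, 20, 3))
  lab <- predict_segmentation(model, vol)
  expect_equal(dim(lab), c(20, 20, 3))
  expect_true(all(lab == 0L))
  expect_error(predict_segmentation(model, vol, roi = 32), "exceeds")
  lab2 <- predict_segmentation(model, vol, roi = 10)
  expect_equal(dim(lab2), c(10, 10, 3))
})
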