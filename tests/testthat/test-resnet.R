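test_that("task defaults follow the training recipe", {
  cc <- resnet_config(task = "classification")
  expect_equal(cc$loss, "softmax_cross_entropy")
  expect_equal(cc$epochs, 1000L)
  expect_equal(cc$learning_rate, 0.01)
  expect_equal(cc$dropout, 0.3)
  cr <- resnet_config(task = "regression")
  expect_equal(cr$loss, "l2")
  expect_equal(cr$epochs, 1500L)
  expect_equal(cr$learning_rate, 1e-4)
})

test_that("the 1-D builder respects the head contract and input bounds", {
  cfg <- resnet_config(task = "classification", n_bands = 64)
  net <- build_resnet_1d(cfg)
  head <- net$layers[[length(net$layers)]]
  expect_equal(head$type, "dense")
  expect_equal(head$n_out, 4L)
  reg <- build_resnet_1d(resnet_config(task = "regression", n_bands = 64))
  expect_equal(reg$layers[[length(reg$layers)]]$n_out, 1L)
  expect_error(build_resnet_1d(resnet_config(n_bands = 16)), "32")
  # zero input propagates to finite logits
  x0 <- array(0, c(1, 1, 64, 1, 3))
  out <- ripenet:::nn_forward(net, x0, training = FALSE)
  expect_true(all(is.finite(out)))
  expect_equal(dim(out), c(4L, 3L))
})

test_that("parameter counts match a layer-by-layer arithmetic tally", {
  cfg <- resnet_config(task = "classification", n_bands = 64)
  net <- build_resnet_1d(cfg)
  # independent tally for stem 7x1->16, stages (16,32,64) compressed by 4,
  # one pre-activation bottleneck per stage, BN everywhere, dense head
  conv_p <- function(k, cin, cout) k * cin * cout + cout
  bn_p <- function(c) 2 * c
  block_p <- function(cin, w, mid, shortcut) {
    p <- bn_p(cin) + conv_p(1, cin, mid) +
      bn_p(mid) + conv_p(3, mid, mid) +
      bn_p(mid) + conv_p(1, mid, w)
    if (shortcut) p <- p + conv_p(1, cin, w)
    p
  }
  tally <- conv_p(7, 1, 16) + bn_p(16) +
    block_p(16, 16, 4, FALSE) +
    block_p(16, 32, 8, TRUE) +
    block_p(32, 64, 16, TRUE) +
    bn_p(64) + (64 * 4 + 4)
  expect_equal(n_parameters(net), tally)
})

test_that("classification and regression share an identical trunk", {
  sh <- function(task) {
    net <- build_resnet_1d(resnet_config(task = task, n_bands = 64,
                                         seed = 1))
    lapply(ripenet:::nn_param_shapes(net), unname)
  }
  a <- sh("classification")
  b <- sh("regression")
  expect_equal(length(a), length(b))
  # all parameter shapes agree except the dense head (last two entries)
  expect_identical(head(a, -2), head(b, -2))
  expect_false(identical(a[length(a) - 1], b[length(b) - 1]))
})

test_that("the 3-D builder runs a desk-scale forward pass quickly", {
  cfg <- resnet_config(task = "classification", input_kind = "cube",
                       n_bands = 32, spatial_dims = c(16, 16))
  net <- build_resnet_3d(cfg)
  x <- array(0.5, c(16, 16, 32, 1, 2))
  t0 <- Sys.time()
  out <- ripenet:::nn_forward(net, x, training = FALSE)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_true(all(is.finite(out)))
  expect_error(build_resnet_3d(resnet_config(spatial_dims = c(8, 8))),
               "16")
})

test_that("training overfits separable spectra and reduces the loss", {
  d <- separable_spectra(2, seed = 10)
  fit <- resnet(d$x, d$y,
                config = fast_config("classification", 200, seed = 2))
  expect_equal(mean(predict(fit, d$x) == as.character(d$y)), 1)
  expect_lt(fit$log$train_loss[nrow(fit$log)], fit$log$train_loss[1])
})

test_that("regression capacity: noise-free linear target is learned", {
  set.seed(6)
  x <- matrix(rnorm(48 * 64), 48, 64)
  y <- 9 + 1.5 * x[, 10]
  fit <- resnet(x, y, config = fast_config("regression", 1500, seed = 3))
  rmse <- sqrt(mean((fitted(fit) - y)^2))
  expect_lt(rmse, 0.1 * sd(y))
  expect_equal(residuals(fit), y - fitted(fit))
})

test_that("prediction is deterministic in eval mode with dropout off", {
  d <- separable_spectra(3, seed = 4)
  fit <- resnet(d$x, d$y,
                config = fast_config("classification", 30, seed = 7))
  p1 <- predict(fit, d$x, type = "prob")
  p2 <- predict(fit, d$x, type = "prob")
  expect_identical(p1, p2)
  expect_true(all(abs(rowSums(p1) - 1) < 1e-6))
  dup <- rbind(d$x[1, , drop = FALSE], d$x[1, , drop = FALSE])
  pd <- predict(fit, dup, type = "prob")
  expect_identical(pd[1, ], pd[2, ])
  expect_error(predict(fit, d$x[, 1:10]), "matrix|contract")
  expect_error(residuals(fit), "regression")
})

test_that("validation monitoring retains the best snapshot", {
  d <- separable_spectra(4, seed = 5)
  hold <- separable_spectra(2, seed = 6)
  fit <- resnet(d$x, d$y,
                config = fast_config("classification", 60, seed = 8),
                validation = list(x = hold$x, y = hold$y))
  expect_true(is.finite(fit$best_epoch))
  expect_true(any(!is.na(fit$log$val_metric)))
  acc_best <- mean(predict(fit, hold$x, model = "best") ==
                     as.character(hold$y))
  expect_equal(acc_best, max(fit$log$val_metric, na.rm = TRUE),
               tolerance = 1e-12)
})
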