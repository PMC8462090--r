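test_that("gradients of a linear map equal its weights", {
  net <- ripenet:::nn_network(list(ripenet:::nn_dense(5, 1)))
  w <- c(0.5, -1, 2, 0, 3)
  net$layers[[1]]$W <- matrix(w, 1, 5)
  x <- matrix(rnorm(5 * 4), 5, 4)
  out <- ripenet:::nn_forward(net, x, training = FALSE)
  expect_equal(as.numeric(out), as.numeric(w %*% x + net$layers[[1]]$b))
  g <- ripenet:::nn_backward(net, matrix(1, 1, 4))
  expect_equal(abs(g), matrix(abs(w), 5, 4), tolerance = 1e-14)
  # all-zero weights give a zero gradient
  net$layers[[1]]$W[] <- 0
  ripenet:::nn_forward(net, x, training = FALSE)
  expect_true(all(ripenet:::nn_backward(net, matrix(1, 1, 4)) == 0))
})

test_that("input gradients match central finite differences", {
  set.seed(15)
  x <- matrix(rnorm(24 * 64), 24, 64)
  y <- 9 + 2 * x[, 7] - x[, 30]
  fit <- resnet(x, y, config = fast_config("regression", 80, seed = 4))
  xs <- ripenet:::resnet_standardize(
    ripenet:::resnet_tensor(x),
    list(center = fit$x_center, scale = fit$x_scale))
  net <- fit$net
  ripenet:::nn_set_state(net, fit$state_best)
  ripenet:::nn_forward(net, xs, training = FALSE)
  g <- ripenet:::nn_backward(net, matrix(1, 1, 24)) + 0
  eps <- 1e-5
  set.seed(16)
  for (t in 1:20) {
    s <- sample(24, 1); b <- sample(64, 1)
    xp <- xs; xp[1, 1, b, 1, s] <- xp[1, 1, b, 1, s] + eps
    xm <- xs; xm[1, 1, b, 1, s] <- xm[1, 1, b, 1, s] - eps
    op <- ripenet:::nn_forward(net, ripenet:::nn_slice(xp, s),
                               training = FALSE)[1, 1]
    om <- ripenet:::nn_forward(net, ripenet:::nn_slice(xm, s),
                               training = FALSE)[1, 1]
    fd <- (op - om) / (2 * eps)
    expect_equal(g[1, 1, b, 1, s], fd,
                 tolerance = 1e-3 * max(abs(fd), 1e-6))
  }
  # the exported accessor returns |gradient| per band
  ig <- input_gradient(fit, x)
  expect_equal(dim(ig), c(24L, 64L))
  expect_true(all(ig >= 0))
})

test_that("correct-classification selection equals the comparison loop", {
  d <- separable_spectra(3, seed = 20)
  fit <- resnet(d$x, d$y,
                config = fast_config("classification", 150, seed = 5))
  pred <- predict(fit, d$x)
  sel <- select_correct_classified(fit, d$x, d$y)
  oracle <- integer(0)
  for (i in seq_along(pred)) {
    if (pred[i] == as.character(d$y[i])) oracle <- c(oracle, i)
  }
  expect_identical(sel, oracle)
  expect_identical(sel, seq_along(pred))  # separable set: all correct
  # a constant predictor keeps exactly one balanced class
  const_pred <- rep("0", length(pred))
  sel0 <- select_correct_classified(NULL, d$x, d$y,
                                    predictions = const_pred)
  expect_equal(length(sel0) / length(pred), 0.25)
})

test_that("the prediction-error-rate rule is thresholded arithmetic", {
  y <- c(10, 10, 8, 0, 12)
  pred <- c(9.4, 10.2, 8.9, 1, 12.1)
  expect_warning(
    sel5 <- select_correct_regression(NULL, NULL, y, 0.05,
                                      predictions = pred),
    "non-positive")
  expect_identical(sel5, c(2L, 5L))  # sample 1 at 6% misses the 5% rule
  sel10 <- suppressWarnings(
    select_correct_regression(NULL, NULL, y, 0.10, predictions = pred))
  expect_identical(sel10, c(1L, 2L, 5L))
  expect_true(all(sel5 %in% sel10))
  # perfect predictions are always kept
  expect_identical(
    select_correct_regression(NULL, NULL, y[-4], 0.05,
                              predictions = y[-4]),
    1:4)
  expect_error(select_correct_regression(NULL, NULL, y, 1.5,
                                         predictions = pred), "\\(0, 1\\)")
})

test_that("the 5% rule set is nested in the 10% rule set", {
  set.seed(22)
  for (rep in 1:20) {
    y <- runif(30, 6, 13)
    pred <- y + rnorm(30, sd = 0.8)
    s5 <- select_correct_regression(NULL, NULL, y, 0.05,
                                    predictions = pred)
    s10 <- select_correct_regression(NULL, NULL, y, 0.10,
                                     predictions = pred)
    expect_true(all(s5 %in% s10))
  }
})

test_that("wavelength contributions are normalized and scale-invariant", {
  wl <- seq(441, 947, length.out = 20)
  g <- matrix(0, 1, 20)
  g[1, 7] <- 4.2
  prof <- wavelength_contributions(g, wl)
  expect_equal(prof$contributions, replace(rep(0, 20), 7, 1))
  set.seed(23)
  gr <- matrix(abs(rnorm(6 * 20)), 6, 20)
  p1 <- wavelength_contributions(gr, wl)
  expect_lt(abs(sum(p1$contributions) - 1), 1e-9)
  p2 <- wavelength_contributions(37.5 * gr, wl)
  expect_equal(p1$contributions, p2$contributions, tolerance = 1e-12)
  expect_error(wavelength_contributions(gr[0, , drop = FALSE], wl),
               "no samples")
  expect_error(wavelength_contributions(gr * 0, wl), "zero")
  # 3-D gradients: spatial pixels pool into the band profile
  ga <- array(abs(rnorm(4 * 4 * 20 * 3)), c(4, 4, 20, 3))
  p3 <- wavelength_contributions(ga, wl)
  oracle <- apply(ga, 3, sum)
  expect_equal(p3$contributions, oracle / sum(oracle), tolerance = 1e-12)
})

test_that("pixel saliency highlights the fruit over the background", {
  pc <- phantom_config(image_height = 16, image_width = 16,
                       n_crop_bands = 32)
  ds <- suppressMessages(simulate_dataset(10, pc, master_seed = 8))
  prep <- lapply(ds$phantoms, function(ph) {
    preprocess_cube(ph$cube, resize_to = c(16, 16))
  })
  X3 <- array(0, c(16, 16, 32, 40))
  for (i in 1:40) X3[, , , i] <- prep[[i]]$resized$values
  y <- factor(ds$manifest$label, levels = 0:3)
  cfg <- resnet_config(task = "classification", input_kind = "cube",
                       epochs = 30, batch_size = 32, seed = 5)
  fit <- resnet(X3, y, config = cfg)
  for (i in c(1, 11, 21, 31)) {
    m <- pixel_saliency(fit, X3[, , , i], target = as.character(y[i]))
    fruit <- prep[[i]]$mask
    expect_gt(mean(m[fruit]), mean(m[!fruit]))
  }
})

test_that("pixel saliency maps have spatial dims and zero-model nullity", {
  set.seed(24)
  x3 <- array(rnorm(16 * 16 * 32 * 8), c(16, 16, 32, 8))
  y3 <- factor(rep(0:3, 2), levels = 0:3)
  cfg <- resnet_config(task = "classification", input_kind = "cube",
                       epochs = 3, batch_size = 8, seed = 9)
  fit <- resnet(x3, y3, config = cfg)
  m <- pixel_saliency(fit, x3[, , , 1], target = "0")
  expect_equal(dim(m), c(16L, 16L))
  expect_true(all(m >= 0) && any(m > 0))
  # zero the head: every gradient (and hence the map) vanishes
  fit$state_final[[length(fit$state_final)]]$W[] <- 0
  fit$state_final[[length(fit$state_final)]]$b[] <- 0
  m0 <- pixel_saliency(fit, x3[, , , 1], target = "0")
  expect_true(all(m0 == 0))
})
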