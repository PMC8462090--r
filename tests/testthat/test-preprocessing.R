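make_cube <- function(vals, wl) hyper_cube(vals, wl)

test_that("reflectance calibration is the guarded (raw-dark)/(white-dark)", {
  wl <- 1:5
  d <- c(3, 3, 5)
  dark <- make_cube(array(0.1, d), wl)
  white <- make_cube(array(0.9, d), wl)
  raw_w <- make_cube(array(0.9, d), wl)
  raw_d <- make_cube(array(0.1, d), wl)
  raw_m <- make_cube(array(0.5, d), wl)
  expect_equal(calibrate_reflectance(raw_w, white, dark)$values,
               array(1, d))
  expect_equal(calibrate_reflectance(raw_d, white, dark)$values,
               array(0, d))
  expect_equal(calibrate_reflectance(raw_m, white, dark)$values,
               array(0.5, d))
  bad <- make_cube(array(0.5, c(2, 2, 5)), wl)
  expect_error(calibrate_reflectance(bad, white, dark), "identical shapes")
  dead <- white
  dead$values[1, 1, ] <- dark$values[1, 1, ]
  expect_warning(calibrate_reflectance(raw_m, dead, dark), "clamped")
})

test_that("band cropping keeps the closed wavelength interval", {
  wl <- c(430, 441, 500, 947, 960)
  cube <- make_cube(array(seq_len(4 * 5), c(2, 2, 5)), wl)
  out <- crop_bands(cube)
  expect_equal(out$wavelengths, c(441, 500, 947))
  expect_equal(out$values, cube$values[, , 2:4])
  one <- crop_bands(cube, 500, 500)
  expect_equal(one$wavelengths, 500)
  expect_error(crop_bands(cube, 960.5, 999), "no bands")
  # the reference grid keeps exactly 400 analysis bands
  full <- spectrum(rep(1, 515), grid_for_crop(400))
  expect_length(crop_bands(full)$values, 400L)
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  wl <- seq(441, 947, length.out = 40)
  const <- spectrum(rep(2.5, 40), wl)
  expect_equal(sg_smooth(const)$values, const$values, tolerance = 1e-12)
  quad <- spectrum(3 + 0.5 * (1:40) - 0.01 * (1:40)^2, wl)
  expect_equal(sg_smooth(quad, polyorder = 2)$values, quad$values,
               tolerance = 1e-9)
  expect_error(sg_smooth(quad, window = 10), "odd")
  expect_error(sg_smooth(quad, window = 11, polyorder = 11), "smaller")
})

test_that("SG output equals the pointwise least-squares polynomial fit", {
  set.seed(8)
  n <- 61
  wl <- seq_len(n)
  v <- sin(wl / 5) + rnorm(n, sd = 0.2)
  sp <- sg_smooth(spectrum(v, wl), window = 11, polyorder = 3)
  half <- 5
  for (i in seq(half + 1, n - half, by = 7)) {
    idx <- (i - half):(i + half)
    fit <- lm(y ~ poly(t, 3, raw = TRUE),
              data = data.frame(y = v[idx], t = idx - i))
    expect_equal(sp$values[i], unname(coef(fit)[1]), tolerance = 1e-8)
  }
})

test_that("SG smoothing attenuates i.i.d. noise on smooth spectra", {
  set.seed(9)
  n <- 101
  base <- sin(seq(0, 3, length.out = n))
  ratios <- replicate(100, {
    noise <- rnorm(n, sd = 0.1)
    sm <- sg_smooth(spectrum(base + noise, seq_len(n)))$values
    var(noise) / var(sm - base)
  })
  expect_gt(mean(ratios), 2)
})

test_that("area normalization produces unit-sum, scale-invariant spectra", {
  wl <- 1:4
  expect_equal(area_normalize(spectrum(c(2, 2, 2, 2), wl))$values,
               rep(0.25, 4))
  set.seed(2)
  v <- runif(4) + 0.1
  a <- area_normalize(spectrum(v, wl))$values
  b <- area_normalize(spectrum(7.3 * v, wl))$values
  expect_equal(a, b, tolerance = 1e-14)
  cube <- make_cube(array(runif(3 * 3 * 4) + 0.1, c(3, 3, 4)), wl)
  nrm <- area_normalize(cube)
  sums <- apply(nrm$values, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  neg <- spectrum(c(-1, 0.2, 0.2, 0.2), wl)
  expect_error(area_normalize(neg), "non-positive")
})

test_that("fruit segmentation recovers the phantom mask", {
  ph0 <- simulate_phantom(tiny_phantom_config(noise_sd = 0, seed = 4))
  m0 <- segment_fruit(ph0$cube)
  expect_identical(m0, ph0$fruit_mask)
  ph <- simulate_phantom(tiny_phantom_config(seed = 4))
  m <- segment_fruit(ph$cube)
  jac <- sum(m & ph$fruit_mask) / sum(m | ph$fruit_mask)
  expect_gte(jac, 0.99)
  flat <- make_cube(array(0.02, c(8, 8, 40)), seq(441, 947, length.out = 40))
  expect_error(segment_fruit(flat), "contrast")
})

test_that("mean spectra match a brute-force double-loop average", {
  set.seed(5)
  wl <- 1:6
  cube <- make_cube(array(runif(4 * 5 * 6), c(4, 5, 6)), wl)
  mask <- matrix(runif(20) > 0.4, 4, 5)
  ms <- mean_spectrum(cube, mask)
  oracle <- numeric(6)
  for (b in 1:6) {
    acc <- 0; k <- 0
    for (i in 1:4) for (j in 1:5) if (mask[i, j]) {
      acc <- acc + cube$values[i, j, b]; k <- k + 1
    }
    oracle[b] <- acc / k
  }
  expect_equal(ms$values, oracle, tolerance = 1e-14)
  uni <- make_cube(array(0.7, c(4, 5, 6)), wl)
  expect_equal(mean_spectrum(uni, mask)$values, rep(0.7, 6))
  single <- matrix(FALSE, 4, 5); single[2, 3] <- TRUE
  expect_equal(mean_spectrum(cube, single)$values, cube$values[2, 3, ])
  expect_error(mean_spectrum(cube, matrix(FALSE, 4, 5)), "no pixels")
})

test_that("first derivatives match analytic slopes", {
  wl <- seq(400, 800, by = 2)
  lin <- spectrum(0.003 * wl + 1, wl)
  expect_equal(first_derivative(lin)$values, rep(0.003, length(wl)),
               tolerance = 1e-10)
  const <- spectrum(rep(1, length(wl)), wl)
  expect_equal(first_derivative(const)$values, rep(0, length(wl)),
               tolerance = 1e-12)
  quad <- spectrum((wl - 600)^2 / 1e4, wl)
  d <- first_derivative(quad)$values
  interior <- 10:(length(wl) - 10)
  expect_equal(d[interior], (2 * (wl - 600) / 1e4)[interior],
               tolerance = 1e-8)
  expect_error(first_derivative(spectrum(1, 500)), "at least 2")
})

test_that("spatial resizing preserves constants and identity", {
  wl <- 1:5
  cube <- make_cube(array(0.4, c(12, 10, 5)), wl)
  out <- resize_cube(cube, 85, 85)
  expect_equal(dim(out$values), c(85L, 85L, 5L))
  expect_true(all(abs(out$values - 0.4) < 1e-12))
  set.seed(3)
  rnd <- make_cube(array(runif(12 * 10 * 5), c(12, 10, 5)), wl)
  same <- resize_cube(rnd, 12, 10)
  expect_equal(same$values, rnd$values, tolerance = 1e-12)
  expect_error(resize_cube(rnd, 0, 10), "positive")
})

test_that("band-wise operations commute with spatial averaging", {
  ph <- simulate_phantom(tiny_phantom_config(seed = 14))
  mask <- ph$fruit_mask
  a <- mean_spectrum(crop_bands(ph$cube), mask)
  b <- crop_bands(mean_spectrum(ph$cube, mask))
  expect_equal(a$values, b$values, tolerance = 0)
  expect_equal(a$wavelengths, b$wavelengths)
})

test_that("the preprocessing pipeline is reproducible bit for bit", {
  ph <- simulate_phantom(tiny_phantom_config(seed = 6))
  p1 <- preprocess_cube(ph$cube, resize_to = c(16, 16))
  p2 <- preprocess_cube(ph$cube, resize_to = c(16, 16))
  expect_identical(p1$spectrum$values, p2$spectrum$values)
  expect_identical(p1$resized$values, p2$resized$values)
  # area normalization after smoothing absorbs per-pixel scaling
  scaled <- hyper_cube(ph$cube$values * 3, ph$cube$wavelengths)
  p3 <- preprocess_cube(scaled)
  expect_equal(p3$spectrum$values, p1$spectrum$values, tolerance = 1e-12)
})
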