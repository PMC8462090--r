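test_that("maturity labels follow the red-fraction thresholds on [0, 1]", {
  f <- seq(0, 1, by = 0.001)
  oracle <- ifelse(f <= 0.25, 0L,
                   ifelse(f <= 0.5, 1L, ifelse(f <= 0.75, 2L, 3L)))
  expect_identical(maturity_label(f), oracle)
  expect_identical(maturity_label(0.10), 0L)
  expect_identical(maturity_label(0.80), 3L)
  expect_error(maturity_label(1.2), "\\[0, 1\\]")
})

test_that("endmembers separate in the pigment region, not the NIR", {
  lib <- endmember_library(grid_for_crop(400))
  w <- lib$wavelengths
  d <- abs(lib$green - lib$red)
  vis <- w >= 441 & w <= 700
  nir <- w >= 750 & w <= 947
  expect_true(all(lib$green > 0) && all(lib$red > 0))
  expect_gt(max(d[vis]), 10 * max(d[nir]))
  # equal-area construction over the analysis window
  win <- w >= 441 & w <= 947
  expect_lt(abs(sum(lib$green[win]) - sum(lib$red[win])) /
              sum(lib$green[win]), 0.01)
})

test_that("noiseless phantoms are exact endmember mixtures", {
  cfg <- tiny_phantom_config(red_fraction = 0.8, noise_sd = 0, seed = 3)
  ph <- simulate_phantom(cfg, ssc = 9)
  lib <- endmember_library(cfg$wavelengths)
  bump <- ripenet:::ssc_bump(cfg$wavelengths, 9)
  pix <- matrix(ph$cube$values, ncol = length(cfg$wavelengths))
  fruit <- pix[as.vector(ph$fruit_mask), ]
  d_green <- apply(fruit, 1, function(s) max(abs(s - lib$green - bump)))
  d_red <- apply(fruit, 1, function(s) max(abs(s - lib$red - bump)))
  expect_true(all(pmin(d_green, d_red) < 1e-12))
  # closed-form limit: masked mean spectrum equals the realized mixture
  ms <- mean_spectrum(ph$cube, ph$fruit_mask)
  f <- ph$true_red_fraction
  mix <- f * (lib$red + bump) + (1 - f) * (lib$green + bump)
  expect_equal(ms$values, mix, tolerance = 1e-14)
  expect_identical(ph$maturity_label, 3L)
})

test_that("phantom simulation is deterministic and validates its config", {
  cfg <- tiny_phantom_config(seed = 11)
  a <- simulate_phantom(cfg)
  b <- simulate_phantom(cfg)
  expect_identical(a$cube$values, b$cube$values)
  expect_identical(a$ssc, b$ssc)
  expect_error(phantom_config(red_fraction = -0.1), "\\[0, 1\\]")
  expect_error(phantom_config(noise_sd = -1), "nonnegative")
  expect_error(
    simulate_phantom(tiny_phantom_config(ellipse_a = 0.9)),
    "does not fit")
})

test_that("class spectral separation concentrates in 441-700 nm", {
  cfg <- tiny_phantom_config()
  reps <- c(0.12, 0.38, 0.62, 0.88)
  means <- lapply(seq_along(reps), function(i) {
    cc <- tiny_phantom_config(red_fraction = reps[i], seed = 100 + i)
    ph <- simulate_phantom(cc)
    pp <- preprocess_cube(ph$cube, low = 441, high = 947)
    pp$spectrum
  })
  w <- means[[1]]$wavelengths
  vis <- w >= 441 & w <= 700
  nir <- w >= 750 & w <= 947
  dist_in <- function(keep) {
    d <- 0
    for (i in 1:3) for (j in (i + 1):4) {
      d <- d + sqrt(sum((means[[i]]$values[keep] -
                           means[[j]]$values[keep])^2))
    }
    d / 6
  }
  expect_gt(dist_in(vis), 5 * dist_in(nir))
})

test_that("SSC draws follow the class-conditional distributions", {
  set.seed(42)
  x <- simulate_ssc(3, n = 1e5)
  expect_lt(abs(mean(x) - 10.37), 0.05)
  expect_true(all(x > 0))
  ms <- vapply(0:3, function(cl) mean(simulate_ssc(cl, 5e4)), 0)
  expect_true(all(diff(ms) > 0))
  expect_equal(simulate_ssc(2, 10, sds = rep(0, 4)), rep(9.58, 10))
  expect_error(simulate_ssc(4), "label")
})

test_that("simulated datasets have the requested structure and manifest", {
  cfg <- tiny_phantom_config()
  ds <- simulate_dataset(5, cfg, master_seed = 7)
  expect_equal(nrow(ds$manifest), 20L)
  expect_equal(as.integer(table(ds$manifest$label)), rep(5L, 4))
  expect_identical(ds$manifest$label,
                   maturity_label(ds$manifest$red_fraction))
  ds2 <- simulate_dataset(5, cfg, master_seed = 7)
  expect_identical(ds$manifest, ds2$manifest)
  expect_error(simulate_dataset(0, cfg), "at least 1")
})

test_that("manifest SSC group means track the class distributions", {
  cfg <- phantom_config(image_height = 8L, image_width = 8L,
                        n_crop_bands = 32L)
  ds <- simulate_dataset(1000, cfg, master_seed = 5)
  mns <- tapply(ds$manifest$ssc, ds$manifest$label, mean)
  expect_true(all(abs(mns - c(8.23, 8.57, 9.58, 10.37)) < 0.2))
})

test_that("ENVI cubes round-trip through header + binary files", {
  cfg <- tiny_phantom_config(seed = 21)
  ph <- simulate_phantom(cfg)
  path <- file.path(tempdir(), "cube_roundtrip")
  write_envi(ph$cube, path)
  back <- read_envi(path)
  expect_equal(back$wavelengths, ph$cube$wavelengths, tolerance = 1e-8)
  expect_equal(back$values, ph$cube$values, tolerance = 1e-6)
  unlink(paste0(path, c(".hdr", ".dat")))
})

test_that("dataset export writes cubes and a readable manifest", {
  dir <- file.path(tempdir(), "ds_export")
  ds <- simulate_dataset(1, tiny_phantom_config(), master_seed = 3,
                         dir = dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4L)
  cube <- read_envi(man$path[1])
  expect_equal(cube$values, ds$phantoms[[1]]$cube$values,
               tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
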