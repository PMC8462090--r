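# Shared fixture builders.  Everything is generated in code at test time;
# sizes are kept small so the default run stays fast.

# A small phantom configuration: 16 x 16 pixels, 32 bands retained by the
# analysis crop
tiny_phantom_config <- function(red_fraction = 0.5, noise_sd = 0.01,
                                seed = 1L, ...) {
  phantom_config(image_height = 16L, image_width = 16L, n_crop_bands = 32L,
                 red_fraction = red_fraction, noise_sd = noise_sd,
                 seed = seed, ...)
}

# Linearly separable 4-class spectra: class signal in distinct band blocks
separable_spectra <- function(n_per_class, n_bands = 64L, shift = 3,
                              seed = 1L) {
  set.seed(seed)
  n <- 4L * n_per_class
  x <- matrix(stats::rnorm(n * n_bands, sd = 0.5), n, n_bands)
  y <- rep(0:3, each = n_per_class)
  for (cl in 0:3) {
    bands <- cl * 8L + seq_len(8L)
    x[y == cl, bands] <- x[y == cl, bands] + shift
  }
  list(x = x, y = factor(y, levels = 0:3))
}

# Fast 1-D model configuration for tests
fast_config <- function(task, epochs, n_bands = 64L, seed = 1L, ...) {
  resnet_config(task = task, n_bands = n_bands, epochs = epochs,
                batch_size = 32L, seed = seed, ...)
}

expect_identical_num <- function(a, b) {
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 0)
}
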