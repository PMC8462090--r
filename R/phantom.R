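# Synthetic strawberry phantoms: hyperspectral cubes with an elliptical
# fruit on a dark background, a contiguous red ripened cap grown from the
# fruit apex, class-conditional SSC, and i.i.d. Gaussian sensor noise.

#' Maturity class of a red-area fraction
#'
#' Maturity degrees D1-D4 are encoded 0-3 and defined by the fraction of
#' the fruit surface that is red, with half-open intervals
#' (0, 0.25], (0.25, 0.50], (0.50, 0.75], (0.75, 1].
#'
#' @param red_fraction numeric in \[0, 1\] (vectorized).
#' @return integer labels 0-3.
#' @export
maturity_label <- function(red_fraction) {
  if (any(red_fraction < 0 | red_fraction > 1)) {
    stop("red_fraction must lie in [0, 1]")
  }
  ifelse(red_fraction <= 0.25, 0L,
         ifelse(red_fraction <= 0.50, 1L,
                ifelse(red_fraction <= 0.75, 2L, 3L)))
}

#' Phantom generator configuration
#'
#' @param image_height,image_width image size in pixels.
#' @param wavelength_start,wavelength_end full spectral range in nm.
#' @param n_bands number of bands of the full grid; the default (`NULL`)
#'   solves for the grid whose 441-947 nm crop retains `n_crop_bands`
#'   bands.
#' @param n_crop_bands bands retained by the default analysis crop; 400
#'   reproduces the reference instrument, smaller values give desk-scale
#'   cubes.
#' @param red_fraction fraction of fruit pixels covered by the red cap.
#' @param noise_sd standard deviation of additive Gaussian noise, in
#'   reflectance units (default 1% of full scale).
#' @param ellipse_a,ellipse_b fruit semi-axes as fractions of the image
#'   height and width.
#' @param ssc_amplitude,ssc_center,ssc_width,ssc_reference parameters of the
#'   SSC-proportional near-infrared reflectance bump (see Details); set
#'   `ssc_amplitude = 0` to decouple the spectra from SSC.
#' @param ssc_zero_sum use a zero-sum (difference-of-Gaussians) bump that
#'   integrates to zero over the 441-947 nm window, so area normalization
#'   leaves the perturbation confined to its own support.
#' @param seed integer seed.
#'
#' @details SSC influences pixel spectra through a broad Gaussian bump in
#' the 700-940 nm region with amplitude `ssc_amplitude * (ssc -
#' ssc_reference)` reflectance units, which makes SSC regression learnable
#' from the spectra while leaving the visible pigment region untouched.
#'
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_height = 64L, image_width = 64L,
                           wavelength_start = 380, wavelength_end = 1030,
                           n_bands = NULL, n_crop_bands = 400L,
                           red_fraction = 0.5, noise_sd = 0.01,
                           ellipse_a = 0.42, ellipse_b = 0.35,
                           ssc_amplitude = 0.004, ssc_center = 820,
                           ssc_width = 60, ssc_reference = 8,
                           ssc_zero_sum = FALSE,
                           seed = 1L) {
  if (red_fraction < 0 || red_fraction > 1) {
    stop("red_fraction must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  wl <- if (is.null(n_bands)) {
    grid_for_crop(n_crop_bands, wavelength_start, wavelength_end)
  } else {
    make_wavelength_grid(wavelength_start, wavelength_end, n_bands)
  }
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              wavelengths = wl,
              red_fraction = red_fraction, noise_sd = noise_sd,
              ellipse_a = ellipse_a, ellipse_b = ellipse_b,
              ssc_amplitude = ssc_amplitude, ssc_center = ssc_center,
              ssc_width = ssc_width, ssc_reference = ssc_reference,
              ssc_zero_sum = isTRUE(ssc_zero_sum),
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

phantom_mask <- function(config) {
  h <- config$image_height
  wd <- config$image_width
  a <- config$ellipse_a * h
  b <- config$ellipse_b * wd
  if (a > (h - 1) / 2 || b > (wd - 1) / 2 || a < 1 || b < 1) {
    stop("fruit ellipse does not fit inside the image")
  }
  cr <- (h + 1) / 2
  cc <- (wd + 1) / 2
  r <- matrix(seq_len(h), h, wd)
  cl <- matrix(seq_len(wd), h, wd, byrow = TRUE)
  ((r - cr) / a)^2 + ((cl - cc) / b)^2 <= 1
}

#' Simulate one strawberry phantom
#'
#' Builds an elliptical fruit on a dark background.  A contiguous cap grown
#' from the fruit apex (topmost rows) covering `red_fraction` of the fruit
#' pixels receives the red endmember spectrum, the rest the green one.
#' SSC is drawn from the class-conditional distribution of the assigned
#' maturity degree (unless supplied) and perturbs the near-infrared region
#' of all fruit pixels; i.i.d. Gaussian noise is added per voxel.
#'
#' @param config a [phantom_config()].
#' @param ssc optional fixed SSC value in Brix; the default draws from the
#'   class-conditional normal via [simulate_ssc()].
#' @return an object of class `strawberry_phantom`: a list with `cube`
#'   (a [hyper_cube()]), `fruit_mask`, `true_red_fraction` (the realized
#'   pixel fraction), `maturity_label` (0-3), `ssc` and `config`.
#' @export
simulate_phantom <- function(config, ssc = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  h <- config$image_height
  wd <- config$image_width
  w <- config$wavelengths
  B <- length(w)
  mask <- phantom_mask(config)
  npix <- sum(mask)
  lib <- endmember_library(w)
  label <- maturity_label(config$red_fraction)
  if (is.null(ssc)) ssc <- simulate_ssc(label, n = 1L)

  # red cap grown from the apex: order fruit pixels top-down, breaking ties
  # towards the vertical midline so the cap stays contiguous
  idx <- which(mask, arr.ind = TRUE)
  ord <- order(idx[, 1], abs(idx[, 2] - (wd + 1) / 2), idx[, 2])
  k <- round(config$red_fraction * npix)
  red_lin <- (idx[ord, 2][seq_len(npix) <= k] - 1L) * h +
    idx[ord, 1][seq_len(npix) <= k]

  bump <- ssc_bump(w, ssc, config$ssc_amplitude, config$ssc_center,
                   config$ssc_width, config$ssc_reference,
                   config$ssc_zero_sum)
  pix <- matrix(rep(lib$background, each = h * wd), h * wd, B)
  fruit_lin <- which(as.vector(mask))
  pix[fruit_lin, ] <- rep(lib$green + bump, each = npix)
  if (k > 0) pix[red_lin, ] <- rep(lib$red + bump, each = k)
  if (config$noise_sd > 0) {
    pix <- pix + stats::rnorm(length(pix), sd = config$noise_sd)
    pix[pix < 1e-6] <- 1e-6
  }
  cube <- hyper_cube(array(pix, c(h, wd, B)), w)
  structure(list(cube = cube, fruit_mask = mask,
                 true_red_fraction = k / npix,
                 maturity_label = label, ssc = ssc, config = config),
            class = "strawberry_phantom")
}

#' @export
print.strawberry_phantom <- function(x, ...) {
  cat(sprintf(paste0("strawberry phantom: %d x %d pixels, %d bands, ",
                     "degree D%d (red fraction %.3f), SSC %.2f Brix\n"),
              x$config$image_height, x$config$image_width,
              length(x$cube$wavelengths), x$maturity_label + 1L,
              x$true_red_fraction, x$ssc))
  invisible(x)
}

#' Class-conditional soluble solids content
#'
#' Draws SSC values (degrees Brix) from the maturity-class-conditional
#' normal distributions with means 8.23, 8.57, 9.58, 10.37 and standard
#' deviations 1.15, 0.8, 1.32, 1.71 for degrees D1-D4, truncated at zero.
#'
#' @param label maturity label in 0-3.
#' @param n number of draws.
#' @param means,sds per-class distribution parameters (overridable).
#' @param seed optional seed.
#' @return numeric vector of `n` positive SSC values.
#' @export
simulate_ssc <- function(label, n = 1L,
                         means = c(8.23, 8.57, 9.58, 10.37),
                         sds = c(1.15, 0.8, 1.32, 1.71),
                         seed = NULL) {
  if (length(label) != 1L || !label %in% 0:3) {
    stop("label must be a single value in 0, 1, 2, 3")
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- means[label + 1L]
  sg <- sds[label + 1L]
  out <- stats::rnorm(n, mu, sg)
  while (any(bad <- out <= 0)) out[bad] <- stats::rnorm(sum(bad), mu, sg)
  out
}

#' Simulate a labelled phantom dataset
#'
#' For each maturity class, draws red-area fractions uniformly within the
#' class interval, couples SSC to the class (or decouples it, see
#' `ssc_mode`), simulates the phantoms and returns them with a manifest.
#' With `dir` set, cubes are written as ENVI header + binary pairs and the
#' manifest as CSV.
#'
#' @param n_per_class phantoms per maturity degree.
#' @param config a [phantom_config()] template (its `red_fraction` and
#'   `seed` are overridden per sample).
#' @param master_seed seed from which all per-sample seeds are derived.
#' @param ssc_mode `"class"` draws SSC from the class-conditional normals;
#'   `"independent"` fixes every red fraction at the template value and
#'   draws SSC from a single normal, so the near-infrared SSC bump is the
#'   only SSC-informative signal.
#' @param dir optional output directory for ENVI cubes and manifest.
#' @return an object of class `sample_set`: list with `manifest` (a data
#'   frame with sample_id, label, red_fraction, ssc, path), `phantoms`
#'   (list of [simulate_phantom()] results) and `config`.
#' @export
simulate_dataset <- function(n_per_class, config = phantom_config(),
                             master_seed = 1L,
                             ssc_mode = c("class", "independent"),
                             dir = NULL) {
  ssc_mode <- match.arg(ssc_mode)
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stop("n_per_class must be at least 1")
  set.seed(master_seed)
  n <- 4L * n_per_class
  labels <- rep(0:3, each = n_per_class)
  lo <- c(0, 0.25, 0.50, 0.75)
  if (ssc_mode == "class") {
    fractions <- lo[labels + 1L] + stats::runif(n) * 0.25
    ssc <- numeric(n)
    for (cl in 0:3) {
      ssc[labels == cl] <- simulate_ssc(cl, n_per_class)
    }
  } else {
    fractions <- rep(config$red_fraction, n)
    labels <- rep(maturity_label(config$red_fraction), n)
    ssc <- stats::rnorm(n, 9.2, 1.5)
    while (any(bad <- ssc <= 0)) ssc[bad] <- stats::rnorm(sum(bad), 9.2, 1.5)
  }
  seeds <- sample.int(.Machine$integer.max - 1L, n)

  if (!is.null(dir) && !dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  phantoms <- vector("list", n)
  paths <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$red_fraction <- fractions[i]
    cfg$seed <- seeds[i]
    phantoms[[i]] <- simulate_phantom(cfg, ssc = ssc[i])
    if (!is.null(dir)) {
      paths[i] <- file.path(dir, sprintf("sample_%03d", i))
      write_envi(phantoms[[i]]$cube, paths[i])
    }
  }
  manifest <- data.frame(sample_id = sprintf("sample_%03d", seq_len(n)),
                         label = labels, red_fraction = fractions,
                         ssc = ssc, path = paths,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(manifest = manifest, phantoms = phantoms, config = config,
                 master_seed = master_seed, ssc_mode = ssc_mode),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set: %d phantoms (%s SSC), %d bands\n",
              nrow(x$manifest), x$ssc_mode, length(x$config$wavelengths)))
  print(table(degree = paste0("D", x$manifest$label + 1L)))
  invisible(x)
}
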