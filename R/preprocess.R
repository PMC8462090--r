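# Preprocessing of reflectance cubes into model inputs.  The pipeline order
# is: calibrate -> crop bands -> Savitzky-Golay smooth -> area normalize ->
# (segment + mean spectrum for 1-D models | resize for 3-D models).

#' Spectrum container
#'
#' @param values reflectance vector.
#' @param wavelengths matching wavelength vector in nm.
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(values, wavelengths) {
  values <- as.numeric(values)
  wavelengths <- as.numeric(wavelengths)
  if (length(values) != length(wavelengths)) {
    stop("values and wavelengths must have equal length")
  }
  if (any(!is.finite(values))) stop("spectrum values must be finite")
  structure(list(values = values, wavelengths = wavelengths),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum: %d bands (%.1f-%.1f nm), mean %.4f\n",
              length(x$values), min(x$wavelengths), max(x$wavelengths),
              mean(x$values)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  plot(x$wavelengths, x$values, type = "l", xlab = "wavelength (nm)",
       ylab = "reflectance", ...)
  invisible(x)
}

#' Reflectance calibration with white and dark references
#'
#' Converts raw counts to reflectance as `(raw - dark) / (white - dark)`,
#' voxel by voxel.  Denominators below `floor` (dead pixels) are clamped to
#' `floor` and the affected voxels counted in a warning.
#'
#' @param raw,white,dark [hyper_cube()]s with identical shapes and
#'   wavelength grids.
#' @param floor denominator clamp.
#' @return calibrated [hyper_cube()].
#' @export
calibrate_reflectance <- function(raw, white, dark, floor = 1e-6) {
  stopifnot(inherits(raw, "hyper_cube"), inherits(white, "hyper_cube"),
            inherits(dark, "hyper_cube"))
  if (!identical(dim(raw$values), dim(white$values)) ||
      !identical(dim(raw$values), dim(dark$values))) {
    stop("raw, white and dark cubes must have identical shapes")
  }
  if (max(abs(raw$wavelengths - white$wavelengths)) > 1e-9 ||
      max(abs(raw$wavelengths - dark$wavelengths)) > 1e-9) {
    stop("wavelength grids differ between the reference cubes")
  }
  den <- white$values - dark$values
  n_flagged <- sum(den < floor)
  if (n_flagged > 0) {
    warning(n_flagged, " voxels with near-zero white-dark difference were ",
            "clamped")
    den[den < floor] <- floor
  }
  hyper_cube((raw$values - dark$values) / den, raw$wavelengths)
}

#' Crop a cube or spectrum to a wavelength window
#'
#' Retains exactly the bands with `low <= wavelength <= high` (closed
#' interval).  On the default full-range phantom grid the default window
#' 441-947 nm retains 400 bands.
#'
#' @param x a [hyper_cube()] or [spectrum()].
#' @param low,high window bounds in nm.
#' @return the cropped object, same class as `x`.
#' @export
crop_bands <- function(x, low = 441, high = 947) {
  if (low > high) stop("low must not exceed high")
  w <- x$wavelengths
  keep <- w >= low - 1e-9 & w <= high + 1e-9
  if (!any(keep)) stop("no bands fall inside [", low, ", ", high, "]")
  if (inherits(x, "hyper_cube")) {
    hyper_cube(x$values[, , keep, drop = FALSE], w[keep])
  } else if (inherits(x, "spectrum")) {
    spectrum(x$values[keep], w[keep])
  } else {
    stop("x must be a hyper_cube or spectrum")
  }
}

# Full bands x bands Savitzky-Golay operator: interior rows apply the
# central filter, the first/last half-windows use the corresponding
# least-squares polynomial fits over the end windows.  m = 0 smooths,
# m = 1 differentiates (per index step).
sg_operator <- function(n_bands, window, polyorder, m = 0L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (window > n_bands) stop("window exceeds the number of bands")
  Fm <- unclass(signal::sgolay(p = polyorder, n = window, m = m))
  half <- (window - 1L) %/% 2L
  S <- matrix(0, n_bands, n_bands)
  for (i in seq_len(half)) S[i, seq_len(window)] <- Fm[i, ]
  for (i in seq(half + 1L, n_bands - half)) {
    S[i, (i - half):(i + half)] <- Fm[half + 1L, ]
  }
  for (i in seq(n_bands - half + 1L, n_bands)) {
    S[i, (n_bands - window + 1L):n_bands] <- Fm[window - (n_bands - i), ]
  }
  S
}

#' Savitzky-Golay smoothing along the spectral axis
#'
#' Each pixel spectrum is replaced by its local least-squares polynomial
#' fit; polynomials of degree up to `polyorder` are reproduced exactly.
#' Edges are handled by the polynomial fits over the first and last
#' windows.
#'
#' @param x a [hyper_cube()] or [spectrum()].
#' @param window odd filter window length (bands); default 11.
#' @param polyorder polynomial order, less than `window`; default 3.
#' @return smoothed object, same class and shape as `x`.
#' @export
sg_smooth <- function(x, window = 11L, polyorder = 3L) {
  if (inherits(x, "hyper_cube")) {
    d <- dim(x$values)
    S <- sg_operator(d[3], window, polyorder)
    M <- matrix(x$values, nrow = d[1] * d[2]) %*% t(S)
    hyper_cube(array(M, d), x$wavelengths)
  } else if (inherits(x, "spectrum")) {
    S <- sg_operator(length(x$values), window, polyorder)
    spectrum(as.numeric(S %*% x$values), x$wavelengths)
  } else {
    stop("x must be a hyper_cube or spectrum")
  }
}

#' Pixel-wise area normalization
#'
#' Divides every pixel spectrum by the sum of its values so each spectrum
#' sums to one, removing brightness and sample-shape effects.
#'
#' @param x a [hyper_cube()] or [spectrum()].
#' @return normalized object, same class and shape as `x`.
#' @export
area_normalize <- function(x) {
  if (inherits(x, "hyper_cube")) {
    d <- dim(x$values)
    M <- matrix(x$values, nrow = d[1] * d[2])
    s <- rowSums(M)
    if (any(s <= 0)) {
      stop(sum(s <= 0), " pixel spectra have non-positive sums and cannot ",
           "be area-normalized")
    }
    hyper_cube(array(M / s, d), x$wavelengths)
  } else if (inherits(x, "spectrum")) {
    s <- sum(x$values)
    if (s <= 0) stop("spectrum sum is non-positive")
    spectrum(x$values / s, x$wavelengths)
  } else {
    stop("x must be a hyper_cube or spectrum")
  }
}

#' Segment the fruit from the background
#'
#' Thresholds a high near-infrared band (Otsu's criterion), where fruit
#' tissue is far brighter than the stage, and keeps the largest connected
#' component.
#'
#' @param cube a calibrated (optionally normalized) [hyper_cube()].
#' @param nir_wavelength band used for thresholding, in nm (nearest grid
#'   band is taken).
#' @return logical rows x cols matrix, `TRUE` on fruit pixels.
#' @export
segment_fruit <- function(cube, nir_wavelength = 800) {
  stopifnot(inherits(cube, "hyper_cube"))
  b <- which.min(abs(cube$wavelengths - nir_wavelength))
  band <- cube$values[, , b]
  rg <- range(band)
  if (diff(rg) < 1e-12) stop("no contrast at the segmentation band")
  thr <- EBImage::otsu(EBImage::Image(band), range = rg)
  mask <- band > thr
  if (!any(mask)) stop("segmentation produced an empty mask")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(lab[lab > 0])
  mask <- matrix(as.integer(lab) == which.max(tab), nrow(band), ncol(band))
  mask
}

#' Mean spectrum over a pixel mask
#'
#' @param cube a [hyper_cube()].
#' @param mask logical rows x cols matrix; must select at least one pixel.
#' @return a [spectrum()]: the per-band arithmetic mean over masked pixels.
#' @export
mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2])) {
    stop("mask must be a logical matrix matching the cube's spatial size")
  }
  if (!any(mask)) stop("mask selects no pixels")
  M <- matrix(cube$values, nrow = d[1] * d[2])
  spectrum(colMeans(M[as.vector(mask), , drop = FALSE]), cube$wavelengths)
}

#' First-derivative spectrum
#'
#' Savitzky-Golay first derivative with respect to wavelength (nm^-1),
#' consistent with the smoothing filter; spectra shorter than the window
#' fall back to central finite differences with replicated edges.
#'
#' @param x a [spectrum()].
#' @param window,polyorder as in [sg_smooth()].
#' @return a [spectrum()] of the same length holding the derivative.
#' @export
first_derivative <- function(x, window = 11L, polyorder = 3L) {
  stopifnot(inherits(x, "spectrum"))
  n <- length(x$values)
  if (n < 2L) stop("at least 2 bands are required")
  step <- mean(diff(x$wavelengths))
  if (n >= window) {
    S <- sg_operator(n, window, polyorder, m = 1L)
    d <- as.numeric(S %*% x$values) / step
  } else {
    v <- x$values
    d <- c(v[2] - v[1], (v[seq(3, n)] - v[seq(1, n - 2)]) / 2,
           v[n] - v[n - 1]) / step
  }
  spectrum(d, x$wavelengths)
}

#' Spatial resize of a cube
#'
#' Per-band bilinear interpolation to a new spatial size; the spectral axis
#' is untouched.  The reference contract for 3-D models resizes every fruit
#' cube to 85 x 85 pixels.
#'
#' @param cube a [hyper_cube()].
#' @param out_rows,out_cols target spatial size in pixels.
#' @return resized [hyper_cube()].
#' @export
resize_cube <- function(cube, out_rows = 85L, out_cols = 85L) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (out_rows < 1L || out_cols < 1L) {
    stop("target dimensions must be positive")
  }
  img <- EBImage::resize(EBImage::Image(cube$values), w = out_rows,
                         h = out_cols, filter = "bilinear")
  d3 <- dim(cube$values)[3]
  hyper_cube(array(EBImage::imageData(img), c(out_rows, out_cols, d3)),
             cube$wavelengths)
}

#' Standard preprocessing of one phantom or cube
#'
#' Applies the fixed pipeline crop -> Savitzky-Golay smooth -> area
#' normalize (optionally the inverse order of the last two), segments the
#' fruit and extracts the masked mean spectrum; optionally also returns the
#' masked, spatially resized cube for 3-D models.
#'
#' @param cube a reflectance [hyper_cube()].
#' @param low,high crop window in nm.
#' @param window,polyorder Savitzky-Golay settings.
#' @param normalize_first apply area normalization before smoothing.
#' @param resize_to optional `c(rows, cols)`; when given, the background is
#'   zeroed and the cube resized for 3-D model input.
#' @return list with `spectrum`, `mask`, `cube` (the preprocessed cube) and
#'   `resized` (or `NULL`).
#' @export
preprocess_cube <- function(cube, low = 441, high = 947, window = 11L,
                            polyorder = 3L, normalize_first = FALSE,
                            resize_to = NULL) {
  x <- crop_bands(cube, low, high)
  x <- if (normalize_first) {
    sg_smooth(area_normalize(x), window, polyorder)
  } else {
    area_normalize(sg_smooth(x, window, polyorder))
  }
  mask <- segment_fruit(x)
  sp <- mean_spectrum(x, mask)
  resized <- NULL
  if (!is.null(resize_to)) {
    masked <- x$values * array(mask, dim(x$values))
    resized <- resize_cube(hyper_cube(masked, x$wavelengths),
                           resize_to[1], resize_to[2])
  }
  list(spectrum = sp, mask = mask, cube = x, resized = resized)
}

#' Write mean spectra as CSV
#'
#' @param spectra samples x bands matrix.
#' @param wavelengths band wavelengths (nm), used as column names.
#' @param ids sample identifiers.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, wavelengths, ids, path) {
  df <- data.frame(sample_id = ids, spectra, check.names = FALSE)
  colnames(df)[-1] <- sprintf("%.2f", wavelengths)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
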