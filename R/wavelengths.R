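#' Evenly spaced wavelength grid
#'
#' @param start,end grid endpoints in nm (`end > start`).
#' @param n_bands number of bands (at least 2).
#' @return strictly increasing numeric vector of length `n_bands` from
#'   `start` to `end`.
#' @examples
#' make_wavelength_grid(0, 10, 11)
#' @export
make_wavelength_grid <- function(start, end, n_bands) {
  n_bands <- as.integer(n_bands)
  if (is.na(n_bands) || n_bands < 2L) stop("n_bands must be at least 2")
  if (!(end > start)) stop("end must be greater than start")
  seq(start, end, length.out = n_bands)
}

#' Full-range grid with a prescribed number of bands in the analysis window
#'
#' Solves by brute force for the smallest evenly spaced grid over
#' `[start, end]` whose closed sub-interval `[low, high]` contains exactly
#' `n_crop` grid points.  The spectrometer's native band spacing is not a
#' published quantity, so the default full-range grid of the phantom
#' generator is derived this way: 380-1030 nm with 400 bands retained in
#' the 441-947 nm analysis window (which this search resolves to 515 full
#' bands, about 1.27 nm spacing).
#'
#' @param n_crop required number of bands inside `[low, high]`.
#' @param start,end full spectral range in nm.
#' @param low,high analysis window in nm.
#' @param max_bands search limit.
#' @return the wavelength grid (full range).
#' @export
grid_for_crop <- function(n_crop, start = 380, end = 1030,
                          low = 441, high = 947, max_bands = 4096L) {
  for (n in seq(as.integer(n_crop), as.integer(max_bands))) {
    w <- seq(start, end, length.out = n)
    if (sum(w >= low - 1e-9 & w <= high + 1e-9) == as.integer(n_crop)) {
      return(w)
    }
  }
  stop("no grid with ", n_crop, " bands in [", low, ", ", high,
       "] found up to ", max_bands, " bands")
}
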