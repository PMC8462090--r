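#' Endmember reflectance library for strawberry phantoms
#'
#' Smooth parametric reflectance curves for the three phantom materials:
#'
#' * `green`: unripe tissue, with a green reflectance bump near 550 nm, a
#'   chlorophyll absorption trough near 670 nm and the red-edge rise to a
#'   near-infrared plateau;
#' * `red`: ripe tissue, with the anthocyanin-driven reflectance rise above
#'   about 600 nm and the same near-infrared plateau;
#' * `background`: a dark, spectrally flat sample stage.
#'
#' The two tissue endmembers share the near-infrared term exactly, so their
#' differences are concentrated in the visible 441-700 nm pigment region and
#' are negligible above 750 nm.  The visible red plateau amplitude is
#' rescaled so that the two tissue curves have equal integrals over the
#' 441-947 nm analysis window; pixel-wise area normalization then removes
#' brightness without leaking ripeness information into the near-infrared
#' bands.
#'
#' @param wavelengths wavelength grid in nm.
#' @return an object of class `endmember_library`: a list with elements
#'   `green`, `red`, `background` (nonnegative reflectance vectors) and
#'   `wavelengths`.
#' @export
endmember_library <- function(wavelengths) {
  w <- as.numeric(wavelengths)
  gauss <- function(mu, sg) exp(-((w - mu)^2) / (2 * sg^2))
  nir <- 0.68 * stats::plogis((w - 710) / 22)
  green_vis <- 0.20 * gauss(550, 35) - 0.03 * gauss(670, 15)
  # anthocyanin plateau rolled off by 700 nm so tissue differences stay
  # confined to the 441-700 nm pigment window
  red_shape <- stats::plogis((w - 615) / 14) *
    (1 - stats::plogis((w - 690) / 8))
  # equal-area constraint on a fine internal grid over the analysis window
  wf <- seq(441, 947, by = 0.5)
  gaussf <- function(mu, sg) exp(-((wf - mu)^2) / (2 * sg^2))
  gvf <- 0.20 * gaussf(550, 35) - 0.03 * gaussf(670, 15)
  rsf <- stats::plogis((wf - 615) / 14) * (1 - stats::plogis((wf - 690) / 8))
  amp <- sum(gvf) / sum(rsf)
  out <- list(green = 0.06 + green_vis + nir,
              red = 0.06 + amp * red_shape + nir,
              background = rep(0.02, length(w)),
              red_vis_amplitude = amp,
              wavelengths = w)
  stopifnot(all(out$green > 0), all(out$red > 0))
  class(out) <- "endmember_library"
  out
}

# SSC-dependent near-infrared reflectance perturbation: a Gaussian bump
# centered in the 700-940 nm region whose amplitude is proportional to the
# deviation of SSC from a reference level.  With zero_sum = TRUE the bump
# is a difference of Gaussians (outer width 2.25x) balanced to integrate to
# zero over the 441-947 nm analysis window, so pixel-wise area
# normalization passes the perturbation through without redistributing it
# across unrelated bands.
ssc_bump <- function(wavelengths, ssc, amplitude = 0.004, center = 820,
                     width = 60, reference = 8, zero_sum = FALSE) {
  g <- exp(-((wavelengths - center)^2) / (2 * width^2))
  if (zero_sum) {
    go <- exp(-((wavelengths - center)^2) / (2 * (2.25 * width)^2))
    win <- wavelengths >= 441 & wavelengths <= 947
    g <- g - go * (sum(g[win]) / sum(go[win]))
  }
  amplitude * (ssc - reference) * g
}
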