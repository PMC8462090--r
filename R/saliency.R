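# Gradient saliency attribution.  The saliency of an input element is the
# absolute gradient of the model output with respect to that element of the
# network input (the per-band standardized spectra/cubes the network
# actually consumes).  For classification the gradient target is the
# pre-softmax logit of the true class (softmax saturation would null the
# gradients); for regression it is the scalar network output.

#' Input gradient of a fitted residual network
#'
#' Computes, per sample, the elementwise absolute gradient of the class
#' logit (classification) or of the scalar output (regression) with respect
#' to the network input.
#'
#' @param object a fitted [resnet()] model.
#' @param newdata inputs with the training shape contract.
#' @param target for classification, the target classes (typically the true
#'   labels); defaults to the predicted classes.  Ignored for regression.
#' @param model `"final"` (default) or `"best"` parameter snapshot.
#' @return for 1-D models a samples x bands matrix; for 3-D models a
#'   rows x cols x bands x samples array.  Values are nonnegative.
#' @export
input_gradient <- function(object, newdata, target = NULL,
                           model = c("final", "best")) {
  if (!inherits(object, "resnet") || is.null(object$net)) {
    stop("input_gradient requires a trained resnet model")
  }
  model <- match.arg(model)
  xt <- resnet_tensor(newdata)
  if (!identical(dim(xt)[1:3], as.integer(object$dims))) {
    stop("newdata shape does not match the model input contract")
  }
  xs <- resnet_standardize(xt, list(center = object$x_center,
                                    scale = object$x_scale))
  nn_set_state(object$net,
               if (model == "best") object$state_best else object$state_final)
  n <- dim(xs)[5]
  if (object$task == "classification") {
    if (is.null(target)) {
      target <- predict(object, newdata, type = "class", model = model)
    }
    ti <- match(as.character(target), object$classes)
    if (anyNA(ti)) stop("target labels outside the model's class set")
    if (length(ti) == 1L) ti <- rep(ti, n)
  }
  out <- nn_forward(object$net, xs, training = FALSE)
  dy <- matrix(0, nrow(out), ncol(out))
  if (object$task == "classification") {
    dy[cbind(ti, seq_len(n))] <- 1
  } else {
    dy[1, ] <- 1
  }
  g <- abs(nn_backward(object$net, dy))
  d <- dim(xs)
  if (object$input_kind == "spectrum") {
    t(matrix(g, d[3], d[5]))
  } else {
    array(g, c(d[1], d[2], d[3], d[5]))
  }
}

#' Correctly classified subset
#'
#' @param object a fitted classification [resnet()] (ignored when
#'   `predictions` is given).
#' @param x,y inputs and true labels.
#' @param predictions optional precomputed predicted labels.
#' @return integer indices of the samples whose predicted class equals the
#'   true label (empty, with a warning, if none).
#' @export
select_correct_classified <- function(object, x, y, predictions = NULL) {
  pred <- predictions %||% predict(object, x, type = "class")
  sel <- which(as.character(pred) == as.character(y))
  if (!length(sel)) warning("no sample was correctly classified")
  sel
}

#' "Correctly predicted" regression subset by prediction error rate
#'
#' The prediction error rate of a sample is
#' `|measured - predicted| / measured`.  Samples at or below the threshold
#' count as correctly predicted; samples with a non-positive measured value
#' are excluded with a warning.
#'
#' @param object a fitted regression [resnet()] (ignored when
#'   `predictions` is given).
#' @param x,y inputs and measured values.
#' @param threshold error-rate threshold in (0, 1); 0.05 and 0.10 are the
#'   conventional choices.
#' @param predictions optional precomputed predicted values.
#' @return integer indices of the retained samples.
#' @export
select_correct_regression <- function(object, x, y, threshold = 0.10,
                                      predictions = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  pred <- predictions %||% predict(object, x, type = "response")
  ok <- y > 0
  if (!all(ok)) {
    warning(sum(!ok), " samples with non-positive measured values excluded")
  }
  which(ok & abs(y - pred) / y <= threshold)
}

#' Per-wavelength saliency contributions
#'
#' Accumulates absolute gradients over the selected samples (and, for 3-D
#' gradients, over the spatial pixels) per wavelength, then normalizes so
#' the contributions sum to one.
#'
#' @param grads gradients from [input_gradient()]: a samples x bands matrix
#'   or a rows x cols x bands x samples array.
#' @param wavelengths wavelength vector (nm) matching the band dimension.
#' @return an object of class `saliency_profile` with fields `wavelengths`,
#'   `contributions` (nonnegative, summing to 1) and `n_samples`.
#' @export
wavelength_contributions <- function(grads, wavelengths) {
  if (is.matrix(grads)) {
    if (nrow(grads) < 1L) stop("no samples selected")
    contrib <- colSums(abs(grads))
  } else if (is.array(grads) && length(dim(grads)) == 4L) {
    d <- dim(grads)
    if (d[4] < 1L) stop("no samples selected")
    contrib <- colSums(matrix(aperm(abs(grads), c(1, 2, 4, 3)), ncol = d[3]))
  } else {
    stop("grads must be a matrix or a 4-D array")
  }
  if (length(contrib) != length(wavelengths)) {
    stop("gradient band dimension does not match wavelengths")
  }
  total <- sum(contrib)
  if (total <= 0) stop("all gradients are zero; no profile defined")
  structure(list(wavelengths = as.numeric(wavelengths),
                 contributions = contrib / total,
                 n_samples = if (is.matrix(grads)) nrow(grads) else
                   dim(grads)[4]),
            class = "saliency_profile")
}

#' @export
print.saliency_profile <- function(x, ...) {
  top <- order(-x$contributions)[1:5]
  cat(sprintf("saliency profile over %d wavelengths (%d samples)\n",
              length(x$wavelengths), x$n_samples))
  cat("top wavelengths (nm):",
      paste(sprintf("%.0f", x$wavelengths[top]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.saliency_profile <- function(x, ...) {
  plot(x$wavelengths, x$contributions, type = "h",
       xlab = "wavelength (nm)", ylab = "contribution", ...)
  invisible(x)
}

#' Saliency profile of a model on a labelled set
#'
#' High-level wrapper: selects the correctly handled samples (correct
#' classifications, or regression predictions within the error-rate
#' threshold), computes their input gradients against the true targets and
#' accumulates them into a wavelength contribution profile.
#'
#' @param object a fitted [resnet()].
#' @param x,y evaluation inputs and true targets (typically the testing
#'   set).
#' @param error_rate regression error-rate threshold (ignored for
#'   classification).
#' @param by_class for classification, additionally return one profile per
#'   maturity class.
#' @param wavelengths wavelength vector; defaults to the one stored in the
#'   model.
#' @return a `saliency_profile`, or (with `by_class`) a list with `pooled`
#'   and `per_class`.
#' @export
saliency_profile <- function(object, x, y, error_rate = 0.10,
                             by_class = FALSE, wavelengths = NULL) {
  wavelengths <- wavelengths %||% object$wavelengths
  if (is.null(wavelengths)) {
    stop("no wavelengths stored in the model; pass them explicitly")
  }
  sel <- if (object$task == "classification") {
    select_correct_classified(object, x, y)
  } else {
    select_correct_regression(object, x, y, error_rate)
  }
  if (!length(sel)) stop("no correctly predicted samples to attribute")
  xsel <- if (is.matrix(x)) x[sel, , drop = FALSE] else
    x[, , , sel, drop = FALSE]
  target <- if (object$task == "classification") y[sel] else NULL
  g <- input_gradient(object, xsel, target = target)
  pooled <- wavelength_contributions(g, wavelengths)
  if (!by_class || object$task != "classification") return(pooled)
  per_class <- lapply(object$classes, function(cl) {
    ii <- which(as.character(y[sel]) == cl)
    if (!length(ii)) return(NULL)
    gg <- if (is.matrix(g)) g[ii, , drop = FALSE] else
      g[, , , ii, drop = FALSE]
    wavelength_contributions(gg, wavelengths)
  })
  names(per_class) <- object$classes
  list(pooled = pooled, per_class = per_class)
}

#' Per-pixel saliency map of a 3-D model
#'
#' Absolute input gradient summed over the spectral axis, per pixel.
#'
#' @param object a fitted 3-D [resnet()].
#' @param cube one sample: a rows x cols x bands array (or such an array
#'   with a trailing singleton sample dimension).
#' @param target optional class target (defaults to the predicted class).
#' @return an object of class `pixel_saliency_map`: a nonnegative
#'   rows x cols matrix with a `plot` method.
#' @export
pixel_saliency <- function(object, cube, target = NULL) {
  if (object$input_kind != "cube") {
    stop("pixel saliency requires a 3-D (cube) model")
  }
  if (length(dim(cube)) == 3L) dim(cube) <- c(dim(cube), 1L)
  g <- input_gradient(object, cube, target = target)
  m <- apply(g[, , , 1, drop = FALSE], c(1, 2), sum)
  structure(m, class = c("pixel_saliency_map", "matrix"))
}

#' @export
plot.pixel_saliency_map <- function(x, ...) {
  m <- unclass(x)[,]
  graphics::image(t(m)[, nrow(m):1], col = grDevices::hcl.colors(64),
                  axes = FALSE, main = "pixel saliency", ...)
  invisible(x)
}

#' Write a saliency profile as CSV
#'
#' @param profile a `saliency_profile`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(wavelength_nm = profile$wavelengths,
                              contribution = profile$contributions),
                   path, row.names = FALSE)
  invisible(path)
}

#' Jaccard index of two band sets
#'
#' @param a,b integer index vectors.
#' @return `|intersection| / |union|`.
#' @export
band_set_jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Top-decile bands of a profile
#'
#' @param values nonnegative per-band scores (e.g. saliency contributions).
#' @return indices of the top 10% of bands (at least one).
#' @export
top_decile_bands <- function(values) {
  k <- max(1L, ceiling(length(values) / 10))
  order(-values)[seq_len(k)]
}
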