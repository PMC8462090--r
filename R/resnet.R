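#' Configuration for a residual network
#'
#' Collects the architecture and optimization settings of the bottleneck
#' residual networks used for maturity classification and SSC regression.
#' Task-dependent defaults follow the training recipe the models were
#' designed for: classification uses softmax cross-entropy, 1,000 epochs and
#' a learning rate of 0.01; regression uses an L2 loss, 1,500 epochs and a
#' learning rate of 0.0001.  Both are optimized by Adam, and the dense head
#' is preceded by dropout with probability 0.3.
#'
#' @param task `"classification"` (four maturity classes) or `"regression"`
#'   (a single SSC output in degrees Brix).
#' @param input_kind `"spectrum"` for 1-D mean spectra, `"cube"` for 3-D
#'   hyperspectral images.
#' @param n_bands number of spectral bands of the input.
#' @param spatial_dims integer vector of length 2, the spatial size of cube
#'   inputs (ignored for spectra).
#' @param n_classes number of classes for classification.
#' @param stem_kernel,stem_stride,stem_channels the stem convolution: a
#'   large kernel and stride close to the input enlarge the receptive field
#'   so that global features are captured first.
#' @param stage_widths output channels of each bottleneck stage; every stage
#'   after the first halves the resolution.
#' @param blocks_per_stage bottleneck blocks per stage.
#' @param bottleneck_compression channel compression factor inside a
#'   bottleneck block.
#' @param block_kernel kernel size of the middle bottleneck convolution.
#' @param dropout dropout probability before the dense head.
#' @param epochs,learning_rate,batch_size optimization settings; `NULL`
#'   selects the task default given above.
#' @param standardize_input apply per-band z-scoring using training-set
#'   statistics before the network (dataset-level normalization, in
#'   addition to the batch-normalization layers).
#' @param standardize_response for regression, internally center/scale the
#'   response during optimization (predictions are returned in Brix).
#' @param val_every evaluate the validation set every this many epochs.
#' @param seed integer seed controlling initialization and batch shuffling.
#'
#' @return an object of class `resnet_config`.
#' @export
resnet_config <- function(task = c("classification", "regression"),
                          input_kind = c("spectrum", "cube"),
                          n_bands = 400,
                          spatial_dims = c(85L, 85L),
                          n_classes = 4L,
                          stem_kernel = 7L,
                          stem_stride = 2L,
                          stem_channels = 16L,
                          stage_widths = c(16L, 32L, 64L),
                          blocks_per_stage = 1L,
                          bottleneck_compression = 4L,
                          block_kernel = 3L,
                          dropout = 0.3,
                          epochs = NULL,
                          learning_rate = NULL,
                          batch_size = 32L,
                          standardize_input = TRUE,
                          standardize_response = TRUE,
                          val_every = 1L,
                          seed = 1L) {
  task <- match.arg(task)
  input_kind <- match.arg(input_kind)
  if (is.null(epochs)) epochs <- if (task == "classification") 1000L else 1500L
  if (is.null(learning_rate)) {
    learning_rate <- if (task == "classification") 0.01 else 1e-4
  }
  loss <- if (task == "classification") "softmax_cross_entropy" else "l2"
  cfg <- list(task = task, input_kind = input_kind,
              n_bands = as.integer(n_bands),
              spatial_dims = as.integer(spatial_dims),
              n_classes = as.integer(n_classes),
              stem_kernel = as.integer(stem_kernel),
              stem_stride = as.integer(stem_stride),
              stem_channels = as.integer(stem_channels),
              stage_widths = as.integer(stage_widths),
              blocks_per_stage = as.integer(blocks_per_stage),
              bottleneck_compression = as.integer(bottleneck_compression),
              block_kernel = as.integer(block_kernel),
              dropout = dropout, loss = loss,
              epochs = as.integer(epochs), learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              standardize_input = isTRUE(standardize_input),
              standardize_response = isTRUE(standardize_response),
              val_every = as.integer(val_every),
              seed = as.integer(seed))
  class(cfg) <- "resnet_config"
  cfg
}

resnet_head_size <- function(config) {
  if (config$task == "classification") config$n_classes else 1L
}

# Output length of one dimension after a strided convolution
conv_out_len <- function(d, k, s, p) (d + 2L * p - k) %/% s + 1L

# Shared trunk constructor.  `ndim` is 1 for spectra, 3 for cubes.
build_resnet_trunk <- function(config, ndim) {
  w <- config$stage_widths
  mid <- w %/% config$bottleneck_compression
  if (any(mid < 1L)) stop("stage widths too small for the compression factor")
  sk <- config$stem_kernel
  ss <- config$stem_stride
  if (ndim == 1) {
    stem_k <- c(1L, 1L, sk)
    stem_s <- c(1L, 1L, ss)
    dims <- c(1L, 1L, config$n_bands)
  } else {
    stem_k <- rep(sk, 3L)
    stem_s <- rep(ss, 3L)
    dims <- c(config$spatial_dims, config$n_bands)
  }
  # track the resolution through the stride plan
  dims <- mapply(conv_out_len, dims, stem_k, stem_s, (stem_k - 1L) %/% 2L)
  layers <- list(nn_conv(1L, config$stem_channels, stem_k, stride = stem_s),
                 nn_bnrelu(config$stem_channels))
  in_ch <- config$stem_channels
  for (i in seq_along(w)) {
    for (bl in seq_len(config$blocks_per_stage)) {
      stride <- if (i > 1L && bl == 1L) 2L else 1L
      if (stride > 1L) {
        st <- if (ndim == 1) c(1L, 1L, stride) else rep(stride, 3L)
        bk <- if (ndim == 1) c(1L, 1L, config$block_kernel) else
          rep(config$block_kernel, 3L)
        dims <- mapply(conv_out_len, dims, bk, st, (bk - 1L) %/% 2L)
      }
      if (any(dims < 1L))
        stop("input too small for the stride plan of this architecture")
      layers <- c(layers, list(
        nn_bottleneck(in_ch, w[i], mid[i], stride, ndim,
                      config$block_kernel)))
      in_ch <- w[i]
    }
  }
  layers <- c(layers, list(nn_bnrelu(in_ch), nn_gap(),
                           nn_dropout(config$dropout),
                           nn_dense(in_ch, resnet_head_size(config))))
  layers
}

#' Build an untrained 1-D residual network
#'
#' Constructs the bottleneck residual network for 1-D spectra: a stem
#' convolution with a large kernel and stride along the spectral axis,
#' pre-activation bottleneck stages, global average pooling, dropout and a
#' dense head whose size depends on the task.  Classification and regression
#' variants share an identical trunk and differ only in the head and loss.
#'
#' @param config a [resnet_config()] with `input_kind = "spectrum"`.
#' @return an internal network object (used by [resnet()]).
#' @export
build_resnet_1d <- function(config) {
  if (config$n_bands < 32L)
    stop("at least 32 spectral bands are required for the 1-D architecture")
  nn_network(build_resnet_trunk(config, ndim = 1L))
}

#' Build an untrained 3-D residual network
#'
#' Same structural pattern as [build_resnet_1d()] with 3-D convolutions over
#' (rows, cols, bands).  The reference input contract is an 85 x 85 x 400
#' resized cube; smaller cubes (down to 16 x 16 spatial, 32 bands) are
#' accepted for desk-scale work.
#'
#' @param config a [resnet_config()] with `input_kind = "cube"`.
#' @return an internal network object (used by [resnet()]).
#' @export
build_resnet_3d <- function(config) {
  if (config$n_bands < 32L)
    stop("at least 32 spectral bands are required for the 3-D architecture")
  if (any(config$spatial_dims < 16L))
    stop("spatial dimensions must be at least 16 pixels")
  nn_network(build_resnet_trunk(config, ndim = 3L))
}

# Convert user-facing inputs (spectra matrix or cube array) to the internal
# 5-D tensor (d1, d2, d3, C = 1, N).
resnet_tensor <- function(x) {
  if (is.matrix(x)) {
    array(t(x), dim = c(1L, 1L, ncol(x), 1L, nrow(x)))
  } else if (is.array(x) && length(dim(x)) == 4L) {
    d <- dim(x)
    array(x, dim = c(d[1], d[2], d[3], 1L, d[4]))
  } else {
    stop("x must be a samples x bands matrix or a rows x cols x bands x ",
         "samples array")
  }
}

resnet_n_samples <- function(x) {
  if (is.matrix(x)) nrow(x) else dim(x)[4]
}

# Per-band standardization statistics (bands live on the third tensor axis)
resnet_band_stats <- function(xt) {
  d <- dim(xt)
  M <- matrix(aperm(xt, c(1, 2, 4, 5, 3)), ncol = d[3])
  mu <- colMeans(M)
  sdev <- sqrt(pmax(colMeans(M^2) - mu^2, 0))
  sdev[sdev < 1e-12] <- 1
  list(center = mu, scale = sdev)
}

resnet_standardize <- function(xt, stats) {
  d <- dim(xt)
  per_band <- prod(d[1:2])
  ctr <- rep(rep(stats$center, each = per_band), times = d[4] * d[5])
  scl <- rep(rep(stats$scale, each = per_band), times = d[4] * d[5])
  array((as.numeric(xt) - ctr) / scl, dim = d)
}

#' Fit a bottleneck residual network
#'
#' The central model fitter: trains a 1-D (spectra) or 3-D (cube) bottleneck
#' residual convolutional network for maturity classification or SSC
#' regression with the Adam optimizer and manual backpropagation.  Inputs
#' are z-scored per band with training-set statistics before entering the
#' network; for regression the response is internally centered and scaled
#' (predictions are always returned on the original Brix scale).  The
#' parameter snapshot with the best validation metric is retained alongside
#' the final state and used for prediction by default.
#'
#' @param x training inputs: a samples x bands matrix of preprocessed mean
#'   spectra, or a rows x cols x bands x samples array of preprocessed
#'   cubes.
#' @param y training targets: maturity labels (factor or integers 0-3) for
#'   classification, numeric SSC values for regression.
#' @param task,config see [resnet_config()]; `config` overrides `task`.
#' @param validation optional `list(x =, y =)` monitored each epoch.
#' @param wavelengths optional wavelength vector (nm) carried along for
#'   saliency profiles.
#' @param verbose print progress every 50 epochs.
#'
#' @return an object of class `resnet` with `print`, `summary`, `predict`,
#'   `plot`, `coef`, `fitted` and `residuals` methods.
#' @seealso [predict.resnet()], [input_gradient()], [saliency_profile()]
#' @export
resnet <- function(x, y, task = c("classification", "regression"),
                   config = NULL, validation = NULL, wavelengths = NULL,
                   verbose = FALSE) {
  task <- match.arg(task)
  input_kind <- if (is.matrix(x)) "spectrum" else "cube"
  if (is.null(config)) {
    config <- resnet_config(task = task, input_kind = input_kind)
  }
  task <- config$task
  xt <- resnet_tensor(x)
  d <- dim(xt)
  config$n_bands <- d[3]
  if (input_kind == "cube") config$spatial_dims <- d[1:2]
  config$input_kind <- input_kind
  n <- d[5]
  if (n < 1L) stop("empty training set")

  if (task == "classification") {
    if (is.factor(y)) {
      classes <- levels(y)
      yi <- as.integer(y)
    } else {
      classes <- as.character(sort(unique(y)))
      yi <- match(as.character(y), classes)
    }
    if (length(classes) != config$n_classes) {
      config$n_classes <- length(classes)
    }
    if (anyNA(yi)) stop("labels do not match the class set")
  } else {
    if (!is.numeric(y)) stop("regression targets must be numeric")
    classes <- NULL
    yi <- y
  }
  if (length(yi) != n) stop("x and y disagree on the number of samples")

  set.seed(config$seed)
  net <- if (input_kind == "spectrum") build_resnet_1d(config) else
    build_resnet_3d(config)

  xstats <- if (config$standardize_input) resnet_band_stats(xt) else
    list(center = rep(0, d[3]), scale = rep(1, d[3]))
  xs <- resnet_standardize(xt, xstats)

  ystats <- list(center = 0, scale = 1)
  ys <- yi
  if (task == "regression" && config$standardize_response) {
    ystats <- list(center = mean(yi), scale = max(stats::sd(yi), 1e-12))
    ys <- (yi - ystats$center) / ystats$scale
  }

  has_val <- !is.null(validation)
  if (has_val) {
    vxt <- resnet_standardize(resnet_tensor(validation$x), xstats)
    vy <- validation$y
    vyi <- if (task == "classification") {
      if (is.factor(vy)) as.integer(vy) else match(as.character(vy), classes)
    } else vy
  }

  bs <- min(config$batch_size, n)
  log <- vector("list", config$epochs)
  best_metric <- if (task == "classification") -Inf else Inf
  best_state <- NULL
  best_epoch <- NA_integer_

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      db <- dim(xs)
      xb <- nn_buf(net, "batch", prod(db[1:4]) * length(idx),
                   c(db[1:4], length(idx)))
      gather_samples(xs, db, as.integer(idx), xb)
      out <- nn_forward(net, xb, training = TRUE)
      ls <- if (task == "classification") {
        nn_loss_softmax_ce(out, ys[idx])
      } else {
        nn_loss_l2(out, ys[idx])
      }
      if (!is.finite(ls$loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      nn_backward(net, ls$grad, need_input_grad = FALSE)
      nn_adam_step(net, config$learning_rate)
      ep_loss <- ep_loss + ls$loss
      nb <- nb + 1L
    }
    row <- list(epoch = epoch, train_loss = ep_loss / nb,
                val_loss = NA_real_, val_metric = NA_real_)
    if (has_val && (epoch %% config$val_every == 0L ||
                    epoch == config$epochs)) {
      vout <- nn_predict_raw(net, vxt, bs)
      if (task == "classification") {
        vl <- nn_loss_softmax_ce(vout, vyi)
        metric <- mean(max.col(t(vout)) == vyi)
        improved <- metric > best_metric
      } else {
        vl <- nn_loss_l2(vout, (vyi - ystats$center) / ystats$scale)
        metric <- sqrt(mean((as.numeric(vout) * ystats$scale +
                               ystats$center - vyi)^2))
        improved <- metric < best_metric
      }
      row$val_loss <- vl$loss
      row$val_metric <- metric
      if (improved) {
        best_metric <- metric
        best_state <- nn_get_state(net)
        best_epoch <- epoch
      }
    }
    log[[epoch]] <- row
    if (verbose && (epoch %% 50L == 0L || epoch == 1L)) {
      message(sprintf("epoch %d  loss %.5f  val %.4f", epoch,
                      row$train_loss, row$val_metric))
    }
  }

  log <- do.call(rbind, lapply(log, as.data.frame))
  final_state <- nn_get_state(net)
  if (is.null(best_state)) {
    best_state <- final_state
    best_epoch <- config$epochs
  }

  obj <- structure(list(net = net, config = config, task = task,
                        input_kind = input_kind, dims = d[1:3],
                        x_center = xstats$center, x_scale = xstats$scale,
                        y_center = ystats$center, y_scale = ystats$scale,
                        classes = classes, log = log,
                        state_final = final_state, state_best = best_state,
                        best_epoch = best_epoch,
                        n_params = nn_n_params(net),
                        wavelengths = wavelengths, call = match.call()),
                   class = "resnet")
  # fitted values on the training set (final state, eval mode)
  fit_raw <- nn_predict_raw(net, xs, bs)
  if (task == "classification") {
    obj$fitted_prob <- t(nn_softmax(fit_raw))
    colnames(obj$fitted_prob) <- classes
    obj$fitted <- classes[max.col(t(fit_raw))]
  } else {
    obj$fitted <- as.numeric(fit_raw) * ystats$scale + ystats$center
  }
  obj$y <- if (task == "classification") classes[yi] else yi
  obj
}

# Chunked eval-mode forward pass over the sample axis
nn_predict_raw <- function(net, xs, chunk = 64L) {
  d <- dim(xs)
  n <- d[5]
  out <- NULL
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    xb <- nn_buf(net, "batch", prod(d[1:4]) * length(idx),
                 c(d[1:4], length(idx)))
    gather_samples(xs, d, as.integer(idx), xb)
    o <- nn_forward(net, xb, training = FALSE)
    out <- if (is.null(out)) o else cbind(out, o)
  }
  out
}

#' Predict from a fitted residual network
#'
#' @param object a fitted [resnet()] model.
#' @param newdata inputs with the same shape contract as the training data.
#' @param type `"class"` (predicted labels), `"prob"` (class probabilities)
#'   or `"response"` (numeric predictions; the only choice for regression).
#'   Defaults to `"class"` for classification and `"response"` for
#'   regression.
#' @param model use the `"final"` epoch (the default: training runs a fixed
#'   number of epochs) or the `"best"` validation snapshot.
#' @param ... unused.
#' @return a vector of labels, a samples x classes probability matrix, or a
#'   numeric vector of SSC predictions in Brix.
#' @export
predict.resnet <- function(object, newdata,
                           type = c("class", "prob", "response"),
                           model = c("final", "best"), ...) {
  if (missing(type) && object$task == "regression") type <- "response"
  type <- match.arg(type)
  model <- match.arg(model)
  xt <- resnet_tensor(newdata)
  if (!identical(dim(xt)[1:3], as.integer(object$dims))) {
    stop("newdata shape does not match the model input contract (",
         paste(object$dims, collapse = " x "), ")")
  }
  xs <- resnet_standardize(xt, list(center = object$x_center,
                                    scale = object$x_scale))
  nn_set_state(object$net,
               if (model == "best") object$state_best else object$state_final)
  out <- nn_predict_raw(object$net, xs, object$config$batch_size)
  if (object$task == "classification") {
    if (type == "prob" || type == "response") {
      p <- t(nn_softmax(out))
      colnames(p) <- object$classes
      return(p)
    }
    return(object$classes[max.col(t(out))])
  }
  if (type == "class") stop("type = 'class' is only for classification")
  as.numeric(out) * object$y_scale + object$y_center
}

#' @export
print.resnet <- function(x, ...) {
  cat(sprintf("Bottleneck residual network (%s, %s input)\n",
              x$task, x$input_kind))
  cat(sprintf("  input: %s, %d trainable parameters\n",
              paste(x$dims[x$dims > 1L | x$input_kind == "cube"],
                    collapse = " x "), x$n_params))
  cat(sprintf("  trained %d epochs (lr %g, batch %d, loss %s), best epoch %s\n",
              x$config$epochs, x$config$learning_rate, x$config$batch_size,
              x$config$loss, x$best_epoch))
  invisible(x)
}

#' @export
summary.resnet <- function(object, ...) {
  print(object)
  cat("\nStage widths:", paste(object$config$stage_widths, collapse = ", "),
      " (compression", object$config$bottleneck_compression,
      ", dropout", object$config$dropout, ")\n")
  tl <- object$log[nrow(object$log), ]
  cat(sprintf("Final training loss %.5f", tl$train_loss))
  if (!is.na(tl$val_metric)) {
    lab <- if (object$task == "classification") "accuracy" else "RMSE"
    cat(sprintf(", validation %s %.4f", lab, tl$val_metric))
  }
  cat("\n")
  if (object$task == "classification") {
    cat("Training confusion matrix:\n")
    print(table(truth = object$y, predicted = object$fitted))
  }
  invisible(object)
}

#' @export
coef.resnet <- function(object, ...) {
  st <- object$state_final
  names(st) <- vapply(object$net$flat, function(l) l$type, "")
  lapply(st, function(s) s[intersect(names(s), c("W", "b", "gamma", "beta"))])
}

#' @export
fitted.resnet <- function(object, ...) object$fitted

#' @export
residuals.resnet <- function(object, ...) {
  if (object$task != "regression") {
    stop("residuals are defined for regression models only")
  }
  object$y - object$fitted
}

#' @export
plot.resnet <- function(x, ...) {
  lg <- x$log
  plot(lg$epoch, lg$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = sprintf("%s training curve", x$task), ...)
  if (any(!is.na(lg$val_loss))) {
    ok <- !is.na(lg$val_loss)
    lines(lg$epoch[ok], lg$val_loss[ok], lty = 2)
    legend("topright", legend = c("train", "validation"), lty = c(1, 2),
           bty = "n")
  }
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param object a fitted [resnet()] model or an untrained network from the
#'   builders.
#' @return integer parameter count.
#' @export
n_parameters <- function(object) {
  if (inherits(object, "resnet")) return(object$n_params)
  nn_n_params(object)
}
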