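# Orchestration of the two experiments: maturity classification (1-D and
# 3-D models over repeated stratified splits) and SSC regression (outlier
# screening, SPXY partitioning, 1-D model, error-rate saliency).

#' Experiment configuration
#'
#' All knobs of the end-to-end experiments, serializable to YAML.  Defaults
#' reproduce the reference study conditions (204 fruits per maturity
#' degree, 400 analysis bands, cubes resized to 85 x 85 for the 3-D model,
#' 36 fruits per degree with measured SSC); desk-scale runs override
#' `n_per_class`, `n_crop_bands`, `image_size`, `resize_to` and the epoch
#' counts.
#'
#' @param n_per_class phantoms per maturity degree (classification).
#' @param image_size native phantom size `c(rows, cols)` in pixels.
#' @param n_crop_bands bands retained by the 441-947 nm crop.
#' @param noise_sd generator noise level (reflectance units).
#' @param ssc_amplitude SSC-bump amplitude of the generator.
#' @param crop_low,crop_high analysis window (nm).
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param resize_to 3-D model spatial input size `c(rows, cols)`.
#' @param n_val_per_class,n_test_per_class held-out samples per class.
#' @param n_repeats repeated random samplings.
#' @param models model families to train: subset of `c("1d", "3d")`.
#' @param epochs_1d,epochs_3d,batch_size,val_every_3d training settings for
#'   classification models (learning rates follow the task defaults of
#'   [resnet_config()]).
#' @param reg_n_per_class fruits per degree with measured SSC.
#' @param outlier_k,pls_ncomp PLS outlier-screen settings.
#' @param epochs_reg regression training epochs.
#' @param error_rates prediction-error-rate thresholds for regression
#'   saliency.
#' @param seed master seed; every random stage derives its seed from it.
#' @param output_dir optional directory for CSV/PNG/YAML artifacts.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_per_class = 204L,
                              image_size = c(64L, 64L),
                              n_crop_bands = 400L,
                              noise_sd = 0.01,
                              ssc_amplitude = 0.004,
                              crop_low = 441, crop_high = 947,
                              sg_window = 11L, sg_polyorder = 3L,
                              resize_to = c(85L, 85L),
                              n_val_per_class = 34L,
                              n_test_per_class = 34L,
                              n_repeats = 5L,
                              models = c("1d", "3d"),
                              epochs_1d = 1000L, epochs_3d = 1000L,
                              batch_size = 32L, val_every_3d = 5L,
                              reg_n_per_class = 36L,
                              outlier_k = 3, pls_ncomp = 8L,
                              epochs_reg = 1500L,
                              error_rates = c(0.05, 0.10),
                              seed = 1L, output_dir = NULL) {
  cfg <- list(n_per_class = as.integer(n_per_class),
              image_size = as.integer(image_size),
              n_crop_bands = as.integer(n_crop_bands),
              noise_sd = noise_sd, ssc_amplitude = ssc_amplitude,
              crop_low = crop_low, crop_high = crop_high,
              sg_window = as.integer(sg_window),
              sg_polyorder = as.integer(sg_polyorder),
              resize_to = as.integer(resize_to),
              n_val_per_class = as.integer(n_val_per_class),
              n_test_per_class = as.integer(n_test_per_class),
              n_repeats = as.integer(n_repeats),
              models = models,
              epochs_1d = as.integer(epochs_1d),
              epochs_3d = as.integer(epochs_3d),
              batch_size = as.integer(batch_size),
              val_every_3d = as.integer(val_every_3d),
              reg_n_per_class = as.integer(reg_n_per_class),
              outlier_k = outlier_k, pls_ncomp = as.integer(pls_ncomp),
              epochs_reg = as.integer(epochs_reg),
              error_rates = error_rates,
              seed = as.integer(seed), output_dir = output_dir)
  class(cfg) <- "experiment_config"
  cfg
}

#' Write / read an experiment configuration as YAML
#'
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path`; `read_config` the configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(experiment_config, cfg[setdiff(names(cfg), character(0))])
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_config(config, f)
  unname(tools::md5sum(f))
}

exp_log <- function(state, stage, msg) {
  line <- sprintf("[%s] stage=%s %s", format(Sys.time(), "%H:%M:%S"),
                  stage, msg)
  message(line)
  c(state, line)
}

# Derive per-stage seeds from the master seed
derive_seeds <- function(master, n) {
  set.seed(master)
  sample.int(2147483646L, n)
}

# Simulate and preprocess a classification dataset; returns spectra matrix,
# optional cube tensor, labels and manifest
prepare_classification_data <- function(config, data_seed, want_cubes) {
  pc <- phantom_config(image_height = config$image_size[1],
                       image_width = config$image_size[2],
                       n_crop_bands = config$n_crop_bands,
                       noise_sd = config$noise_sd,
                       ssc_amplitude = config$ssc_amplitude)
  ds <- simulate_dataset(config$n_per_class, pc, master_seed = data_seed)
  prep <- lapply(ds$phantoms, function(ph) {
    preprocess_cube(ph$cube, config$crop_low, config$crop_high,
                    config$sg_window, config$sg_polyorder,
                    resize_to = if (want_cubes) config$resize_to)
  })
  X1 <- t(vapply(prep, function(p) p$spectrum$values,
                 numeric(length(prep[[1]]$spectrum$values))))
  wl <- prep[[1]]$spectrum$wavelengths
  X3 <- NULL
  if (want_cubes) {
    B <- length(wl)
    X3 <- array(0, c(config$resize_to, B, length(prep)))
    for (i in seq_along(prep)) X3[, , , i] <- prep[[i]]$resized$values
  }
  list(X1 = X1, X3 = X3, wavelengths = wl,
       labels = factor(ds$manifest$label, levels = 0:3),
       manifest = ds$manifest)
}

#' Run the maturity-classification experiment
#'
#' End to end: simulate phantoms, preprocess, split into
#' train/validation/test per class (repeated `n_repeats` times), train the
#' 1-D (mean spectra) and 3-D (resized cubes) residual networks, and
#' collect confusion matrices, accuracies, the across-repeat ANOVA and
#' gradient saliency profiles (plus pixel maps for the 3-D model).
#'
#' @param config an [experiment_config()].
#' @return an object of class `classification_experiment` with fields
#'   `metrics` (repeat x model x set accuracies), `confusion`, `anova`,
#'   `saliency`, `models` (fits of the first repeat), `splits`, `manifest`,
#'   `wavelengths`, `config`, `config_hash`, `log`.
#' @export
run_classification_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  hash <- config_hash(config)
  lg <- exp_log(character(0), "init", paste("config", hash))
  seeds <- derive_seeds(config$seed, 2L + 3L * config$n_repeats)
  data_seed <- seeds[1]
  want_3d <- "3d" %in% config$models

  lg <- exp_log(lg, "simulate", sprintf("%d phantoms per class, seed %d",
                                        config$n_per_class, data_seed))
  dat <- prepare_classification_data(config, data_seed, want_3d)
  labels <- dat$labels
  lg <- exp_log(lg, "preprocess",
                sprintf("%d samples, %d bands", length(labels),
                        length(dat$wavelengths)))

  metrics <- NULL
  confusion <- list()
  splits <- list()
  models_first <- list()
  for (r in seq_len(config$n_repeats)) {
    sp <- class_stratified_split(labels, config$n_val_per_class,
                                 config$n_test_per_class,
                                 seed = seeds[2L + r], repeat_id = r)
    splits[[r]] <- sp
    for (mdl in config$models) {
      mseed <- seeds[2L + config$n_repeats +
                       (if (mdl == "1d") 0L else config$n_repeats) + r]
      epochs <- if (mdl == "1d") config$epochs_1d else config$epochs_3d
      cfg <- resnet_config(task = "classification",
                           input_kind = if (mdl == "1d") "spectrum" else
                             "cube",
                           epochs = epochs,
                           batch_size = config$batch_size,
                           val_every = if (mdl == "1d") 1L else
                             config$val_every_3d,
                           seed = mseed)
      xall <- if (mdl == "1d") dat$X1 else dat$X3
      take <- function(idx) if (mdl == "1d") {
        xall[idx, , drop = FALSE]
      } else {
        xall[, , , idx, drop = FALSE]
      }
      lg <- exp_log(lg, "train", sprintf("repeat %d model %s (%d epochs)",
                                         r, mdl, epochs))
      fit <- resnet(take(sp$train), labels[sp$train], config = cfg,
                    validation = list(x = take(sp$validation),
                                      y = labels[sp$validation]),
                    wavelengths = dat$wavelengths)
      for (set in c("train", "validation", "test")) {
        idx <- switch(set, train = sp$train, validation = sp$validation,
                      test = sp$test)
        pred <- predict(fit, take(idx), type = "class")
        cm <- confusion_matrix(labels[idx], pred, classes = 0:3, set = set)
        confusion[[paste(mdl, "r", r, set, sep = "_")]] <- cm
        metrics <- rbind(metrics,
                         data.frame(repeat_id = r, model = mdl, set = set,
                                    accuracy = overall_accuracy(cm)))
      }
      if (r == 1L) models_first[[mdl]] <- fit
    }
  }

  anova <- NULL
  if (config$n_repeats >= 2L && length(config$models) >= 2L) {
    anova <- anova_across_repeats(metrics, mode = "pooled")
    lg <- exp_log(lg, "anova", sprintf("F = %.3f, p = %.4f", anova$f,
                                       anova$p_value))
  }

  sp1 <- splits[[1]]
  saliency <- list()
  for (mdl in names(models_first)) {
    xall <- if (mdl == "1d") dat$X1 else dat$X3
    xte <- if (mdl == "1d") xall[sp1$test, , drop = FALSE] else
      xall[, , , sp1$test, drop = FALSE]
    saliency[[mdl]] <- saliency_profile(models_first[[mdl]], xte,
                                        labels[sp1$test], by_class = TRUE)
  }
  pixel_maps <- NULL
  if (want_3d) {
    pick <- sp1$test[1:min(2L, length(sp1$test))]
    pixel_maps <- lapply(pick, function(i) {
      pixel_saliency(models_first[["3d"]], dat$X3[, , , i],
                     target = labels[i])
    })
    names(pixel_maps) <- dat$manifest$sample_id[pick]
  }
  lg <- exp_log(lg, "saliency", "profiles computed on the testing set")

  out <- structure(list(metrics = metrics, confusion = confusion,
                        anova = anova, saliency = saliency,
                        pixel_maps = pixel_maps, models = models_first,
                        splits = splits, manifest = dat$manifest,
                        wavelengths = dat$wavelengths, config = config,
                        config_hash = hash, log = lg),
                   class = "classification_experiment")
  if (!is.null(config$output_dir)) {
    write_classification_outputs(out, config$output_dir)
  }
  out
}

#' @export
print.classification_experiment <- function(x, ...) {
  cat("Maturity classification experiment\n")
  agg <- stats::aggregate(accuracy ~ model + set, data = x$metrics, FUN = mean)
  print(agg, row.names = FALSE)
  if (!is.null(x$anova)) {
    cat(sprintf("ANOVA across repeats: F = %.3f, p = %.4g (%s at 1%%)\n",
                x$anova$f, x$anova$p_value,
                if (x$anova$significant) "significant" else
                  "not significant"))
  }
  invisible(x)
}

write_classification_outputs <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(exp$config, file.path(dir, "config.yaml"))
  utils::write.csv(exp$metrics, file.path(dir, "accuracies.csv"),
                   row.names = FALSE)
  utils::write.csv(exp$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  for (r in seq_along(exp$splits)) {
    write_split_csv(exp$splits[[r]], exp$manifest$sample_id,
                    file.path(dir, sprintf("split_repeat%d.csv", r)))
  }
  for (nm in names(exp$confusion)) {
    utils::write.csv(unclass(exp$confusion[[nm]]),
                     file.path(dir, paste0("confusion_", nm, ".csv")))
  }
  for (mdl in names(exp$saliency)) {
    write_profile_csv(exp$saliency[[mdl]]$pooled,
                      file.path(dir, paste0("saliency_", mdl, ".csv")))
  }
  for (mdl in names(exp$models)) {
    utils::write.csv(exp$models[[mdl]]$log,
                     file.path(dir, paste0("training_log_", mdl, ".csv")),
                     row.names = FALSE)
  }
  writeLines(c(paste("config_hash:", exp$config_hash), exp$log),
             file.path(dir, "run.log"))
  try({
    grDevices::png(file.path(dir, "saliency_1d.png"), 800, 500)
    plot(exp$saliency[["1d"]]$pooled)
    grDevices::dev.off()
  }, silent = TRUE)
  invisible(dir)
}

#' Run the SSC-regression experiment
#'
#' Simulates SSC-coupled phantoms (36 per degree by default), preprocesses
#' them to mean spectra, removes outliers by the cross-validated PLS
#' screen, partitions by SPXY in 4:1:1 proportions, trains the 1-D
#' regression network and reports the R2/RMSE triad plus gradient saliency
#' profiles at the 5% and 10% prediction-error-rate thresholds.
#'
#' @param config an [experiment_config()].
#' @return an object of class `regression_experiment` with fields
#'   `metrics` (per-set R2/RMSE), `model`, `split`, `outliers`, `saliency`
#'   (one profile per error rate), `manifest`, `wavelengths`, `config`,
#'   `config_hash`, `log`.
#' @export
run_regression_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  hash <- config_hash(config)
  lg <- exp_log(character(0), "init", paste("config", hash))
  seeds <- derive_seeds(config$seed + 1L, 3L)

  pc <- phantom_config(image_height = config$image_size[1],
                       image_width = config$image_size[2],
                       n_crop_bands = config$n_crop_bands,
                       noise_sd = config$noise_sd,
                       ssc_amplitude = config$ssc_amplitude)
  ds <- simulate_dataset(config$reg_n_per_class, pc,
                         master_seed = seeds[1])
  lg <- exp_log(lg, "simulate", sprintf("%d SSC-coupled phantoms",
                                        nrow(ds$manifest)))
  prep <- lapply(ds$phantoms, function(ph) {
    preprocess_cube(ph$cube, config$crop_low, config$crop_high,
                    config$sg_window, config$sg_polyorder)
  })
  X <- t(vapply(prep, function(p) p$spectrum$values,
                numeric(length(prep[[1]]$spectrum$values))))
  wl <- prep[[1]]$spectrum$wavelengths
  y <- ds$manifest$ssc

  scr <- pls_outlier_removal(X, y, k = config$outlier_k,
                             ncomp = config$pls_ncomp, seed = seeds[2])
  keep <- scr$retained
  lg <- exp_log(lg, "outliers", sprintf("removed %d of %d samples",
                                        nrow(X) - length(keep), nrow(X)))
  Xk <- X[keep, , drop = FALSE]
  yk <- y[keep]
  n <- length(keep)
  n_train <- round(2 * n / 3)
  n_val <- round(n / 6)
  n_test <- n - n_train - n_val
  sp <- spxy_split(Xk, yk, n_train, n_val, n_test)
  lg <- exp_log(lg, "split", sprintf("SPXY %d/%d/%d", n_train, n_val,
                                     n_test))

  cfg <- resnet_config(task = "regression", epochs = config$epochs_reg,
                       batch_size = config$batch_size, seed = seeds[3])
  fit <- resnet(Xk[sp$train, , drop = FALSE], yk[sp$train], config = cfg,
                validation = list(x = Xk[sp$validation, , drop = FALSE],
                                  y = yk[sp$validation]),
                wavelengths = wl)
  lg <- exp_log(lg, "train", sprintf("regression model, %d epochs",
                                     config$epochs_reg))

  metrics <- NULL
  for (set in c("train", "validation", "test")) {
    idx <- switch(set, train = sp$train, validation = sp$validation,
                  test = sp$test)
    pred <- predict(fit, Xk[idx, , drop = FALSE])
    m <- regression_metrics(yk[idx], pred)
    metrics <- rbind(metrics, data.frame(set = set, r2 = m$r2,
                                         rmse = m$rmse))
  }
  lg <- exp_log(lg, "evaluate",
                paste(sprintf("%s R2 %.3f", metrics$set, metrics$r2),
                      collapse = ", "))

  saliency <- lapply(config$error_rates, function(er) {
    saliency_profile(fit, Xk[sp$test, , drop = FALSE], yk[sp$test],
                     error_rate = er)
  })
  names(saliency) <- sprintf("error_rate_%g", config$error_rates)

  out <- structure(list(metrics = metrics, model = fit, split = sp,
                        outliers = scr, saliency = saliency,
                        manifest = ds$manifest, wavelengths = wl,
                        config = config, config_hash = hash, log = lg),
                   class = "regression_experiment")
  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(dir, "config.yaml"))
    utils::write.csv(metrics, file.path(dir, "regression_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(scr$report, file.path(dir, "outlier_report.csv"),
                     row.names = FALSE)
    write_split_csv(sp, ds$manifest$sample_id[keep],
                    file.path(dir, "split_spxy.csv"))
    for (nm in names(saliency)) {
      write_profile_csv(saliency[[nm]],
                        file.path(dir, paste0("saliency_", nm, ".csv")))
    }
    utils::write.csv(fit$log, file.path(dir, "training_log_reg.csv"),
                     row.names = FALSE)
    writeLines(c(paste("config_hash:", hash), lg),
               file.path(dir, "run.log"))
  }
  out
}

#' @export
print.regression_experiment <- function(x, ...) {
  cat("SSC regression experiment\n")
  print(x$metrics, row.names = FALSE)
  cat(sprintf("outliers removed: %d\n",
              nrow(x$manifest) - length(x$outliers$retained)))
  invisible(x)
}
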