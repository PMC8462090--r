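# Metrics and statistics: confusion matrices, overall accuracy, R2/RMSE,
# ANOVA across repeated runs, grouped summaries with significance letters.

#' Confusion matrix
#'
#' @param truth,predicted label vectors of equal length; values must come
#'   from `classes`.
#' @param classes the ordered class set (default maturity degrees 0-3).
#' @param set optional tag ("train", "validation", "test") carried as an
#'   attribute.
#' @return a `confusion_matrix`: a square count matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, classes = 0:3, set = NULL) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  classes <- as.character(classes)
  t_i <- match(as.character(truth), classes)
  p_i <- match(as.character(predicted), classes)
  if (anyNA(t_i) || anyNA(p_i)) {
    stop("labels outside the class set ", paste(classes, collapse = ", "))
  }
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  for (i in seq_along(t_i)) m[t_i[i], p_i[i]] <- m[t_i[i], p_i[i]] + 1L
  structure(m, class = c("confusion_matrix", "matrix"), set = set)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  set <- attr(x, "set")
  if (!is.null(set)) cat(set, "set\n")
  print(unclass(x)[,])
  cat(sprintf("overall accuracy: %.2f%%\n", overall_accuracy(x)))
  invisible(x)
}

#' Overall classification accuracy
#'
#' The percentage of correctly classified samples:
#' `100 * trace / total` of a confusion matrix.
#'
#' @param m a [confusion_matrix()] or plain square count matrix.
#' @return accuracy in percent.
#' @export
overall_accuracy <- function(m) {
  m <- unclass(m)
  total <- sum(m)
  if (total <= 0) stop("empty confusion matrix")
  100 * sum(diag(m)) / total
}

#' Regression metrics: R2 and RMSE
#'
#' `R2 = 1 - SSres/SStot` (against the mean of the measured values) and
#' `RMSE = sqrt(mean squared error)`.
#'
#' @param measured,predicted numeric vectors of equal length (at least 2).
#' @return list with elements `r2` and `rmse`.
#' @export
regression_metrics <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 2L) {
    stop("measured and predicted must have equal length of at least 2")
  }
  sstot <- sum((measured - mean(measured))^2)
  if (sstot < 1e-300) stop("measured values have zero variance; R2 undefined")
  ssres <- sum((measured - predicted)^2)
  list(r2 = 1 - ssres / sstot, rmse = sqrt(mean((measured - predicted)^2)))
}

#' One-way ANOVA of accuracies across repeated model runs
#'
#' Compares the classification accuracies of two (or more) model families
#' over repeated random data samplings, either pooling the
#' train/validation/test sets or testing each set separately.  Significance
#' is reported at the 1% level.
#'
#' @param acc data frame with columns `model`, `accuracy` and (for
#'   `mode = "per_set"`) `set`.
#' @param mode pool all sets or test per set.
#' @param alpha significance level (default 0.01).
#' @return for `"pooled"`, a list with `f`, `p_value`, `significant`;
#'   for `"per_set"`, a named list of such lists.
#' @export
anova_across_repeats <- function(acc, mode = c("pooled", "per_set"),
                                 alpha = 0.01) {
  mode <- match.arg(mode)
  run_one <- function(d) {
    if (length(unique(d$model)) < 2L) {
      stop("at least two model groups are required")
    }
    if (any(table(d$model) < 2L)) {
      stop("each model group needs at least two accuracy values")
    }
    a <- stats::aov(accuracy ~ model, data = d)
    s <- summary(a)[[1]]
    f <- s[["F value"]][1]
    p <- s[["Pr(>F)"]][1]
    list(f = f, p_value = p, significant = p < alpha)
  }
  if (mode == "pooled") return(run_one(acc))
  out <- lapply(split(acc, acc$set), run_one)
  out
}

#' Grouped mean/SD summary with compact significance letters
#'
#' One-way ANOVA followed by Tukey HSD pairwise comparisons and a compact
#' letter display: groups that are not significantly different share a
#' letter, and the highest-mean group gets "a" (the convention of SSC
#' summary tables).
#'
#' @param values numeric vector.
#' @param groups group labels (at least two groups).
#' @param alpha significance level (default 0.05).
#' @return data frame with group, n, mean, sd and letters, ordered by
#'   decreasing mean.
#' @export
group_stats_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("at least two groups are required")
  if (stats::sd(values) < 1e-12) {
    stop("degenerate input: values have no variance")
  }
  d <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = d)
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  letters <- multcomp::cld(glht_fit, level = alpha, decreasing = TRUE)
  lt <- letters$mcletters$Letters
  out <- data.frame(
    group = levels(groups),
    n = as.integer(table(groups)),
    mean = as.numeric(tapply(values, groups, mean)),
    sd = as.numeric(tapply(values, groups, stats::sd)),
    letters = lt[levels(groups)],
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$mean), ]
}

# Tukey HSD p-values for all group pairs, used as an independent check of
# the letter display
tukey_pairwise_p <- function(values, groups) {
  fit <- stats::aov(y ~ g, data = data.frame(y = values, g = factor(groups)))
  as.data.frame(stats::TukeyHSD(fit)$g)
}
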