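# Sample partitioning: repeated per-class random splits for classification,
# PLS residual screening and SPXY maximin selection for regression.

new_split_indices <- function(train, validation, test, repeat_id = 1L,
                              seed = NA_integer_) {
  structure(list(train = sort(train), validation = sort(validation),
                 test = sort(test), repeat_id = as.integer(repeat_id),
                 seed = seed),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("split (repeat %d): %d train / %d validation / %d test\n",
              x$repeat_id, length(x$train), length(x$validation),
              length(x$test)))
  invisible(x)
}

#' Class-stratified random split
#'
#' Per class, draws the validation and then the test indices uniformly
#' without replacement; the remainder forms the training set.  At the
#' reference scale of 204 samples per class with 34 validation and 34 test
#' draws, each class contributes 136/34/34 samples.
#'
#' @param labels vector of class labels.
#' @param n_val_per_class,n_test_per_class held-out draws per class.
#' @param seed integer seed; the split is a pure function of
#'   `(labels, counts, seed)`.
#' @param repeat_id identifier recorded in the result, for repeated
#'   resampling designs.
#' @return a `split_indices` object (disjoint index sets).
#' @export
class_stratified_split <- function(labels, n_val_per_class,
                                   n_test_per_class, seed = 1L,
                                   repeat_id = 1L) {
  set.seed(seed)
  tr <- va <- te <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    need <- n_val_per_class + n_test_per_class
    if (length(idx) <= need) {
      stop("class ", cl, " has only ", length(idx),
           " samples; cannot hold out ", need)
    }
    held <- sample(idx, need)
    va <- c(va, held[seq_len(n_val_per_class)])
    te <- c(te, held[n_val_per_class + seq_len(n_test_per_class)])
    tr <- c(tr, setdiff(idx, held))
  }
  new_split_indices(tr, va, te, repeat_id, as.integer(seed))
}

# Cross-validated PLS predictions (mixOmics engine)
pls_cv_predict <- function(X, y, ncomp, folds, seed) {
  n <- nrow(X)
  colnames(X) <- colnames(X) %||% paste0("b", seq_len(ncol(X)))
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    nc <- min(ncomp, sum(tr) - 1L, ncol(X))
    fit <- mixOmics::pls(X[tr, , drop = FALSE], y[tr], ncomp = nc,
                         mode = "regression")
    p <- predict(fit, X[!tr, , drop = FALSE])
    pred[!tr] <- p$predict[, 1, nc]
  }
  pred
}

#' PLS-based outlier screening
#'
#' Fits a cross-validated PLS regression of the response on the spectra and
#' flags samples whose studentized prediction residual exceeds `k` standard
#' deviations; after removing them the screen is repeated once on the
#' retained samples.  Under the default policy the screen refuses to drop
#' more than 20% of the set.
#'
#' @param X samples x bands spectra matrix (at least 10 rows).
#' @param y response vector (SSC in Brix).
#' @param k studentized-residual cutoff (default 3; `Inf` retains all).
#' @param ncomp PLS components (capped by fold size).
#' @param folds cross-validation folds.
#' @param seed seed for the fold assignment.
#' @return list with `retained` (index vector) and `report` (data frame
#'   with index, residual, studentized residual, pass of removal).
#' @export
pls_outlier_removal <- function(X, y, k = 3, ncomp = 8L, folds = 10L,
                                seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 10L) stop("at least 10 samples are required")
  if (nrow(X) != length(y)) stop("X rows must match the length of y")
  if (any(apply(X, 2, stats::sd) < 1e-12) || stats::sd(y) < 1e-12) {
    stop("degenerate input: a column of X (or y) has zero variance")
  }
  keep <- seq_len(nrow(X))
  report <- NULL
  for (pass in 1:2) {
    if (!is.finite(k)) break
    pred <- pls_cv_predict(X[keep, , drop = FALSE], y[keep],
                           ncomp, folds, seed + pass - 1L)
    r <- y[keep] - pred
    stud <- r / stats::sd(r)
    bad <- abs(stud) > k
    if (any(bad)) {
      report <- rbind(report,
                      data.frame(index = keep[bad], residual = r[bad],
                                 studentized = stud[bad], pass = pass))
    }
    if (!any(bad)) break
    keep <- keep[!bad]
    n_removed <- nrow(X) - length(keep)
    if (n_removed > 0.2 * nrow(X)) {
      stop("outlier screen would remove ", n_removed, " of ", nrow(X),
           " samples (over 20%); check the data or raise k")
    }
  }
  list(retained = keep,
       report = report %||% data.frame(index = integer(0),
                                       residual = numeric(0),
                                       studentized = numeric(0),
                                       pass = integer(0)))
}

# Joint SPXY distance matrix: Euclidean distances in X and y, each scaled
# by its maximum
spxy_distance <- function(X, y) {
  dX <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, "-"))
  mX <- max(dX)
  my <- max(dy)
  if (mX < 1e-300 || my < 1e-300) {
    stop("SPXY requires non-duplicate data (maximum distance is zero)")
  }
  dX / mX + dy / my
}

# Kennard-Stone maximin selection on a precomputed distance matrix.
# Ties break to the lowest index.
kennard_stone_select <- function(D, n_select) {
  n <- nrow(D)
  first <- which(D == max(D), arr.ind = TRUE)
  first <- first[order(first[, 1], first[, 2]), , drop = FALSE]
  sel <- sort(unname(first[1, ]))
  while (length(sel) < n_select) {
    rest <- setdiff(seq_len(n), sel)
    mind <- apply(D[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(mind)])
  }
  sel
}

#' SPXY sample-set partitioning
#'
#' Splits samples by the SPXY criterion: a joint distance
#' `d(i,j) = dX(i,j)/max dX + dy(i,j)/max dy` combines spectral and
#' response distances, and Kennard-Stone maximin selection on it picks a
#' representative training set (the first two picks are the most distant
#' pair; each further pick maximizes its minimal distance to the selected
#' set, ties to the lowest index).  The remaining samples are ranked by
#' their distance to the training set and assigned alternately to the
#' validation and test sets.  The procedure is fully deterministic.
#'
#' @param X samples x bands spectra matrix.
#' @param y response vector.
#' @param n_train,n_val,n_test set sizes (sum at most `nrow(X)`).
#' @return a `split_indices` object.
#' @export
spxy_split <- function(X, y, n_train, n_val, n_test) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_train + n_val + n_test > n) {
    stop("requested set sizes exceed the number of samples")
  }
  if (n_train < 2L) stop("n_train must be at least 2")
  D <- spxy_distance(X, y)
  train <- kennard_stone_select(D, n_train)
  rest <- setdiff(seq_len(n), train)
  mind <- apply(D[rest, train, drop = FALSE], 1, min)
  rest <- rest[order(-mind, rest)]
  va <- te <- integer(0)
  take_val <- TRUE
  for (i in rest) {
    if (take_val && length(va) < n_val) {
      va <- c(va, i)
    } else if (length(te) < n_test) {
      te <- c(te, i)
    } else if (length(va) < n_val) {
      va <- c(va, i)
    }
    take_val <- !take_val
    if (length(va) >= n_val && length(te) >= n_test) break
  }
  new_split_indices(train, va, te, repeat_id = 1L)
}

#' Write a split manifest as CSV
#'
#' @param split a `split_indices` object.
#' @param ids sample identifiers indexed by the split.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_csv <- function(split, ids, path) {
  df <- data.frame(
    sample_id = ids[c(split$train, split$validation, split$test)],
    set = rep(c("train", "validation", "test"),
              c(length(split$train), length(split$validation),
                length(split$test))),
    repeat_id = split$repeat_id, seed = split$seed)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
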