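test_that("confusion matrices tally counts with conserved row sums", {
  t <- c(0, 0, 1, 2, 3, 3)
  p <- c(0, 1, 1, 2, 3, 0)
  m <- confusion_matrix(t, p)
  expect_equal(sum(m), 6)
  expect_equal(unname(diag(unclass(m)[,])), c(1, 1, 1, 1))
  expect_equal(unname(m["0", "1"]), 1)
  expect_equal(unname(m["3", "0"]), 1)
  perfect <- confusion_matrix(0:3, 0:3)
  expect_true(all(unclass(perfect)[,][upper.tri(diag(4)) |
                                        lower.tri(diag(4))] == 0))
  expect_error(confusion_matrix(c(0, 5), c(0, 1)), "outside")
  set.seed(2)
  tt <- sample(0:3, 200, TRUE); pp <- sample(0:3, 200, TRUE)
  mm <- confusion_matrix(tt, pp)
  expect_equal(unname(rowSums(unclass(mm)[,])),
               as.integer(table(factor(tt, levels = 0:3))))
})

test_that("overall accuracy equals the direct proportion of agreement", {
  set.seed(3)
  for (i in 1:10) {
    t <- sample(0:3, 60, TRUE)
    p <- sample(0:3, 60, TRUE)
    expect_equal(overall_accuracy(confusion_matrix(t, p)),
                 100 * mean(t == p), tolerance = 1e-12)
    # permutation invariance
    o <- sample(60)
    expect_equal(overall_accuracy(confusion_matrix(t[o], p[o])),
                 overall_accuracy(confusion_matrix(t, p)))
  }
  expect_equal(overall_accuracy(confusion_matrix(0:3, 0:3)), 100)
  expect_error(overall_accuracy(matrix(0, 4, 4)), "empty")
})

test_that("regression metrics match hand-computed sums of squares", {
  expect_equal(regression_metrics(c(1, 2, 3), c(1, 2, 3)),
               list(r2 = 1, rmse = 0))
  m <- c(8, 9, 10, 11)
  expect_equal(regression_metrics(m, rep(mean(m), 4))$r2, 0)
  r <- regression_metrics(m, c(8.5, 8.5, 10.5, 10.5))
  # SStot = 5, SSres = 4 * 0.25 = 1
  expect_equal(r$r2, 1 - 1 / 5)
  expect_equal(r$rmse, 0.5)
  # translation equivariance of RMSE
  r2 <- regression_metrics(m + 3, c(8.5, 8.5, 10.5, 10.5) + 3)
  expect_equal(r2$rmse, r$rmse)
  expect_error(regression_metrics(rep(1, 4), rep(1, 4)), "variance")
})

test_that("across-repeat ANOVA matches the closed-form F statistic", {
  acc <- data.frame(model = rep(c("1d", "3d"), each = 5),
                    accuracy = c(rep(0.8, 5), rep(0.8, 5)))
  acc$accuracy <- acc$accuracy + rep(c(-0.01, 0.01, 0, -0.005, 0.005), 2)
  out <- anova_across_repeats(acc)
  expect_equal(out$f, 0, tolerance = 1e-12)
  expect_false(out$significant)
  set.seed(5)
  sep <- data.frame(model = rep(c("a", "b"), each = 5),
                    accuracy = c(rnorm(5, 0.5, 0.01), rnorm(5, 0.9, 0.01)))
  out2 <- anova_across_repeats(sep)
  # closed form: F = MS_between / MS_within for two groups of five
  g <- split(sep$accuracy, sep$model)
  gm <- vapply(g, mean, 0)
  msb <- 5 * sum((gm - mean(sep$accuracy))^2) / 1
  msw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0)) / 8
  expect_equal(out2$f, msb / msw, tolerance = 1e-10)
  expect_true(out2$significant)
  expect_error(anova_across_repeats(sep[1:5, ]), "two model groups")
})

test_that("the ANOVA keeps its nominal type-I error on exchangeable data", {
  set.seed(6)
  rej <- replicate(1000, {
    d <- data.frame(model = rep(c("a", "b"), each = 5),
                    accuracy = rnorm(10))
    anova_across_repeats(d, alpha = 0.05)$significant
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("per-set ANOVA mode reports each sample set", {
  set.seed(7)
  acc <- expand.grid(repeat_id = 1:5, model = c("1d", "3d"),
                     set = c("train", "validation", "test"))
  acc$accuracy <- rnorm(nrow(acc), 0.9, 0.02)
  out <- anova_across_repeats(acc, mode = "per_set")
  expect_setequal(names(out), c("train", "validation", "test"))
  expect_true(all(vapply(out, function(o) is.finite(o$p_value), TRUE)))
})

test_that("significance letters reproduce the SSC grouping pattern", {
  set.seed(31)
  g <- rep(c("D1", "D2", "D3", "D4"), each = 36)
  v <- c(rnorm(36, 8.23, 1.15), rnorm(36, 8.57, 0.8),
         rnorm(36, 9.58, 1.32), rnorm(36, 10.37, 1.71))
  out <- group_stats_letters(v, g)
  lt <- setNames(out$letters, out$group)
  # D1 and D2 share a letter; D3 and D4 are each distinct from both
  expect_true(any(strsplit(lt["D1"], "")[[1]] %in%
                    strsplit(lt["D2"], "")[[1]]))
  expect_false(any(strsplit(lt["D4"], "")[[1]] %in%
                     strsplit(lt["D1"], "")[[1]]))
  expect_false(any(strsplit(lt["D4"], "")[[1]] %in%
                     strsplit(lt["D3"], "")[[1]]))
  expect_equal(out$group[1], "D4")  # highest mean first, lettered "a"
  expect_true(grepl("a", out$letters[1]))
  expect_error(group_stats_letters(rep(1, 8), rep(c("a", "b"), 4)),
               "variance")
  expect_error(group_stats_letters(rnorm(8), rep("a", 8)), "two groups")
})

test_that("letters agree with pairwise Tukey significance adjacency", {
  set.seed(33)
  g <- rep(letters[1:4], each = 20)
  v <- rnorm(80, mean = rep(c(0, 0.2, 1.5, 3), each = 20), sd = 0.5)
  out <- group_stats_letters(v, g, alpha = 0.05)
  lt <- setNames(out$letters, out$group)
  pv <- ripenet:::tukey_pairwise_p(v, g)
  share <- function(a, b) {
    any(strsplit(lt[a], "")[[1]] %in% strsplit(lt[b], "")[[1]])
  }
  for (pair in rownames(pv)) {
    ab <- strsplit(pair, "-")[[1]]
    if (pv[pair, "p adj"] < 0.05) {
      expect_false(share(ab[1], ab[2]))
    } else {
      expect_true(share(ab[1], ab[2]))
    }
  }
})
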