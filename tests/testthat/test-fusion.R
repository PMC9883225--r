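test_that("variance filter drops exactly the sub-threshold columns", {
  set.seed(1)
  X <- cbind(const = rep(1, 40),
             tiny = stats::rnorm(40, sd = 0.01),
             wide = stats::rnorm(40, sd = 2))
  vf <- variance_filter(X, 0.05)
  expect_identical(unname(vf$keep), c(FALSE, FALSE, TRUE))
  ## boundary: a column whose variance equals the threshold is kept
  col <- stats::rnorm(40)
  thr <- stats::var(col)
  X2 <- cbind(a = col, b = rep(0, 40))
  vf2 <- variance_filter(X2, thr)
  expect_true(vf2$keep[["a"]])
  ## random matrix agrees with a per-column loop
  X3 <- matrix(stats::rnorm(200, sd = 0.3), 20)
  colnames(X3) <- paste0("f", 1:10)
  vf3 <- variance_filter(X3, 0.05)
  for (j in 1:10)
    expect_identical(unname(vf3$keep[j]), stats::var(X3[, j]) >= 0.05)
  expect_error(variance_filter(cbind(x = rep(2, 5)), 0.05), "all columns")
})

make_table <- function(n = 150, informative = 3, noise = 5, seed = 2) {
  set.seed(seed)
  y <- rep(pah_classes(), length.out = n)
  X <- matrix(stats::rnorm(n * (informative + noise)), n)
  for (j in seq_len(informative))
    X[, j] <- X[, j] + 2 * as.integer(factor(y, pah_classes()))
  colnames(X) <- c(paste0("sig_", seq_len(informative)),
                   paste0("noise_", seq_len(noise)))
  list(X = X, y = y)
}

test_that("importance selection ranks planted signal above noise", {
  cfg <- boost_config(n_trees = 60L, learning_rate = 0.3)
  wins <- 0L
  for (s in 1:5) {
    tb <- make_table(seed = s)
    sel <- importance_select(tb$X, tb$y, cfg, target_dim = 3L)
    wins <- wins + sum(grepl("^sig_", colnames(sel$matrix)))
  }
  expect_gt(wins / 15, 0.7)
})

test_that("importance selection is deterministic and honors the deep block", {
  tb <- make_table()
  cfg <- boost_config(n_trees = 60L)
  s1 <- importance_select(tb$X, tb$y, cfg, target_dim = 4L)
  s2 <- importance_select(tb$X, tb$y, cfg, target_dim = 4L)
  expect_identical(s1$keep, s2$keep)
  ## identity when the target matches the available count; flagged above it
  s3 <- importance_select(tb$X, tb$y, cfg, target_dim = ncol(tb$X))
  expect_true(all(s3$keep))
  expect_false(attr(s3$keep, "flagged"))
  s4 <- importance_select(tb$X, tb$y, cfg, target_dim = ncol(tb$X) + 10L)
  expect_true(attr(s4$keep, "flagged"))
  ## deep_* columns are exempt from removal
  X5 <- tb$X
  colnames(X5)[4:8] <- paste0("deep_", 1:5)
  s5 <- importance_select(X5, tb$y, cfg, target_dim = 6L)
  expect_true(all(s5$keep[paste0("deep_", 1:5)]))
  expect_equal(sum(s5$keep), 6L)
})

test_that("the boosted classifier separates a separable table", {
  tb <- make_table(n = 300, seed = 4)
  model <- train_classifier(tb$X, tb$y, boost_config(n_trees = 150L))
  expect_gte(mean(predict(model, tb$X) == tb$y), 0.98)
  pr <- predict(model, tb$X, type = "prob")
  expect_equal(dim(pr), c(300L, 3L))
  expect_equal(unname(rowSums(pr)), rep(1, 300), tolerance = 1e-6)
  ## same seed, same data: identical predictions
  model2 <- train_classifier(tb$X, tb$y, boost_config(n_trees = 150L))
  expect_identical(predict(model, tb$X), predict(model2, tb$X))
  expect_error(train_classifier(tb$X, rep("CHD", 300), boost_config()),
               "degenerate")
})

test_that("permuted labels yield chance-level held-out accuracy", {
  tb <- make_table(n = 300, seed = 5)
  set.seed(99)
  y_perm <- sample(tb$y)
  idx <- seq_len(150)
  model <- train_classifier(tb$X[idx, ], y_perm[idx],
                            boost_config(n_trees = 150L))
  acc <- mean(predict(model, tb$X[-idx, ]) == y_perm[-idx])
  expect_gt(acc, 1 / 3 - 0.12)
  expect_lt(acc, 1 / 3 + 0.12)
})

test_that("majority vote equals the mode whenever a strict majority exists", {
  expect_equal(as.character(majority_vote(c("A", "A", "B"))), "A")
  expect_equal(as.character(majority_vote("CHD")), "CHD")
  set.seed(12)
  for (i in 1:1000) {
    n <- sample(3:25, 1)
    maj <- sample(pah_classes(), 1)
    k <- floor(n / 2) + 1
    seqv <- sample(c(rep(maj, k),
                     sample(pah_classes(), n - k, replace = TRUE)))
    counts <- table(seqv)
    expect_identical(as.character(majority_vote(seqv)),
                     names(counts)[which.max(counts)])
  }
})

test_that("no-majority sequences trigger the verification fallback", {
  ## candidate after the single pass need not be modal here
  v <- majority_vote(c("Normal", "CHD", "CHD-PAH", "CHD", "Normal", "CHD-PAH"))
  expect_true(attr(v, "fallback"))
  ## tie broken deterministically by class order
  expect_identical(as.character(v), "Normal")
  v2 <- majority_vote(c("CHD", "CHD-PAH", "CHD", "CHD-PAH", "Normal"))
  expect_true(as.character(v2) %in% c("CHD"))
})
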