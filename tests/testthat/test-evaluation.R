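# Metrics: confusion matrices, macro averages, one-vs-one macro-AUC,
# cross-fold aggregation and paired t-tests.

# independent naive implementation of the macro metrics used as an oracle
oracle_macro <- function(true, pred, C) {
  acc <- mean(true == pred)
  prec <- rec <- f1 <- numeric(C)
  for (c in 1:C) {
    tp <- sum(true == c & pred == c)
    fp <- sum(true != c & pred == c)
    fn <- sum(true == c & pred != c)
    prec[c] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[c] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[c] <- if (prec[c] + rec[c] == 0) 0 else
      2 * prec[c] * rec[c] / (prec[c] + rec[c])
  }
  list(accuracy = acc, precision = mean(prec), recall = mean(rec),
       f1 = mean(f1))
}

# exhaustive Mann-Whitney pair counting (ties count 1/2)
oracle_binary_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

oracle_auc_ovo <- function(true, probs) {
  C <- ncol(probs)
  vals <- c()
  for (i in 1:(C - 1)) for (j in (i + 1):C) {
    if (!any(true == i) || !any(true == j)) next
    a_ij <- oracle_binary_auc(probs[true == i, i], probs[true == j, i])
    a_ji <- oracle_binary_auc(probs[true == j, j], probs[true == i, j])
    vals <- c(vals, (a_ij + a_ji) / 2)
  }
  mean(vals)
}

test_that("confusion matrices count and normalize correctly", {
  expect_equal(confusion_matrix(c(1, 2, 3), c(1, 2, 3), 3), diag(3),
               ignore_attr = TRUE)
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), 2)
  expect_equal(cm, matrix(c(1L, 0L, 1L, 1L), 2, 2))
  norm <- normalize_confusion(cm)
  expect_equal(norm, matrix(c(0.5, 0, 0.5, 1), 2, 2), ignore_attr = TRUE)
  # conservation: total count equals N
  set.seed(16)
  for (i in 1:10) {
    N <- sample(5:50, 1); C <- sample(2:6, 1)
    t0 <- sample(C, N, replace = TRUE); p0 <- sample(C, N, replace = TRUE)
    expect_equal(sum(confusion_matrix(t0, p0, C)), N)
  }
  expect_error(confusion_matrix(c(0, 1), c(1, 1), 2), "out of range")
  # zero-support rows are flagged
  cm2 <- confusion_matrix(c(1, 1), c(1, 2), 3)
  expect_equal(attr(normalize_confusion(cm2), "zero_support"), c(2L, 3L))
})

test_that("macro metrics reproduce the hand-evaluated two-class example", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), 2)
  m <- macro_metrics(cm)
  expect_equal(m$accuracy, 2 / 3, tolerance = 1e-12)
  expect_equal(m$precision, (1 + 0.5) / 2, tolerance = 1e-12)
  expect_equal(m$recall, (0.5 + 1) / 2, tolerance = 1e-12)
  expect_equal(m$f1, ((2 * 1 * 0.5 / 1.5) + (2 * 0.5 * 1 / 1.5)) / 2,
               tolerance = 1e-12)
  # perfect predictions
  perf <- macro_metrics(diag(4) * 3)
  expect_equal(unlist(perf[c("accuracy", "precision", "recall", "f1")]),
               rep(1, 4), ignore_attr = TRUE)
})

test_that("macro metrics agree with an independent oracle on random label sets", {
  set.seed(17)
  for (i in 1:100) {
    N <- sample(5:30, 1); C <- sample(2:6, 1)
    t0 <- sample(C, N, replace = TRUE)
    p0 <- sample(C, N, replace = TRUE)
    m <- macro_metrics(confusion_matrix(t0, p0, C))
    ref <- oracle_macro(t0, p0, C)
    for (k in names(ref)) expect_equal(m[[k]], ref[[k]], tolerance = 1e-9)
  }
})

test_that("macro metrics are invariant to consistent relabeling", {
  set.seed(18)
  t0 <- sample(4, 40, replace = TRUE)
  p0 <- sample(4, 40, replace = TRUE)
  perm <- sample(4)
  m1 <- macro_metrics(confusion_matrix(t0, p0, 4))
  m2 <- macro_metrics(confusion_matrix(perm[t0], perm[p0], 4))
  for (k in c("accuracy", "precision", "recall", "f1"))
    expect_equal(m1[[k]], m2[[k]], tolerance = 1e-12)
})

test_that("one-vs-one macro-AUC matches exhaustive pair enumeration", {
  # perfectly separated probabilities
  probs <- rbind(c(.8, .1, .1), c(.7, .2, .1), c(.1, .8, .1),
                 c(.2, .7, .1), c(.1, .2, .7), c(.1, .1, .8))
  expect_equal(as.numeric(macro_auc_ovo(c(1, 1, 2, 2, 3, 3), probs)), 1)
  # label-independent probabilities give 0.5 by the tie convention
  flat <- matrix(1 / 3, 6, 3)
  expect_equal(as.numeric(macro_auc_ovo(c(1, 1, 2, 2, 3, 3), flat)), 0.5)
  # 3-class, 6-sample toy table vs the exhaustive oracle
  set.seed(19)
  probs2 <- matrix(runif(18), 6, 3)
  probs2 <- probs2 / rowSums(probs2)
  y2 <- c(1, 2, 3, 1, 2, 3)
  expect_equal(as.numeric(macro_auc_ovo(y2, probs2)),
               oracle_auc_ovo(y2, probs2), tolerance = 1e-12)
  # random instances
  for (i in 1:25) {
    N <- sample(6:30, 1); C <- sample(2:5, 1)
    y <- sample(C, N, replace = TRUE)
    if (length(unique(y)) < 2) next
    p <- matrix(runif(N * C), N, C); p <- p / rowSums(p)
    expect_equal(as.numeric(macro_auc_ovo(y, p)), oracle_auc_ovo(y, p),
                 tolerance = 1e-9)
  }
})

test_that("for two classes the OvO macro-AUC reduces to binary AUC", {
  skip_if_not_installed("pROC")
  set.seed(20)
  y <- sample(2, 40, replace = TRUE)
  p1 <- runif(40)
  probs <- cbind(p1, 1 - p1)
  mine <- as.numeric(macro_auc_ovo(y, probs))
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = y == 1, predictor = p1, direction = "<", quiet = TRUE))))
  expect_equal(mine, ref, tolerance = 1e-9)
  # a pair with a missing class is skipped and flagged
  res <- macro_auc_ovo(rep(1L, 5), matrix(runif(15), 5, 3))
  expect_true(is.na(res))
  expect_gt(length(attr(res, "skipped_pairs")), 0)
})

test_that("fold aggregation reports mean and sample sd to four decimals", {
  agg <- aggregate_folds(data.frame(accuracy = c(0.8, 0.9)))
  expect_equal(agg$mean, 0.85)
  expect_equal(agg$sd, sd(c(0.8, 0.9)), tolerance = 1e-12)
  expect_equal(agg$sd, 0.0707107, tolerance = 1e-6)
  expect_equal(agg$formatted, "0.8500 ± 0.0707")
  expect_equal(aggregate_folds(data.frame(f1 = c(0.5, 0.5, 0.5)))$sd, 0)
  single <- aggregate_folds(data.frame(f1 = 0.4))
  expect_equal(single$sd, 0)
  expect_true(attr(single, "single_fold"))
  # mean lies within [min, max] on random inputs
  set.seed(21)
  for (i in 1:20) {
    v <- runif(sample(2:8, 1))
    a <- aggregate_folds(data.frame(m = v))
    expect_gte(a$mean, min(v)); expect_lte(a$mean, max(v))
  }
})

test_that("paired t-tests match the hand formula and flag degeneracy", {
  # identical vectors: statistic 0, p = 1
  same <- paired_ttest(c(.5, .6, .7), c(.5, .6, .7))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_true(same$zero_variance)
  # constant non-zero differences: zero-variance flag, undefined p
  const <- paired_ttest(c(.6, .7, .8, .9, 1), c(.5, .6, .7, .8, .9))
  expect_true(const$zero_variance)
  expect_true(is.na(const$p.value))
  # hand formula t = mean(d) / (sd(d) / sqrt(n))
  set.seed(22)
  a <- runif(6); b <- runif(6)
  res <- paired_ttest(a, b)
  d <- a - b
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(6)), tolerance = 1e-12)
  expect_equal(res$p.value,
               2 * pt(abs(mean(d) / (sd(d) / sqrt(6))), df = 5,
                      lower.tail = FALSE), tolerance = 1e-12)
})

test_that("evaluation reports bundle metrics, confusion and per-class summaries", {
  set.seed(23)
  y <- sample(6, 60, replace = TRUE)
  p <- matrix(runif(360), 60, 6); p <- p / rowSums(p)
  rep1 <- eval_report(y, p, fold = 2)
  expect_equal(rep1$fold, 2)
  expect_true(all(unlist(rep1$metrics) >= 0 & unlist(rep1$metrics) <= 1))
  rs <- rowSums(rep1$confusion_norm)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-9))
  expect_length(rep1$per_class, 6)
  expect_equal(rep1$n, 60)
  # ROC curve coordinates are monotone from (0,0) to (1,1)
  rocs <- roc_curves(y, p)
  for (rc in rocs) {
    expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
    expect_equal(tail(rc$fpr, 1), 1); expect_equal(tail(rc$tpr, 1), 1)
    expect_true(all(diff(rc$fpr) >= 0))
    expect_true(all(diff(rc$tpr) >= 0))
  }
})
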