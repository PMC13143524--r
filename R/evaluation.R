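# Evaluation: confusion matrices, macro metrics, one-vs-one macro-AUC,
# cross-fold aggregation and paired t-tests.

#' Confusion matrix of multiclass predictions
#'
#' Entry (i, j) counts samples of true class i predicted as class j.
#'
#' @param true,pred Integer class ids in 1..C.
#' @param C Number of classes.
#' @return C x C count matrix.
#' @export
confusion_matrix <- function(true, pred, C) {
  stopifnot(length(true) == length(pred))
  if (any(true < 1 | true > C | pred < 1 | pred > C))
    stop("labels out of range 1..", C)
  cm <- matrix(0L, C, C)
  for (i in seq_along(true)) cm[true[i], pred[i]] <- cm[true[i], pred[i]] + 1L
  cm
}

#' Row-normalized confusion matrix
#'
#' Rows (true classes) are divided by their sums; rows with zero support
#' are left at zero and flagged in the `zero_support` attribute.
#'
#' @param cm C x C count matrix.
#' @return C x C matrix with rows summing to 1 (or 0 for empty classes).
#' @export
normalize_confusion <- function(cm) {
  rs <- rowSums(cm)
  out <- cm / ifelse(rs == 0, 1, rs)
  attr(out, "zero_support") <- which(rs == 0)
  out
}

#' Macro-averaged accuracy, precision, recall and F1
#'
#' Per-class one-vs-rest precision TP/(TP+FP), recall TP/(TP+FN) and
#' F1 = 2PR/(P+R), macro-averaged without class weighting; accuracy is
#' trace/N. Classes with a zero denominator contribute 0 and are flagged.
#'
#' @param cm C x C confusion count matrix.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `per_class`
#'   data.frame and `flagged` class indices.
#' @export
macro_metrics <- function(cm) {
  C <- nrow(cm)
  stopifnot(C >= 2, ncol(cm) == C)
  N <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  flagged <- which((tp + fp) == 0 | (tp + fn) == 0)
  list(accuracy = if (N == 0) 0 else sum(tp) / N,
       precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       per_class = data.frame(class = seq_len(C), tp = tp, fp = fp, fn = fn,
                              tn = N - tp - fp - fn, precision = prec,
                              recall = rec, f1 = f1),
       flagged = flagged)
}

# binary ranking AUC with the Mann-Whitney tie convention (ties count 1/2)
binary_auc <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n0 <- length(scores_neg)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-one macro-averaged AUC
#'
#' For each unordered class pair (i, j), restricted to samples of those two
#' classes, the AUC of class i's probability for discriminating i from j
#' and the AUC of class j's probability for discriminating j from i are
#' averaged; the macro average runs over all C(C-1)/2 pairs. Pairs with a
#' class absent are skipped and flagged.
#'
#' @param true Integer class ids in 1..C.
#' @param probs N x C probability matrix (rows sum to 1).
#' @return Scalar macro-AUC with attribute `skipped_pairs`.
#' @export
macro_auc_ovo <- function(true, probs) {
  C <- ncol(probs)
  stopifnot(length(true) == nrow(probs))
  pair_aucs <- c()
  skipped <- list()
  for (i in seq_len(C - 1)) for (j in (i + 1):C) {
    sel <- true == i | true == j
    if (!any(true[sel] == i) || !any(true[sel] == j)) {
      skipped[[length(skipped) + 1L]] <- c(i, j)
      next
    }
    a_ij <- binary_auc(probs[true == i, i], probs[sel & true == j, i])
    a_ji <- binary_auc(probs[true == j, j], probs[sel & true == i, j])
    pair_aucs <- c(pair_aucs, (a_ij + a_ji) / 2)
  }
  out <- if (length(pair_aucs) == 0) NA_real_ else mean(pair_aucs)
  attr(out, "skipped_pairs") <- skipped
  out
}

#' Per-class ROC curve coordinates (one-vs-rest)
#'
#' @param true Integer class ids in 1..C.
#' @param probs N x C probability matrix.
#' @return List of data.frames (`threshold`, `fpr`, `tpr`) per class.
#' @export
roc_curves <- function(true, probs) {
  lapply(seq_len(ncol(probs)), function(c) {
    y <- as.integer(true == c)
    sc <- probs[, c]
    th <- c(Inf, sort(unique(sc), decreasing = TRUE), -Inf)
    pos <- sum(y == 1); neg <- sum(y == 0)
    data.frame(
      threshold = th,
      fpr = vapply(th, function(t) if (neg == 0) 0 else sum(sc >= t & y == 0) / neg, 0),
      tpr = vapply(th, function(t) if (pos == 0) 0 else sum(sc >= t & y == 1) / pos, 0))
  })
}

#' Evaluation report for one fold
#'
#' @param true Integer class ids of the validation samples.
#' @param probs N x C predicted probability matrix.
#' @param class_names Class labels.
#' @param fold Fold id.
#' @return An `eval_report`: macro metrics + macro-AUC, confusion matrices,
#'   per-class correct fraction and top misclassifications.
#' @export
eval_report <- function(true, probs, class_names = CSF_CLASSES, fold = 1L) {
  C <- ncol(probs)
  pred <- max.col(probs)
  cm <- confusion_matrix(true, pred, C)
  norm <- normalize_confusion(cm)
  m <- macro_metrics(cm)
  mauc <- macro_auc_ovo(true, probs)
  per_class <- lapply(seq_len(C), function(i) {
    row <- norm[i, ]
    mis <- order(row, decreasing = TRUE)
    mis <- setdiff(mis, i)[1:2]
    list(class = class_names[i], correct = unname(row[i]),
         top_misclassifications = stats::setNames(row[mis], class_names[mis]))
  })
  structure(list(fold = fold,
                 metrics = list(accuracy = m$accuracy, precision = m$precision,
                                recall = m$recall, f1 = m$f1,
                                mauc = as.numeric(mauc)),
                 confusion = cm, confusion_norm = norm,
                 per_class = per_class, flagged = m$flagged,
                 skipped_pairs = attr(mauc, "skipped_pairs"),
                 n = length(true), class_names = class_names),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report (fold ", x$fold, ", n = ", x$n, ")\n", sep = "")
  with(x$metrics, cat(sprintf(
    "  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f  mAUC %.4f\n",
    accuracy, precision, recall, f1, mauc)))
  invisible(x)
}

#' Aggregate per-fold metrics into a mean ± sd table
#'
#' Arithmetic mean and sample standard deviation (ddof 1) per metric,
#' formatted to four decimals. With a single fold the sd is reported as 0
#' and flagged.
#'
#' @param fold_metrics data.frame of per-fold metric columns.
#' @return data.frame with `metric`, `mean`, `sd`, `formatted`.
#' @export
aggregate_folds <- function(fold_metrics) {
  stopifnot(nrow(fold_metrics) >= 1)
  single <- nrow(fold_metrics) < 2
  out <- do.call(rbind, lapply(names(fold_metrics), function(nm) {
    v <- fold_metrics[[nm]]
    s <- if (single) 0 else stats::sd(v)
    data.frame(metric = nm, mean = mean(v), sd = s,
               formatted = fmt_mean_sd(mean(v), s))
  }))
  attr(out, "single_fold") <- single
  out
}

#' Paired two-sided t-test on fold-paired metric vectors
#'
#' @param a,b Equal-length numeric vectors (one value per fold).
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic`, `p.value`, `significant`,
#'   `zero_variance` flag.
#' @export
paired_ttest <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) < 1e-12) {
    return(list(statistic = if (mean(d) == 0) 0 else NA_real_,
                p.value = if (mean(d) == 0) 1 else NA_real_,
                significant = FALSE, zero_variance = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       significant = tt$p.value < alpha, zero_variance = FALSE)
}
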