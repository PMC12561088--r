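# Multiclass evaluation: accuracy, macro-averaged precision/recall/F1,
# one-vs-rest macro AUROC and AUPR, and misclassification analysis
# (per-class error table and normalized confusion heatmap).

# One-vs-rest AUROC via the normalized Mann-Whitney U statistic; tied
# scores count 1/2 (midrank convention).
auroc_binary <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# One-vs-rest AUPR as step-wise precision-recall integration without
# interpolation (average precision): sum of precision at each recalled
# positive, in descending score order (ties broken by original index).
aupr_binary <- function(scores, positive) {
  np <- sum(positive)
  if (np == 0) return(NA_real_)
  ord <- order(-scores, seq_along(scores))
  pos <- positive[ord]
  prec_at <- cumsum(pos) / seq_along(pos)
  sum(prec_at[pos]) / np
}

#' Metric suite for multiclass probability predictions
#'
#' Accuracy is the fraction of argmax matches (argmax ties go to the
#' lowest class id).  Precision, recall and F1 are unweighted means over
#' the classes present in the test set; a class with no predicted
#' positives contributes precision 0.  AUROC (Mann-Whitney, ties 1/2) and
#' AUPR (step-wise average precision) are computed one-vs-rest per class
#' and unweighted-averaged over classes with at least one positive.
#' Catalog classes absent from the test set are excluded from the macro
#' averages with a warning (their one-vs-rest curves are undefined).
#'
#' @param y_true integer vector of 0-based true class ids.
#' @param prob n x n_classes probability matrix, column j corresponding to
#'   class id j-1; rows must sum to 1 (within 1e-6).
#' @return object of class `ddi_metrics`: list with `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `macro_auroc`,
#'   `macro_aupr`, `per_class_accuracy` (named by class id, `NA` for
#'   test-absent classes), `n` and `classes_evaluated`.
#' @export
compute_metrics <- function(y_true, prob) {
  prob <- as.matrix(prob)
  n <- nrow(prob)
  stopifnot(length(y_true) == n, n >= 1)
  if (any(abs(rowSums(prob) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  k <- ncol(prob)
  if (any(y_true < 0 | y_true >= k)) stop("label outside 0..", k - 1)
  pred <- max.col(prob, ties.method = "first") - 1L
  accuracy <- mean(pred == y_true)

  all_classes <- 0:(k - 1)
  present <- all_classes[all_classes %in% y_true]
  absent <- setdiff(all_classes, present)
  if (length(absent) > 0)
    warning("class(es) absent from the test set excluded from macro ",
            "averages: ", paste(absent, collapse = ", "))
  prec <- rec <- f1 <- auroc <- aupr <- numeric(length(present))
  per_class_acc <- stats::setNames(rep(NA_real_, k), all_classes)
  for (i in seq_along(present)) {
    cl <- present[i]
    tp <- sum(pred == cl & y_true == cl)
    fp <- sum(pred == cl & y_true != cl)
    fn <- sum(pred != cl & y_true == cl)
    prec[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[i] <- tp / (tp + fn)
    f1[i] <- if (prec[i] + rec[i] == 0) 0 else
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
    per_class_acc[as.character(cl)] <- rec[i]
    auroc[i] <- auroc_binary(prob[, cl + 1L], y_true == cl)
    aupr[i] <- aupr_binary(prob[, cl + 1L], y_true == cl)
  }
  structure(list(accuracy = accuracy,
                 macro_precision = mean(prec),
                 macro_recall = mean(rec),
                 macro_f1 = mean(f1),
                 macro_auroc = mean(auroc, na.rm = TRUE),
                 macro_aupr = mean(aupr, na.rm = TRUE),
                 per_class_accuracy = per_class_acc,
                 n = n, classes_evaluated = present),
            class = "ddi_metrics")
}

#' @export
print.ddi_metrics <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.4f | macro P %.4f R %.4f F1 %.4f | ",
                     "macro AUROC %.4f AUPR %.4f  (n = %d, %d classes)\n"),
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
              x$macro_auroc, x$macro_aupr, x$n, length(x$classes_evaluated)))
  invisible(x)
}

#' Per-class misclassification table and confusion matrix
#'
#' For each class: its test count and share of the test set, the number of
#' its samples predicted as some other class, and that number as a
#' percentage of *all* misclassified samples (so the column sums to 100
#' whenever any errors exist).  Rows are ranked by descending
#' misclassification share, matching the "most misclassified types" view.
#'
#' @param y_true,y_pred aligned 0-based integer label vectors.
#' @param catalog optional class catalog (data.frame with `class_id`,
#'   `description`) fixing the class universe and adding descriptions.
#' @return object of class `ddi_confusion_summary`: list with `confusion`
#'   (counts matrix, rows = true), ranked `table` (class_id, description,
#'   test_count, test_ratio_pct, miscls_count, miscls_ratio_pct),
#'   `total` and `total_misclassified`.
#' @export
misclassification_table <- function(y_true, y_pred, catalog = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  classes <- if (!is.null(catalog)) sort(catalog$class_id)
             else sort(unique(c(y_true, y_pred)))
  lv <- as.character(classes)
  conf <- table(factor(y_true, levels = lv), factor(y_pred, levels = lv))
  conf <- unclass(conf)
  names(dimnames(conf)) <- c("true", "predicted")
  test_count <- rowSums(conf)
  total <- sum(test_count)
  miscls <- test_count - diag(conf)
  total_mis <- sum(miscls)
  if (total_mis == 0)
    message("no misclassified samples; misclassification ratios are 0")
  tab <- data.frame(
    class_id = classes,
    description = if (!is.null(catalog))
      catalog$description[match(classes, catalog$class_id)] else NA_character_,
    test_count = as.integer(test_count),
    test_ratio_pct = 100 * test_count / total,
    miscls_count = as.integer(miscls),
    miscls_ratio_pct = if (total_mis > 0) 100 * miscls / total_mis else
      rep(0, length(classes)),
    row.names = NULL)
  tab <- tab[order(-tab$miscls_ratio_pct, -tab$miscls_count, tab$class_id), ]
  rownames(tab) <- NULL
  structure(list(confusion = conf, table = tab, total = total,
                 total_misclassified = total_mis),
            class = "ddi_confusion_summary")
}

#' Normalized error heatmap over the most-misclassified classes
#'
#' Restricts the confusion matrix to the `top_k` classes by
#' misclassification share and divides each off-diagonal cell by the total
#' number of misclassified samples, so each cell is the proportion of all
#' errors flowing from the row's true class to the column's predicted
#' class.  Diagonal cells (correct predictions) are masked as `NA`.
#'
#' @param summary a [misclassification_table()] result.
#' @param top_k number of classes to keep (default 10).
#' @return top_k x top_k numeric matrix with class ids as dimnames.
#' @export
error_heatmap <- function(summary, top_k = 10) {
  stopifnot(inherits(summary, "ddi_confusion_summary"))
  if (top_k > nrow(summary$confusion))
    stop("top_k exceeds the number of classes")
  top <- as.character(summary$table$class_id[seq_len(top_k)])
  H <- summary$confusion[top, top, drop = FALSE]
  H <- if (summary$total_misclassified > 0)
    H / summary$total_misclassified else H * 0
  diag(H) <- NA_real_
  H
}

#' Plot an error heatmap
#'
#' Thin wrapper around `pheatmap` (masked diagonal shown as blank); only
#' available when the pheatmap package is installed.
#'
#' @param heatmap matrix from [error_heatmap()].
#' @param filename optional output file (PNG/PDF per extension).
#' @return the pheatmap object, invisibly.
#' @export
plot_error_heatmap <- function(heatmap, filename = NA) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_error_heatmap needs the pheatmap package")
  m <- heatmap
  m[is.na(m)] <- 0
  invisible(pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                               display_numbers = TRUE, filename = filename))
}
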