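#' One-vs-rest confusion tallies
#'
#' For every class `c`, counts TP (true `c` predicted `c`), FP (other
#' predicted `c`), FN (true `c` predicted other) and TN, plus the class
#' support.  `TP + FP + FN + TN = n` for every class.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param classes Class universe (default: union of observed labels).
#' @return An object of class `confusion_tally`: a data.frame with one row per
#'   class and columns `class`, `tp`, `fp`, `fn`, `tn`, `support`.
#' @export
confusion_tally <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  if (!all(y_pred %in% classes)) {
    stop("label mismatch: predicted label outside the class list", call. = FALSE)
  }
  n <- length(y_true)
  rows <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn,
               support = sum(y_true == cl))
  })
  structure(do.call(rbind, rows), class = c("confusion_tally", "data.frame"))
}

safe_ratio <- function(num, den) ifelse(den == 0, 0, num / den)

#' Metric suite from confusion tallies
#'
#' Per class: `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `accuracy = (TP+TN)/n`, `F1 = 2PR/(P+R)`,
#' `specificity = TN/(TN+FP)`, `error_rate = 1 - accuracy`.  Weighted mode
#' averages per-class values with support weights; its overall accuracy is
#' plain correct/total (`sum(TP)/n`).  Zero-denominator metrics are reported
#' as 0 and flagged rather than NaN.
#'
#' @param tally A [confusion_tally()].
#' @param mode `"weighted"` (default) or `"per_class"`.
#' @return An object of class `metrics_report`: for `"per_class"` a data.frame
#'   of per-class metrics; for `"weighted"` a named list of aggregate metrics
#'   plus the per-class table.  Either carries a `degenerate` flag naming
#'   zero-denominator cells.
#' @export
metrics_from_tally <- function(tally, mode = c("weighted", "per_class")) {
  mode <- match.arg(mode)
  n <- tally$tp[1] + tally$fp[1] + tally$fn[1] + tally$tn[1]
  degenerate <- character(0)
  per <- data.frame(class = tally$class,
                    precision = safe_ratio(tally$tp, tally$tp + tally$fp),
                    recall = safe_ratio(tally$tp, tally$tp + tally$fn),
                    accuracy = (tally$tp + tally$tn) / n,
                    specificity = safe_ratio(tally$tn, tally$tn + tally$fp),
                    support = tally$support)
  pr <- per$precision + per$recall
  per$f1 <- ifelse(pr == 0, 0, 2 * per$precision * per$recall / pr)
  per$error_rate <- 1 - per$accuracy
  for (m in c("precision", "recall", "f1", "specificity")) {
    den <- switch(m,
                  precision = tally$tp + tally$fp,
                  recall = tally$tp + tally$fn,
                  f1 = pr,
                  specificity = tally$tn + tally$fp)
    bad <- which(den == 0)
    if (length(bad)) degenerate <- c(degenerate, paste(m, tally$class[bad], sep = ":"))
  }
  per <- per[, c("class", "precision", "recall", "accuracy", "f1", "specificity",
                 "error_rate", "support")]

  if (mode == "per_class") {
    out <- structure(list(per_class = per, mode = "per_class",
                          degenerate = degenerate),
                     class = "metrics_report")
    return(out)
  }
  wts <- per$support / sum(per$support)
  overall_acc <- sum(tally$tp) / n
  out <- list(accuracy = overall_acc,
              precision = sum(wts * per$precision),
              recall = sum(wts * per$recall),
              f1 = sum(wts * per$f1),
              specificity = sum(wts * per$specificity),
              error_rate = 1 - overall_acc,
              per_class = per, mode = "weighted", degenerate = degenerate)
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  if (x$mode == "weighted") {
    cat(sprintf("<metrics_report (weighted): accuracy %.4f, precision %.4f, recall %.4f, f1 %.4f, specificity %.4f, error %.4f>\n",
                x$accuracy, x$precision, x$recall, x$f1, x$specificity, x$error_rate))
  } else {
    cat("<metrics_report (per class)>\n")
    print(x$per_class)
  }
  invisible(x)
}

#' One-vs-rest ROC AUC
#'
#' Per-class AUC via the rank (Mann-Whitney) statistic with half-credit for
#' ties, plus exportable (FPR, TPR) curve points.
#'
#' @param y_true Label vector.
#' @param scores Numeric matrix, one column per class (any monotone scores).
#' @return An object of class `roc_report`: list with `auc` (named numeric,
#'   `NA` + flag for classes absent from `y_true`) and `curves` (per-class
#'   data.frames of `fpr`, `tpr`).
#' @export
roc_auc_ovr <- function(y_true, scores) {
  y_true <- as.character(y_true)
  scores <- as.matrix(scores)
  classes <- colnames(scores)
  if (is.null(classes)) stop("score matrix needs class column names", call. = FALSE)
  auc <- stats::setNames(rep(NA_real_, length(classes)), classes)
  curves <- list()
  flagged <- character(0)
  for (cl in classes) {
    pos <- y_true == cl
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    if (n_pos == 0 || n_neg == 0) {
      flagged <- c(flagged, cl)
      next
    }
    s <- scores[, cl]
    r <- rank(s)  # average ranks give ties half credit
    auc[cl] <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    th <- c(Inf, sort(unique(s), decreasing = TRUE))
    curves[[cl]] <- data.frame(
      fpr = vapply(th, function(t) sum(s >= t & !pos) / n_neg, 0),
      tpr = vapply(th, function(t) sum(s >= t & pos) / n_pos, 0))
  }
  structure(list(auc = auc, curves = curves, undefined = flagged),
            class = "roc_report")
}

#' With/without-optimizer ANOVA comparison
#'
#' One-way ANOVA across the two groups of repeated accuracies (the
#' optimized-vs-unoptimized comparison protocol), via `stats::aov`.
#'
#' @param acc_without,acc_with Numeric vectors (length >= 2 each) of repeated
#'   accuracy measurements for the two arms.
#' @return List with `f`, `p`, `means` (named pair) and a `degenerate` flag
#'   (zero within-group variance with unequal means reports `p = 0`).
#' @export
compare_with_anova <- function(acc_without, acc_with) {
  stopifnot(length(acc_without) >= 2, length(acc_with) >= 2)
  df <- data.frame(acc = c(acc_without, acc_with),
                   group = factor(rep(c("without", "with"),
                                      c(length(acc_without), length(acc_with))),
                                  levels = c("without", "with")))
  m <- tapply(df$acc, df$group, mean)
  means <- stats::setNames(as.numeric(m), names(m))
  ssw <- sum(tapply(df$acc, df$group, function(v) sum((v - mean(v))^2)))
  degenerate <- FALSE
  if (ssw == 0 && means[1] != means[2]) {
    return(list(f = Inf, p = 0, means = means, degenerate = TRUE))
  }
  if (ssw == 0 && means[1] == means[2]) {
    return(list(f = 0, p = 1, means = means, degenerate = TRUE))
  }
  fit <- summary(stats::aov(acc ~ group, data = df))[[1]]
  list(f = fit[["F value"]][1], p = fit[["Pr(>F)"]][1], means = means,
       degenerate = degenerate)
}

#' Flatten a weighted metrics report to one CSV-ready row
#'
#' @param report A weighted [metrics_from_tally()] report.
#' @param ... Named leading identifier columns (e.g. model, optimizer, split).
#' @return A one-row data.frame.
#' @export
metrics_row <- function(report, ...) {
  stopifnot(report$mode == "weighted")
  cbind(data.frame(...),
        data.frame(accuracy = report$accuracy, precision = report$precision,
                   recall = report$recall, f1 = report$f1,
                   specificity = report$specificity,
                   error_rate = report$error_rate))
}
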