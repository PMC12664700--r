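#' Build a multi-class confusion matrix
#'
#' Tallies truth/prediction label pairs over a shared id set into a square
#' matrix with rows indexed by truth and columns by prediction, both in
#' the supplied label order (typically the registry plus `"non-Nif"`).
#' Row sums therefore equal the truth label frequencies.
#'
#' @param truth,predictions Named character vectors (id -> label) over
#'   identical id sets.
#' @param labels Ordered label set covering every label that occurs.
#' @return Integer matrix of class `multiclass_confusion`.
#' @export
build_confusion <- function(truth, predictions, labels) {
  if (is.null(names(truth)) || is.null(names(predictions))) {
    stop("truth and predictions must be named by sequence id")
  }
  if (!setequal(names(truth), names(predictions)) ||
      length(truth) != length(predictions)) {
    stop("truth and predictions must cover identical id sets")
  }
  predictions <- predictions[names(truth)]
  bad <- setdiff(unique(c(truth, predictions)), labels)
  if (length(bad) > 0L) {
    stop("label(s) outside the label set: ", paste(bad, collapse = ", "))
  }
  counts <- table(
    factor(unname(truth), levels = labels),
    factor(unname(predictions), levels = labels)
  )
  M <- matrix(as.integer(counts), nrow = length(labels),
              dimnames = list(truth = labels, prediction = labels))
  class(M) <- c("multiclass_confusion", class(M))
  M
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' Reduces the multi-class confusion to one binary problem per class
#' (TP = diagonal entry; FN = rest of the row; FP = rest of the column;
#' TN = everything else) and applies the standard formulas. Zero
#' denominators yield 0 with the affected metric named in `undefined`.
#' Classes absent from both truth and predictions are marked
#' `evaluated = FALSE` so summaries can exclude them.
#'
#' @param confusion A `multiclass_confusion`.
#' @return Data frame with one row per class: counts, `accuracy`,
#'   `sensitivity`, `precision`, `f1`, `undefined` (comma-separated) and
#'   `evaluated`.
#' @export
per_class_metrics <- function(confusion) {
  M <- unclass(confusion)
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  labels <- rownames(M)
  total <- sum(M)
  rows <- lapply(seq_along(labels), function(i) {
    tp <- M[i, i]
    fn <- sum(M[i, ]) - tp
    fp <- sum(M[, i]) - tp
    tn <- total - tp - fn - fp
    m <- metrics_from_counts(tp, fp, tn, fn)
    data.frame(
      class = labels[i],
      tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
      accuracy = m$accuracy, sensitivity = m$sensitivity,
      precision = m$precision, f1 = m$f1,
      undefined = paste(m$undefined, collapse = ","),
      evaluated = (sum(M[i, ]) + sum(M[, i])) > 0,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Correlation between annotated and predicted class counts
#'
#' The class correlation coefficient: the Pearson correlation between the
#' per-class sequence counts of an annotation and of the predictions,
#' summarizing how well the predicted class composition tracks the
#' annotated one across a dataset. It is symmetric in its arguments and
#' invariant to common positive scaling of either vector. A constant
#' count vector leaves the coefficient undefined; `NA` is returned with a
#' warning.
#'
#' @param truth_counts,predicted_counts Non-negative numeric vectors of
#'   equal length (>= 2), same class order.
#' @return A single correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
class_correlation <- function(truth_counts, predicted_counts) {
  stopifnot(is.numeric(truth_counts), is.numeric(predicted_counts))
  if (length(truth_counts) != length(predicted_counts)) {
    stop("count vectors must have the same length and class order")
  }
  if (length(truth_counts) < 2L) stop("need counts for at least 2 classes")
  if (stats::sd(truth_counts) == 0 || stats::sd(predicted_counts) == 0) {
    warning("class correlation undefined for a constant count vector",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(truth_counts, predicted_counts, method = "pearson")
}

#' Summarize multi-class performance
#'
#' Per-class one-vs-rest metrics plus unweighted (macro) means over the
#' evaluated classes, micro-averaged metrics pooled over all confusion
#' counts, and the class correlation between the truth and prediction
#' marginals. Classes named in `exclude` (e.g. `"non-Nif"` when only the
#' Nif classes should drive the summary) are dropped from the macro and
#' micro aggregation but kept in the per-class table.
#'
#' @param confusion A `multiclass_confusion`.
#' @param exclude Labels excluded from aggregation (default none).
#' @return An object of class `evaluation_summary`: list with `per_class`
#'   (data frame), `macro` (named numeric), `micro` (named numeric) and
#'   `class_correlation`.
#' @export
evaluation_summary <- function(confusion, exclude = character(0)) {
  pc <- per_class_metrics(confusion)
  keep <- pc$evaluated & !(pc$class %in% exclude)
  if (!any(keep)) stop("no evaluated class left after exclusion")
  agg <- pc[keep, , drop = FALSE]
  macro <- c(
    accuracy = mean(agg$accuracy),
    sensitivity = mean(agg$sensitivity),
    precision = mean(agg$precision),
    f1 = mean(agg$f1)
  )
  mm <- metrics_from_counts(sum(agg$tp), sum(agg$fp), sum(agg$tn), sum(agg$fn))
  micro <- c(accuracy = mm$accuracy, sensitivity = mm$sensitivity,
             precision = mm$precision, f1 = mm$f1)
  M <- unclass(confusion)
  keep_lab <- setdiff(rownames(M)[rowSums(M) + colSums(M) > 0], exclude)
  cc <- if (length(keep_lab) >= 2L) {
    suppressWarnings(class_correlation(rowSums(M)[keep_lab],
                                       colSums(M)[keep_lab]))
  } else {
    NA_real_
  }
  structure(
    list(per_class = pc, macro = macro, micro = micro,
         class_correlation = cc, excluded = exclude),
    class = "evaluation_summary"
  )
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("Evaluation summary over", sum(x$per_class$evaluated), "evaluated classes",
      if (length(x$excluded) > 0L) {
        paste0("(aggregates exclude ", paste(x$excluded, collapse = ", "), ")")
      } else "", "\n")
  cat(sprintf("  macro: acc=%.4f sens=%.4f prec=%.4f F1=%.4f\n",
              x$macro["accuracy"], x$macro["sensitivity"],
              x$macro["precision"], x$macro["f1"]))
  cat(sprintf("  micro: acc=%.4f sens=%.4f prec=%.4f F1=%.4f\n",
              x$micro["accuracy"], x$micro["sensitivity"],
              x$micro["precision"], x$micro["f1"]))
  cat(sprintf("  class correlation: %s\n",
              if (is.na(x$class_correlation)) "undefined"
              else sprintf("%.4f", x$class_correlation)))
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes the per-class metrics table, a summary block (macro, micro,
#' class correlation) and the labeled confusion matrix as delimited text.
#'
#' @param summary An `evaluation_summary`.
#' @param confusion The `multiclass_confusion` it came from.
#' @param prefix Output path prefix; writes `<prefix>.metrics.tsv`,
#'   `<prefix>.summary.tsv`, `<prefix>.confusion.tsv`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_evaluation <- function(summary, confusion, prefix) {
  stopifnot(inherits(summary, "evaluation_summary"),
            inherits(confusion, "multiclass_confusion"))
  metrics_path <- paste0(prefix, ".metrics.tsv")
  summary_path <- paste0(prefix, ".summary.tsv")
  confusion_path <- paste0(prefix, ".confusion.tsv")
  utils::write.table(summary$per_class, metrics_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sm <- data.frame(
    statistic = c(paste0("macro_", names(summary$macro)),
                  paste0("micro_", names(summary$micro)),
                  "class_correlation"),
    value = c(unname(summary$macro), unname(summary$micro),
              summary$class_correlation)
  )
  utils::write.table(sm, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  M <- unclass(confusion)
  utils::write.table(cbind(truth = rownames(M), as.data.frame(M)),
                     confusion_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(metrics = metrics_path, summary = summary_path,
              confusion = confusion_path))
}
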