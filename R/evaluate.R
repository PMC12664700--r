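#' Evaluate a binary classifier on held-out vectors
#'
#' Scores the test partitions, thresholds at `threshold` (score >=
#' threshold predicts the class) and reports the confusion counts together
#' with accuracy, sensitivity (TP/(TP+FN)), precision (TP/(TP+FP)) and F1
#' (their harmonic mean). Ratios with a zero denominator are reported as 0
#' and listed in the report's `undefined` flag, so comparisons stay
#' well-defined on degenerate test sets. All metrics are exactly
#' recomputable from the stored counts.
#'
#' @param model An `mlp_model` or `rbf_model`.
#' @param test_pos,test_neg Numeric matrices of held-out vectors.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `training_report`: list with `architecture`,
#'   `seed`, `threshold`, counts `tp`/`fp`/`tn`/`fn`, metrics `accuracy`/
#'   `sensitivity`/`precision`/`f1` and the `undefined` flag.
#' @export
evaluate_model <- function(model, test_pos, test_neg, threshold = 0.5) {
  test_pos <- as.matrix(test_pos); test_neg <- as.matrix(test_neg)
  if (nrow(test_pos) == 0L || nrow(test_neg) == 0L) {
    stop("both test partitions must be non-empty")
  }
  sp <- score_model(model, test_pos)
  sn <- score_model(model, test_neg)
  m <- metrics_from_counts(
    tp = sum(sp >= threshold), fn = sum(sp < threshold),
    fp = sum(sn >= threshold), tn = sum(sn < threshold)
  )
  structure(
    c(list(architecture = model$architecture,
           seed = model$seed,
           threshold = threshold),
      m),
    class = "training_report"
  )
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf(
    "%s  TP=%d FP=%d TN=%d FN=%d  acc=%.4f sens=%.4f prec=%.4f F1=%.4f%s\n",
    toupper(x$architecture), x$tp, x$fp, x$tn, x$fn,
    x$accuracy, x$sensitivity, x$precision, x$f1,
    if (length(x$undefined) > 0L) {
      paste0("  [undefined->0: ", paste(x$undefined, collapse = ","), "]")
    } else ""
  ))
  invisible(x)
}

#' Select the best candidate model for a class
#'
#' Deterministic model selection over `(model, report)` candidates: the
#' highest F1 score wins; equal F1 is broken by the higher accuracy; any
#' remaining tie falls back to a fixed architecture order (MLP before RBF)
#' and finally to candidate position, so the choice never depends on
#' floating-point noise or list ordering beyond these documented rules.
#'
#' @param candidates Non-empty list, each element a list with `model` and
#'   `report` (a `training_report`).
#' @return The winning element (list with `model` and `report`).
#' @export
select_best <- function(candidates) {
  if (!is.list(candidates) || length(candidates) == 0L) {
    stop("select_best needs at least one candidate")
  }
  ok <- vapply(candidates, function(cand) {
    is.list(cand) && !is.null(cand$model) && inherits(cand$report, "training_report")
  }, logical(1))
  if (!all(ok)) stop("each candidate must be a list(model=, report=)")
  f1 <- vapply(candidates, function(cand) cand$report$f1, numeric(1))
  acc <- vapply(candidates, function(cand) cand$report$accuracy, numeric(1))
  arch <- vapply(candidates, function(cand) cand$report$architecture, character(1))
  arch_rank <- match(arch, c("mlp", "rbf"), nomatch = 3L)
  best <- order(-f1, -acc, arch_rank, seq_along(candidates))[1L]
  candidates[[best]]
}
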