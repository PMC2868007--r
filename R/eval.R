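# Evaluation harness: majority-class baseline (MAV) and leave-one-out
# nearest-neighbour classification over binary contexts.

# Truncate (floor) to d decimals; printed-precision comparisons in this
# package truncate rather than round.
trunc_dec <- function(x, d) floor(x * 10^d) / 10^d

#' Minimum accepted value (majority-class baseline accuracy)
#'
#' The accuracy obtained by assigning every sequence of a dataset to its
#' biggest class: `100 * max(class size) / n`, truncated to one decimal.
#' Any useful classifier must beat this floor.
#'
#' @param labels Character vector of class labels (one per instance).
#' @return Percentage in (0, 100].
#' @examples
#' mav(rep(c("a", "b"), c(14, 26)))  # 65
#' @export
mav <- function(labels) {
  stopifnot(length(labels) > 0L)
  trunc_dec(100 * max(table(labels)) / length(labels), 1L)
}

#' Leave-one-out nearest-neighbour evaluation of a binary context
#'
#' For each instance, predicts the class of its nearest neighbour among
#' all remaining instances and reports the rate of correctly classified
#' sequences. Deterministic: ties on distance resolve to the earliest
#' instance in input order, and repeated runs give identical reports.
#'
#' @param c A `binary_context` with >= 2 instances and >= 2 classes.
#' @param metric `"hamming"` (count of differing bits) or `"jaccard"`
#'   (1 - |intersection| / |union| over the 1-bits; all-zero pairs get
#'   distance 0).
#' @return An object of class `eval_report`: list with `accuracy`
#'   (percentage), `correct`, `total`, `predicted`, and `per_class` counts.
#' @export
loo_nn <- function(c, metric = c("hamming", "jaccard")) {
  stopifnot(inherits(c, "binary_context"))
  metric <- match.arg(metric)
  X <- c$data
  n <- nrow(X)
  if (n < 2L || length(unique(c$labels)) < 2L)
    stop("need >= 2 instances and >= 2 classes")
  if (all(X == 0L))
    warning("degenerate context: all features are zero everywhere")

  if (metric == "hamming") {
    # pairwise Hamming via cross-products of the 0/1 matrix
    G <- tcrossprod(X)
    ones <- rowSums(X)
    D <- outer(ones, ones, "+") - 2 * G
  } else {
    G <- tcrossprod(X)
    ones <- rowSums(X)
    un <- outer(ones, ones, "+") - G
    D <- ifelse(un == 0, 0, 1 - G / un)
  }
  diag(D) <- Inf
  nn <- apply(D, 1L, which.min)  # which.min takes the first minimum
  pred <- c$labels[nn]
  correct <- sum(pred == c$labels)
  per_class <- t(vapply(sort(unique(c$labels), method = "radix"),
                        function(cl) {
    idx <- c$labels == cl
    c(correct = sum(pred[idx] == cl), total = sum(idx))
  }, c(correct = 0, total = 0)))
  structure(list(accuracy = 100 * correct / n, correct = correct,
                 total = n, predicted = pred, per_class = per_class,
                 metric = metric),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Leave-one-out 1-NN (%s): %d/%d correct, accuracy %.1f%%\n",
              x$metric, x$correct, x$total, x$accuracy))
  for (cl in rownames(x$per_class))
    cat(sprintf("  %s: %d/%d\n", cl, x$per_class[cl, "correct"],
                x$per_class[cl, "total"]))
  invisible(x)
}

#' Render an evaluation report as TSV text
#' @param x An `eval_report`.
#' @param path Optional output path.
#' @return TSV text, invisibly.
#' @export
report_tsv <- function(x, path = NULL) {
  stopifnot(inherits(x, "eval_report"))
  lines <- c("class\tcorrect\ttotal",
             paste(rownames(x$per_class), x$per_class[, "correct"],
                   x$per_class[, "total"], sep = "\t"),
             paste("overall", x$correct, x$total, sep = "\t"))
  if (!is.null(path)) writeLines(lines, path)
  invisible(paste(lines, collapse = "\n"))
}
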