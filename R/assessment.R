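#' Confusion matrix of a hard classification
#'
#' Counts of (predicted, reference) label pairs; rows are predicted
#' classes, columns are reference classes, in the fixed order intact,
#' logged, burned.
#'
#' @param predicted,reference equal-length character vectors of class
#'   labels.
#' @return 3 x 3 integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference))
  bad <- setdiff(unique(c(predicted, reference)), DCLASSES)
  if (length(bad))
    stop("labels outside the modeled classes: ", paste(bad, collapse = ", "))
  cm <- table(factor(predicted, levels = DCLASSES),
              factor(reference, levels = DCLASSES))
  cm <- unclass(matrix(as.integer(cm), 3L, 3L,
                       dimnames = list(predicted = DCLASSES,
                                       reference = DCLASSES)))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Coerce a plain count matrix to a confusion matrix
#'
#' @param m 3 x 3 nonnegative counts, rows predicted, columns reference,
#'   class order intact, logged, burned.
#' @return a `confusion_matrix`.
#' @export
as_confusion_matrix <- function(m) {
  m <- as.matrix(m)
  if (!identical(dim(m), c(3L, 3L)) || any(m < 0))
    stop("need a 3 x 3 nonnegative count matrix")
  if (sum(m) <= 0) stop("confusion matrix has no observations")
  dimnames(m) <- list(predicted = DCLASSES, reference = DCLASSES)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = predicted, cols = reference)\n")
  print(unclass(x))
  m <- accuracy_metrics(x)
  cat(sprintf("overall accuracy: %.4f\n", m$overall))
  invisible(x)
}

#' Map accuracy measures from a confusion matrix
#'
#' Overall accuracy is the proportion mapped correctly (trace / total);
#' user's accuracy per class is the fraction of cells mapped as the class
#' that truly are it (complement of commission error); producer's
#' accuracy is the fraction of reference cells of the class that are
#' mapped as it (complement of omission error).  Classes with an empty
#' row or column yield `NaN`.
#'
#' @param cm a `confusion_matrix` (or coercible 3 x 3 count matrix).
#' @return list with `overall`, `users` and `producers` (named per class).
#' @export
accuracy_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) cm <- as_confusion_matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has no observations")
  diagc <- diag(unclass(cm))
  list(overall = sum(diagc) / total,
       users = diagc / rowSums(cm),
       producers = diagc / colSums(cm))
}

#' Confidence interval on overall accuracy
#'
#' Normal-approximation binomial interval
#' \eqn{\hat p \pm z \sqrt{\hat p (1-\hat p)/n}} on the overall accuracy,
#' clipped to [0, 1].
#'
#' @param cm a `confusion_matrix`.
#' @param level confidence level (default 0.95).
#' @return numeric `(low, high)`.
#' @export
accuracy_ci <- function(cm, level = 0.95) {
  if (!inherits(cm, "confusion_matrix")) cm <- as_confusion_matrix(cm)
  n <- sum(cm)
  if (n <= 1) stop("need more than one observation for an interval")
  p <- sum(diag(unclass(cm))) / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(low = max(0, p - half), high = min(1, p + half))
}

#' Plain-text accuracy report
#'
#' Confusion matrix with per-class producer's and user's accuracy and the
#' overall accuracy with its confidence interval, laid out like a
#' standard map-accuracy table.
#'
#' @param cm a `confusion_matrix`.
#' @param level confidence level for the overall-accuracy interval.
#' @return the report lines, invisibly; printed as a side effect.
#' @export
accuracy_report <- function(cm, level = 0.95) {
  if (!inherits(cm, "confusion_matrix")) cm <- as_confusion_matrix(cm)
  m <- accuracy_metrics(cm)
  ci <- accuracy_ci(cm, level)
  lines <- c("Class accuracy (rows = predicted, cols = reference)",
             sprintf("%-10s %8s %8s %8s %10s %8s", "",
                     DCLASSES[1L], DCLASSES[2L], DCLASSES[3L],
                     "producer", "user"))
  for (i in seq_len(3L))
    lines <- c(lines,
               sprintf("%-10s %8d %8d %8d %10.2f %8.2f", DCLASSES[i],
                       cm[i, 1L], cm[i, 2L], cm[i, 3L],
                       m$producers[i], m$users[i]))
  lines <- c(lines,
             sprintf("overall accuracy %.2f (%d%% CI %.2f-%.2f), n = %d",
                     m$overall, round(100 * level), ci[1L], ci[2L],
                     sum(cm)))
  cat(lines, sep = "\n")
  invisible(lines)
}
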