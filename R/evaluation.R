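#' Confusion matrix and derived metrics
#'
#' Pooled accuracy (trace over total), and per class the recall (predicted
#' members of class x among true members of x) and miss rate (1 - recall);
#' the two always sum to one exactly.
#'
#' @param truth,pred equal-length label vectors (factors or characters).
#' @return list with `confusion` (true classes in rows, predictions in
#'   columns), `accuracy`, `recall`, `miss_rate` (the latter two named per
#'   class), `truth` and `pred`.
#' @export
confusion_and_metrics <- function(truth, pred) {
  if (length(truth) == 0) stop("empty input")
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  lev <- union(levels(as.factor(truth)), levels(as.factor(pred)))
  truth <- factor(truth, levels = lev)
  pred <- factor(pred, levels = lev)
  cm <- table(truth = truth, pred = pred)
  recall <- vapply(lev, function(cl) {
    n <- sum(cm[cl, ])
    if (n == 0) NA_real_ else cm[cl, cl] / n
  }, numeric(1))
  list(confusion = cm,
       accuracy = sum(diag(cm)) / sum(cm),
       recall = recall,
       miss_rate = 1 - recall,
       truth = truth, pred = pred)
}

#' Five-number boxplot summary with Tukey adjacents
#'
#' Median and quartiles by linear interpolation of order statistics, and the
#' lower/upper adjacent values: the most extreme observations within
#' 1.5 x IQR of the quartiles (the whisker convention).
#'
#' @param values numeric vector (at least one value).
#' @return list with `median`, `q1`, `q3`, `lower_adjacent`,
#'   `upper_adjacent`, `n`.
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty input")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  inside <- values[values >= q[1] - 1.5 * iqr & values <= q[3] + 1.5 * iqr]
  list(median = q[2], q1 = q[1], q3 = q[3],
       lower_adjacent = min(inside), upper_adjacent = max(inside),
       n = length(values))
}

#' Chance-level accuracy for uninformed guessing
#'
#' @param n_classes number of classes (>= 2).
#' @return `1 / n_classes`.
#' @export
#' @examples
#' chance_level(3) # 0.3333...
chance_level <- function(n_classes) {
  if (n_classes < 2) stop("need at least 2 classes")
  1 / n_classes
}

#' Extract per-run metric vectors from run results
#'
#' @param results a `run_results` list from [run_experiment()].
#' @param metric `"accuracy"`, `"miss_rate"` or `"recall"`; the class-wise
#'   metrics are averaged over classes per run (macro).
#' @return numeric vector, one value per run.
#' @export
run_metric <- function(results, metric = c("accuracy", "miss_rate", "recall")) {
  metric <- match.arg(metric)
  vapply(results, function(r) {
    v <- r[[metric]]
    if (length(v) > 1) mean(v, na.rm = TRUE) else v
  }, numeric(1))
}

#' Summarize a resampled experiment
#'
#' Boxplot-style distribution summaries (median, quartiles, Tukey adjacents)
#' of accuracy, macro miss rate and macro recall over all runs.
#'
#' @param results a `run_results` list.
#' @return data.frame with one row per metric.
#' @export
experiment_summary <- function(results) {
  rows <- lapply(c("accuracy", "miss_rate", "recall"), function(m) {
    b <- boxplot_stats(run_metric(results, m))
    data.frame(metric = m, median = b$median, q1 = b$q1, q3 = b$q3,
               lower_adjacent = b$lower_adjacent,
               upper_adjacent = b$upper_adjacent, n_runs = b$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pooled confusion matrix over runs
#' @param results a `run_results` list.
#' @return an integer matrix summing the per-run confusion matrices.
#' @export
pooled_confusion <- function(results) {
  Reduce(`+`, lapply(results, function(r) unclass(r$confusion)))
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> accuracy %.3f on %d eval trials\n",
              x$accuracy, x$n_eval))
  print(x$confusion)
  invisible(x)
}

#' Boxplot of per-run accuracies
#'
#' @param x a `run_results` list.
#' @param metric which metric to plot.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.run_results <- function(x, metric = "accuracy", ...) {
  graphics::boxplot(run_metric(x, metric),
                    ylab = metric, range = 1.5, ...)
  graphics::abline(h = chance_level(length(x[[1]]$recall)), lty = 2)
  invisible(x)
}
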