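# MTLBin baseline: median-binarize every continuous outcome so the task set
# becomes pure multi-task classification, then reuse the standard machinery.

#' Median-binarize a continuous outcome
#'
#' Labels +1 where `y > median(y)` and -1 where `y <= median(y)` (ties at the
#' median go to the negative class). This is the information-discarding step
#' of the MTLBin baseline: downstream fitting never sees the continuous
#' values, only the split.
#'
#' @param y Continuous outcome, length >= 2, non-constant.
#' @param name Task label recorded alongside the threshold.
#' @return A list: `labels` (-1/+1 vector), `record` (task name, median
#'   threshold, class counts).
#' @examples
#' binarize_median(c(1, 2, 2, 3))$labels # -1 -1 -1 +1
#' @export
binarize_median <- function(y, name = "task") {
  stopifnot(length(y) >= 2)
  m <- stats::median(y)
  labels <- ifelse(y > m, 1, -1)
  if (length(unique(labels)) < 2L)
    stop("degenerate outcome in task '", name,
         "': median binarization leaves a single class")
  list(labels = labels,
       record = list(task = name, threshold = m,
                     n_positive = sum(labels > 0), n_negative = sum(labels < 0)))
}

#' Convert a mixed task set to the all-classification MTLBin form
#'
#' Every regression task's outcome is median-binarized ([binarize_median]);
#' classification tasks pass through unchanged. The result has `c = t` and is
#' fitted with the ordinary machinery (the classification loss weight is kept
#' at its default so lambda scales remain comparable; with a single loss type
#' the relative balance is unaffected).
#'
#' @param ts A [mixed_task_set].
#' @return A list: `ts` (the all-classification [mixed_task_set], task order
#'   preserved by name), `records` (one binarization record per converted
#'   task).
#' @export
as_mtlbin <- function(ts) {
  stopifnot(inherits(ts, "mixed_task_set"))
  records <- list()
  tasks <- lapply(ts$tasks, function(tk) {
    if (tk$type == "regression") {
      bz <- binarize_median(tk$y, tk$name)
      records[[tk$name]] <<- bz$record
      task_data(tk$X, bz$labels, "classification", name = tk$name,
                feature_names = tk$feature_names)
    } else tk
  })
  list(ts = mixed_task_set(tasks), records = records)
}

#' Fit the MTLBin baseline at one lambda
#'
#' @param ts A [mixed_task_set]; regression tasks are median-binarized first.
#' @param lambda Sparsity strength (defaults to `control$lambda`).
#' @param control An [mtl_control].
#' @return An `mtlcomb` fit on the converted task set, with the binarization
#'   `records` attached.
#' @export
fit_mtlbin <- function(ts, lambda = NULL, control = mtl_control()) {
  conv <- as_mtlbin(ts)
  fit <- mtlcomb(conv$ts, lambda = lambda, control = control)
  fit$binarization <- conv$records
  fit
}

#' Cross-validated MTLBin
#'
#' @inheritParams cv_mtlcomb
#' @return A `cv_mtlcomb` object fitted on the median-binarized task set,
#'   with the binarization `records` attached.
#' @export
cv_mtlbin <- function(ts, control = mtl_control(), n_folds = 10L, seed = 1L,
                      one_se = FALSE) {
  conv <- as_mtlbin(ts)
  cv <- cv_mtlcomb(conv$ts, control, n_folds = n_folds, seed = seed,
                   one_se = one_se)
  cv$binarization <- conv$records
  cv
}
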