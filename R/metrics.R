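# Evaluation and interpretability metrics: AUC, (pseudo-)explained variance,
# ground-truth feature recovery, and cross-model reproducibility measures.

#' Area under the ROC curve
#'
#' Mann-Whitney convention: the probability that a uniformly drawn positive
#' outscores a uniformly drawn negative, with ties counted one half. Computed
#' from mid-ranks, so it is invariant under any strictly increasing transform
#' of the scores.
#'
#' @param y Labels in \{-1, +1\} (or any coding accepted by [task_data]).
#' @param scores Real-valued scores, higher meaning more positive.
#' @return Scalar in \[0, 1\].
#' @examples
#' auc(c(1, 1, -1, -1), c(0.9, 0.4, 0.6, 0.1)) # 0.75
#' @export
auc <- function(y, scores) {
  y <- recode_labels(y)
  stopifnot(length(y) == length(scores))
  npos <- sum(y > 0); nneg <- sum(y < 0)
  if (npos == 0L || nneg == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[y > 0]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Explained variance of a continuous prediction
#'
#' `1 - SS_res / SS_tot`; 1 for a perfect fit, 0 for predicting the mean,
#' negative when worse than the mean.
#'
#' @param y Observed values (non-constant, length >= 2).
#' @param yhat Predicted values.
#' @return Scalar <= 1.
#' @export
explained_variance <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("explained variance undefined for constant y")
  1 - sum((y - yhat)^2) / sst
}

#' Pseudo-explained variance for binary outcomes
#'
#' Squared Pearson correlation between the (linear) scores and the 0/1-coded
#' labels — the binary-task stand-in for explained variance used when
#' classification and regression tasks are reported on one scale. Constant
#' scores return 0 by convention.
#'
#' @inheritParams auc
#' @return Scalar in \[0, 1\].
#' @export
pseudo_explained_variance <- function(y, scores) {
  y <- recode_labels(y)
  stopifnot(length(y) == length(scores))
  if (stats::sd(scores) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(scores, (y + 1) / 2)^2
}

# Squared correlation of a score with a continuous outcome; used when the
# score is on an arbitrary (z) scale so residual-based explained variance
# does not apply.
pseudo_r2_continuous <- function(y, scores) {
  if (stats::sd(scores) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(scores, y)^2
}

#' Ground-truth feature recovery rate
#'
#' With `k = |true_support|`, the fraction of the true support found among
#' the model's top-`k` features ranked by coefficient row norm. Invariant to
#' positive rescaling of `W`. Precision and recall of the exact selected
#' support (nonzero rows) are attached as attributes for transparency.
#'
#' @param W Coefficient matrix (features x tasks) or an `mtlcomb` fit.
#' @param true_support Integer indices of the ground-truth features.
#' @return Scalar in \[0, 1\] with attributes `precision` and `recall`.
#' @export
feature_recovery <- function(W, true_support) {
  if (inherits(W, "mtlcomb")) W <- W$W
  W <- as.matrix(W)
  k <- length(true_support)
  stopifnot(k >= 1, k <= nrow(W))
  rn <- row_norms(W)
  sel <- which(rn > 0)
  prec <- if (length(sel)) mean(sel %in% true_support) else NA_real_
  rec <- mean(true_support %in% sel)
  if (all(rn == 0)) {
    warning("all-zero coefficient matrix: recovery is 0")
    return(structure(0, precision = prec, recall = rec))
  }
  topk <- order(rn, decreasing = TRUE)[seq_len(k)]
  structure(sum(topk %in% true_support) / k, precision = prec, recall = rec)
}

#' Top-k feature overlap between two models
#'
#' Counts the features shared by the two models' top-`k` lists ranked by
#' coefficient row norm — the reproducibility count reported when the same
#' model is trained on independent cohorts.
#'
#' @param W_a,W_b Coefficient matrices over the same feature space (or
#'   `mtlcomb` fits).
#' @param k List length (default 10).
#' @return Integer in \[0, k\].
#' @export
top_k_overlap <- function(W_a, W_b, k = 10) {
  if (inherits(W_a, "mtlcomb")) W_a <- W_a$W
  if (inherits(W_b, "mtlcomb")) W_b <- W_b$W
  stopifnot(nrow(W_a) == nrow(W_b))
  if (k > nrow(W_a)) stop("k exceeds the number of features")
  top <- function(W) order(row_norms(as.matrix(W)), decreasing = TRUE)[seq_len(k)]
  length(intersect(top(W_a), top(W_b)))
}

#' Cross-model coefficient similarity
#'
#' Pearson correlation of the flattened coefficient matrices of two models
#' fitted on the same feature/task layout (e.g. independent cohorts); 1 for
#' identical up to positive scaling.
#'
#' @inheritParams top_k_overlap
#' @return Scalar in \[-1, 1\].
#' @export
model_similarity <- function(W_a, W_b) {
  if (inherits(W_a, "mtlcomb")) W_a <- W_a$W
  if (inherits(W_b, "mtlcomb")) W_b <- W_b$W
  stopifnot(identical(dim(W_a), dim(W_b)))
  a <- as.numeric(W_a); b <- as.numeric(W_b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("model similarity undefined for a constant coefficient matrix")
  stats::cor(a, b)
}

#' Per-task evaluation report
#'
#' Scores a fitted model on (new) data: AUC for classification tasks,
#' explained variance for regression tasks, plus their means.
#'
#' @param fit An `mtlcomb` fit (or a plain coefficient matrix, in which case
#'   no standardization/intercepts are applied).
#' @param ts A [mixed_task_set] with the same feature space and task layout.
#' @return A list with a per-task data.frame `tasks` (`task`, `type`,
#'   `metric`, `value`) and aggregate means `mean_auc`, `mean_ev`.
#' @export
evaluate_model <- function(fit, ts) {
  stopifnot(inherits(ts, "mixed_task_set"))
  vals <- numeric(ts$t); metric <- character(ts$t)
  for (i in seq_len(ts$t)) {
    tk <- ts$tasks[[i]]
    s <- predict_task(fit, tk$X, i)
    if (tk$type == "classification") {
      metric[i] <- "auc"; vals[i] <- auc(tk$y, s)
    } else {
      metric[i] <- "explained_variance"; vals[i] <- explained_variance(tk$y, s)
    }
  }
  tasks <- data.frame(task = task_names(ts), type = task_types(ts),
                      metric = metric, value = vals)
  list(tasks = tasks,
       mean_auc = if (any(metric == "auc")) mean(vals[metric == "auc"]) else NA_real_,
       mean_ev = if (any(metric == "explained_variance"))
         mean(vals[metric == "explained_variance"]) else NA_real_)
}

#' Write a metric report
#'
#' Emits the flat key-value report as JSON and, alongside it, the per-task
#' table as TSV.
#'
#' @param report A list as returned by [evaluate_model()] (or any flat list
#'   of named numbers plus an optional `tasks` data.frame).
#' @param path Output JSON path; the TSV goes to the same path with
#'   extension `.tsv`.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  flat <- report[vapply(report, is.numeric, logical(1))]
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(report$tasks))
    utils::write.table(report$tasks, sub("\\.json$", ".tsv", path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
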