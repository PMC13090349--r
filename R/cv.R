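# Prediction and cross-validated lambda selection over the path.

# Linear score of task i on new data, applying the stored standardization.
predict_task <- function(fit, X, i) {
  X <- as.matrix(X)
  if (inherits(fit, "mtlcomb")) {
    if (ncol(X) != nrow(fit$W))
      stop("X has ", ncol(X), " columns, model expects ", nrow(fit$W))
    if (!is.null(fit$scaling)) {
      sc <- fit$scaling[[i]]
      X <- sweep(sweep(X, 2L, sc$center, "-"), 2L, sc$scale, "/")
    }
    drop(X %*% fit$W[, i]) + fit$intercepts[i]
  } else {
    W <- as.matrix(fit)
    if (ncol(X) != nrow(W))
      stop("X has ", ncol(X), " columns, model expects ", nrow(W))
    drop(X %*% W[, i])
  }
}

#' Predict from a fitted model
#'
#' Returns the linear score `X w^(i)` (plus the task intercept if fitted) for
#' one task; for classification tasks, `type = "response"` maps scores
#' through the logistic function to probabilities.
#'
#' @param object An `mtlcomb` fit.
#' @param X New data matrix over the same `p` features (original scale; the
#'   stored standardization is applied internally).
#' @param task Task index (column of `W`) or task name.
#' @param type `"link"` (linear score) or `"response"` (probability for
#'   classification tasks, identical to the score for regression tasks).
#' @param ... Unused.
#' @return Numeric vector of length `nrow(X)`.
#' @export
predict.mtlcomb <- function(object, X, task = 1L, type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.character(task)) {
    task <- match(task, object$task_names)
    if (is.na(task)) stop("unknown task name")
  }
  s <- predict_task(object, X, task)
  if (type == "response" && object$task_types[task] == "classification")
    s <- stats::plogis(s)
  s
}

# Per-task fold assignment: stratified over the two classes for
# classification, plain random folds for regression; sizes within a task
# differ by at most one. All draws come from the current RNG state.
assign_folds <- function(ts, n_folds) {
  lapply(ts$tasks, function(tk) {
    n <- length(tk$y)
    fold <- integer(n)
    if (tk$type == "classification") {
      pos <- which(tk$y > 0); neg <- which(tk$y < 0)
      for (idx in list(pos, neg)) {
        if (length(idx) < n_folds)
          stop("stratification error: task '", tk$name, "' has only ",
               length(idx), " samples of one class for ", n_folds, " folds")
      }
      # near-equal per-class splits aligned so total fold sizes differ by <= 1
      split_sizes <- function(m) tabulate(rep_len(seq_len(n_folds), m), n_folds)
      tot <- split_sizes(n)
      ps <- split_sizes(length(pos))
      ord <- sample(n_folds) # which folds carry the remainders
      tot_s <- sort(tot, decreasing = TRUE)[order(ord)]
      ps_s <- sort(ps, decreasing = TRUE)[order(ord)]
      ns_s <- tot_s - ps_s
      fold[pos] <- sample(rep(seq_len(n_folds), ps_s))
      fold[neg] <- sample(rep(seq_len(n_folds), ns_s))
    } else {
      fold <- sample(rep_len(seq_len(n_folds), n))
    }
    fold
  })
}

subset_task_set <- function(ts, keep) {
  tasks <- lapply(seq_len(ts$t), function(i) {
    tk <- ts$tasks[[i]]
    tk$X <- tk$X[keep[[i]], , drop = FALSE]
    tk$y <- tk$y[keep[[i]]]
    tk
  })
  mixed_task_set(tasks)
}

# Held-out weighted loss of one fitted model on held-out rows, task by task:
# the same 2 Z + 0.5 R weighting used for training.
heldout_loss <- function(fit, ts, ctl) {
  vapply(seq_len(ts$t), function(i) {
    tk <- ts$tasks[[i]]
    s <- predict_task(fit, tk$X, i)
    if (tk$type == "classification") {
      ctl$weight_class * mean(softplus(-tk$y * s))
    } else {
      ctl$weight_reg * mean((tk$y - s)^2)
    }
  }, numeric(1))
}

#' Cross-validated lambda selection
#'
#' Estimates the lambda sequence on the full data, then, per fold, refits the
#' warm-started path on the training portion (per-task folds, stratified for
#' classification tasks) and accumulates the held-out weighted loss
#' `w_c Z + w_r R` summed over tasks — the same weighting used for training,
#' so classification and regression tasks contribute on one scale. The
#' selected lambda minimises the mean CV loss; ties prefer the larger
#' (sparser) lambda. Optionally the one-standard-error rule picks the largest
#' lambda within one SE of the minimum. Deterministic given `seed`.
#'
#' @param ts A [mixed_task_set].
#' @param control An [mtl_control].
#' @param n_folds Number of folds (default 10). Every classification task
#'   needs at least `n_folds` members of each class.
#' @param seed Integer seed driving fold assignment.
#' @param one_se Use the one-standard-error rule for `lambda_best`
#'   (default `FALSE`).
#' @return An object of class `cv_mtlcomb`: `lambdas`, `cvm` (mean CV loss),
#'   `cvsd`, `per_task` (lambda x task matrix of mean held-out losses),
#'   `lambda_best`, `index_best`, `fold_ids`, `seed`, and `path` — the full
#'   regularization path fitted on all data, whose fit at `index_best` is the
#'   selected model (`best_fit()`).
#' @export
cv_mtlcomb <- function(ts, control = mtl_control(), n_folds = 10L, seed = 1L,
                       one_se = FALSE) {
  stopifnot(inherits(ts, "mixed_task_set"), n_folds >= 2)
  set.seed(seed)
  fold_ids <- assign_folds(ts, n_folds)
  path <- mtlcomb_path(ts, control)
  lambdas <- path$lambdas
  L <- length(lambdas)
  fold_loss <- matrix(NA_real_, n_folds, L)       # summed over tasks
  task_loss <- array(0, c(n_folds, L, ts$t))
  for (f in seq_len(n_folds)) {
    train <- lapply(fold_ids, function(id) which(id != f))
    test <- lapply(fold_ids, function(id) which(id == f))
    ts_tr <- subset_task_set(ts, train)
    ts_te <- subset_task_set(ts, test)
    p_tr <- mtlcomb_path(ts_tr, control, lambdas = lambdas)
    for (j in seq_len(L)) {
      pl <- heldout_loss(p_tr$fits[[j]], ts_te, control)
      task_loss[f, j, ] <- pl
      fold_loss[f, j] <- sum(pl)
    }
  }
  cvm <- colMeans(fold_loss)
  cvsd <- apply(fold_loss, 2L, stats::sd) / sqrt(n_folds)
  idx <- which.min(cvm) # lambdas descend, so the first minimum is the largest
  if (one_se) idx <- min(which(cvm <= cvm[idx] + cvsd[idx]))
  structure(
    list(lambdas = lambdas, cvm = cvm, cvsd = cvsd,
         per_task = apply(task_loss, c(2L, 3L), mean),
         lambda_best = lambdas[idx], index_best = idx,
         fold_ids = fold_ids, seed = seed, n_folds = n_folds, path = path),
    class = "cv_mtlcomb")
}

#' @export
print.cv_mtlcomb <- function(x, ...) {
  cat(sprintf("cv_mtlcomb: %d-fold CV over %d lambdas; lambda_best = %.4g (index %d), CV loss %.4g\n",
              x$n_folds, length(x$lambdas), x$lambda_best, x$index_best,
              x$cvm[x$index_best]))
  invisible(x)
}

#' Model at the CV-selected lambda
#'
#' @param cv A `cv_mtlcomb` object.
#' @return The `mtlcomb` fit at `lambda_best` from the full-data path.
#' @export
best_fit <- function(cv) {
  stopifnot(inherits(cv, "cv_mtlcomb"))
  cv$path$fits[[cv$index_best]]
}

#' Repeated nested cross-validation
#'
#' Outer folds hold out evaluation samples; on each outer training portion an
#' inner CV selects lambda, the selected model predicts the held-out samples,
#' and per-task metrics (AUC / explained variance) are computed on the pooled
#' out-of-fold predictions. The whole procedure is repeated with fresh fold
#' draws and the results averaged. A combined shared-marker score — the mean
#' of the per-task z-scored linear predictors — is also evaluated against
#' every task's outcome, reflecting the use of one marker set to predict all
#' outcomes.
#'
#' @param ts A [mixed_task_set].
#' @param control An [mtl_control].
#' @param outer_folds,inner_folds Fold counts (default 10 each).
#' @param repeats Number of repetitions (default 10).
#' @param seed Master seed; repetition r uses `seed + r`.
#' @return A list with `per_repeat` (data.frame of per-task metrics and
#'   combined-score metrics per repetition) and `means` (column means).
#' @export
nested_cv <- function(ts, control = mtl_control(), outer_folds = 10L,
                      inner_folds = 10L, repeats = 10L, seed = 1L) {
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    fold_ids <- assign_folds(ts, outer_folds)
    pred <- lapply(seq_len(ts$t), function(i) numeric(length(ts$tasks[[i]]$y)))
    for (f in seq_len(outer_folds)) {
      train <- lapply(fold_ids, function(id) which(id != f))
      test <- lapply(fold_ids, function(id) which(id == f))
      ts_tr <- subset_task_set(ts, train)
      cv <- cv_mtlcomb(ts_tr, control, n_folds = inner_folds,
                       seed = seed + 1000L * r + f)
      fit <- best_fit(cv)
      for (i in seq_len(ts$t))
        pred[[i]][test[[i]]] <- predict_task(fit, ts$tasks[[i]]$X[test[[i]], , drop = FALSE], i)
    }
    vals <- list(repeat_id = r)
    for (i in seq_len(ts$t)) {
      tk <- ts$tasks[[i]]
      nm <- tk$name
      if (tk$type == "classification") {
        vals[[paste0("auc_", nm)]] <- auc(tk$y, pred[[i]])
      } else {
        vals[[paste0("ev_", nm)]] <- explained_variance(tk$y, pred[[i]])
      }
    }
    # shared-marker combined score: when every task scores the same subjects
    # (one cohort, several outcomes), average the z-scored per-task
    # predictors and evaluate that single score against each outcome.
    ns <- lengths(pred)
    if (ts$t > 1L && length(unique(ns)) == 1L) {
      zs <- vapply(pred, function(s) {
        if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else s
      }, numeric(ns[1L]))
      combined <- rowMeans(zs)
      for (i in seq_len(ts$t)) {
        tk <- ts$tasks[[i]]
        nm <- tk$name
        if (tk$type == "classification") {
          vals[[paste0("auc_combined_", nm)]] <- auc(tk$y, combined)
        } else {
          vals[[paste0("ev_combined_", nm)]] <-
            pseudo_r2_continuous(tk$y, combined)
        }
      }
    }
    rows[[r]] <- as.data.frame(vals)
  }
  per_repeat <- do.call(rbind, rows)
  list(per_repeat = per_repeat,
       means = colMeans(per_repeat[, -1L, drop = FALSE]))
}
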