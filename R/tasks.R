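#' Bundle one task's design matrix and outcome
#'
#' A task is one cohort/outcome pair sharing the common feature space: a dense
#' numeric design matrix `X` (samples in rows, features in columns) and an
#' outcome vector `y`. Classification outcomes are recoded internally to the
#' -1/+1 convention used by the logistic loss; `{0, 1}` vectors, logicals,
#' two-level factors and two-valued character vectors are accepted, with the
#' larger (or alphabetically later) level mapped to +1.
#'
#' @param X Numeric matrix, `n` samples by `p` features; no missing values.
#' @param y Outcome vector of length `n`. Continuous for `type = "regression"`;
#'   two-valued for `type = "classification"`.
#' @param type `"regression"` or `"classification"`.
#' @param name Task label used in reports and error messages.
#' @param feature_names Feature labels; defaults to `colnames(X)` or `V1..Vp`.
#' @return An object of class `task_data`.
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' task_data(X, rnorm(10), "regression", name = "age")
#' task_data(X, rep(c(0, 1), 5), "classification", name = "dx")
#' @export
task_data <- function(X, y, type = c("regression", "classification"),
                      name = "task", feature_names = NULL) {
  type <- match.arg(type)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("task '", name, "': X contains missing values")
  if (nrow(X) < 2L) stop("task '", name, "': needs at least 2 samples")
  if (length(y) != nrow(X))
    stop("task '", name, "': length(y) != nrow(X)")
  if (is.null(feature_names)) feature_names <- colnames(X)
  if (is.null(feature_names)) feature_names <- paste0("V", seq_len(ncol(X)))
  if (length(feature_names) != ncol(X))
    stop("task '", name, "': feature_names length != ncol(X)")
  if (type == "classification") {
    y <- recode_labels(y, name)
  } else {
    y <- as.numeric(y)
    if (anyNA(y)) stop("task '", name, "': y contains missing values")
  }
  structure(
    list(name = name, type = type, X = unname(X), y = y,
         feature_names = as.character(feature_names)),
    class = "task_data")
}

# Map an arbitrary two-valued outcome onto {-1, +1}. Input already coded in
# {-1, +1} (or {0, 1}) passes through even if only one class is present;
# two-class presence is enforced where it matters (CV stratification, AUC).
recode_labels <- function(y, name = "task") {
  if (anyNA(y)) stop("task '", name, "': y contains missing values")
  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y)) y <- as.numeric(y)
  if (is.numeric(y) && all(y %in% c(-1, 1))) return(as.numeric(y))
  lev <- sort(unique(y))
  if (length(lev) != 2L)
    stop("task '", name, "': classification outcome must take exactly 2 values, got ",
         length(lev))
  ifelse(y == lev[2L], 1, -1)
}

#' @export
print.task_data <- function(x, ...) {
  cat(sprintf("task '%s' (%s): %d samples x %d features\n",
              x$name, x$type, nrow(x$X), ncol(x$X)))
  if (x$type == "classification")
    cat(sprintf("  classes: %d positive / %d negative\n",
                sum(x$y > 0), sum(x$y < 0)))
  invisible(x)
}

#' Task-centering operator for the mean-regularized penalty
#'
#' Returns the t x t centering matrix `I - (1/t) 11'`. It is symmetric and
#' idempotent with zero row sums, so `||W G||_F^2` measures the dispersion of
#' each feature's coefficients around their cross-task mean and vanishes
#' whenever a feature's coefficients are identical across tasks.
#'
#' @param t Number of tasks.
#' @return A t x t numeric matrix.
#' @export
centering_matrix <- function(t) {
  stopifnot(t >= 1)
  diag(t) - matrix(1 / t, t, t)
}

#' Assemble tasks sharing one feature space
#'
#' Orders classification tasks first (stable within type, as required by the
#' mixed objective's task indexing), verifies that all tasks share the same
#' features in the same order, and attaches the task-centering operator used
#' by the mean-regularized penalty.
#'
#' @param tasks List of [task_data] objects.
#' @return An object of class `mixed_task_set` with elements `tasks`, `c`
#'   (number of classification tasks), `t`, `p`, `feature_names`, `G`.
#' @examples
#' X <- matrix(rnorm(60), 15, 4)
#' ts <- mixed_task_set(list(
#'   task_data(X, rnorm(15), "regression", name = "r1"),
#'   task_data(X, sign(X[, 1]), "classification", name = "c1")))
#' ts
#' @export
mixed_task_set <- function(tasks) {
  if (!length(tasks)) stop("need at least one task")
  ok <- vapply(tasks, inherits, logical(1), "task_data")
  if (!all(ok)) stop("all elements must be task_data objects")
  types <- vapply(tasks, `[[`, character(1), "type")
  tasks <- c(tasks[types == "classification"], tasks[types == "regression"])
  p <- ncol(tasks[[1L]]$X)
  fn <- tasks[[1L]]$feature_names
  for (tk in tasks) {
    if (ncol(tk$X) != p)
      stop("task '", tk$name, "': has ", ncol(tk$X), " features, expected ", p)
    if (!identical(tk$feature_names, fn))
      stop("task '", tk$name, "': feature names differ from the first task")
  }
  nm <- vapply(tasks, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("task names must be unique")
  t <- length(tasks)
  structure(
    list(tasks = tasks, c = sum(types == "classification"), t = t, p = p,
         feature_names = fn, G = centering_matrix(t)),
    class = "mixed_task_set")
}

#' @export
print.mixed_task_set <- function(x, ...) {
  cat(sprintf("mixed_task_set: %d tasks (%d classification, %d regression), p = %d\n",
              x$t, x$c, x$t - x$c, x$p))
  for (tk in x$tasks)
    cat(sprintf("  %-12s %-14s n = %d\n", tk$name, tk$type, length(tk$y)))
  invisible(x)
}

task_names <- function(ts) vapply(ts$tasks, `[[`, character(1), "name")
task_types <- function(ts) vapply(ts$tasks, `[[`, character(1), "type")

#' Solver and penalty settings
#'
#' Collects the hyperparameters of the weighted mixed-loss objective
#' \deqn{w_c Z(W) + w_r R(W) + \lambda \|W\|_{2,1} + \alpha \|WG\|_F^2 +
#'   \beta \|W\|_F^2}
#' and of the accelerated proximal-gradient solver. The default loss weights
#' (2 on the logistic loss, 0.5 on the least-squares loss; ratio 4) equalise
#' the zero-point gradients of the two loss types so both share one lambda
#' scale; `alpha` and `beta` are user priors, `lambda` is typically chosen by
#' cross-validation over the path.
#'
#' @param lambda L2,1 sparsity strength (>= 0).
#' @param alpha Mean-regularization strength (>= 0): shrinks each feature's
#'   coefficients toward their cross-task mean.
#' @param beta Ridge strength (>= 0).
#' @param weight_class,weight_reg Loss weights; defaults 2 and 0.5.
#' @param n_lambda Path length (default 50).
#' @param lambda_ratio Smallest-to-largest lambda ratio in (0, 1); default 0.01.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Iteration cap per fit.
#' @param standardize Z-score each task's columns before fitting (default
#'   `TRUE`); coefficients are reported on the standardized scale, see
#'   [coef.mtlcomb()] for back-transformation. Standardization changes
#'   `lambda_max`, so the same setting must be used throughout an analysis.
#' @param intercept Fit an unpenalized per-task intercept (default `FALSE`,
#'   which reproduces the bare objective; recommended for imbalanced
#'   classification tasks).
#' @return An object of class `mtl_control`.
#' @export
mtl_control <- function(lambda = 0, alpha = 0, beta = 0,
                        weight_class = 2, weight_reg = 0.5,
                        n_lambda = 50L, lambda_ratio = 0.01,
                        tol = 1e-6, max_iter = 5000L,
                        standardize = TRUE, intercept = FALSE) {
  stopifnot(lambda >= 0, alpha >= 0, beta >= 0,
            weight_class >= 0, weight_reg >= 0,
            n_lambda >= 2, lambda_ratio > 0, lambda_ratio < 1,
            tol > 0, max_iter >= 1)
  structure(
    list(lambda = lambda, alpha = alpha, beta = beta,
         weight_class = weight_class, weight_reg = weight_reg,
         n_lambda = as.integer(n_lambda), lambda_ratio = lambda_ratio,
         tol = tol, max_iter = as.integer(max_iter),
         standardize = isTRUE(standardize), intercept = isTRUE(intercept)),
    class = "mtl_control")
}

# Per-task column z-scoring. Constant columns get sd 1 so they pass through
# centred but unscaled. Returns the standardized set plus the per-task
# centers/scales needed for prediction and back-transformation.
standardize_task_set <- function(ts) {
  scaling <- vector("list", ts$t)
  tasks <- ts$tasks
  for (i in seq_len(ts$t)) {
    X <- tasks[[i]]$X
    mu <- colMeans(X)
    sd <- apply(X, 2L, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    tasks[[i]]$X <- sweep(sweep(X, 2L, mu, "-"), 2L, sd, "/")
    scaling[[i]] <- list(center = mu, scale = sd)
  }
  out <- ts
  out$tasks <- tasks
  list(ts = out, scaling = scaling)
}

# Short data fingerprint recorded in path/model metadata so a serialized
# model can be matched to its training data.
fingerprint_task_set <- function(ts) {
  ns <- vapply(ts$tasks, function(tk) length(tk$y), integer(1))
  sums <- vapply(ts$tasks, function(tk) sum(tk$X) + sum(tk$y), numeric(1))
  sprintf("t%d-c%d-p%d-n%s-s%.6e", ts$t, ts$c, ts$p,
          paste(ns, collapse = "."), sum(sums))
}
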