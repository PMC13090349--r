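# Data-driven lambda sequence (lambda_max, log-scale interpolation) and
# warm-started fitting of the regularization path.

#' Smallest lambda with an all-zero solution
#'
#' Reads `lambda_max` off the zero-point gradient: `W = 0` is stationary for
#' the L2,1-penalized weighted loss exactly when every feature row of the
#' smooth gradient at zero has Euclidean norm at most lambda, so
#' `lambda_max = max_j ||g_(j)||_2` with `g = gradient_at_zero(ts)`. The
#' mean-regularized and ridge terms do not enter because their gradients
#' vanish at zero. Because the default loss weighting equalises the
#' zero-point gradients of the two loss types, this single value is
#' consistent across mixed losses. When `control$standardize` is `TRUE` the
#' gradient is taken on the z-scored features (the scale the path is fitted
#' on).
#'
#' @param ts A [mixed_task_set].
#' @param control An [mtl_control].
#' @return Positive scalar.
#' @export
lambda_max <- function(ts, control = mtl_control()) {
  if (control$standardize) ts <- standardize_task_set(ts)$ts
  g <- gradient_at_zero(ts, control)
  rn <- row_norms(g)
  lm <- max(rn)
  if (lm <= 1e-14)
    stop("degenerate input: zero gradient at W = 0 (no feature-outcome covariance)")
  lm
}

#' Geometric lambda sequence
#'
#' Interpolates `n` values from `lmax` down to `ratio * lmax` on the log
#' scale, both endpoints included, so adjacent values share a constant ratio.
#'
#' @param lmax Largest lambda (positive).
#' @param ratio Smallest-to-largest ratio, in (0, 1).
#' @param n Sequence length (>= 2).
#' @return Strictly descending numeric vector of length `n`.
#' @examples
#' lambda_sequence(1, 0.01, 3) # 1, 0.1, 0.01
#' @export
lambda_sequence <- function(lmax, ratio, n) {
  if (!is.finite(lmax) || lmax <= 0) stop("lmax must be positive")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  if (n < 2) stop("n must be at least 2")
  exp(seq(log(lmax), log(ratio * lmax), length.out = n))
}

#' Fit the full regularization path
#'
#' Estimates the lambda sequence from the data (`lambda_max`, then
#' `lambda_ratio * lambda_max`, then log-scale interpolation) and fits in
#' decreasing-lambda order with warm starts, so the first solution is the
#' all-zero model and each subsequent fit starts from its predecessor.
#'
#' @param ts A [mixed_task_set].
#' @param control An [mtl_control]; `n_lambda` and `lambda_ratio` shape the
#'   sequence.
#' @param lambdas Optional user-supplied descending sequence (overrides the
#'   data-driven estimate).
#' @return An object of class `mtlcomb_path`: `lambdas`, `fits` (list of
#'   `mtlcomb` solutions), `support_sizes`, `objectives`, and `meta`
#'   (control, standardization flag, data fingerprint).
#' @export
mtlcomb_path <- function(ts, control = mtl_control(), lambdas = NULL) {
  stopifnot(inherits(ts, "mixed_task_set"))
  scaling <- NULL
  if (control$standardize) {
    std <- standardize_task_set(ts)
    ts_fit <- std$ts
    scaling <- std$scaling
  } else ts_fit <- ts
  if (is.null(lambdas)) {
    ctl0 <- control
    ctl0$standardize <- FALSE # already standardized above
    lmax <- lambda_max(ts_fit, ctl0)
    lambdas <- lambda_sequence(lmax, control$lambda_ratio, control$n_lambda)
  } else {
    if (is.unsorted(rev(lambdas), strictly = TRUE))
      stop("lambdas must be strictly descending")
  }
  ctl <- control
  ctl$standardize <- FALSE
  fits <- vector("list", length(lambdas))
  W <- NULL; b <- NULL
  for (j in seq_along(lambdas)) {
    sol <- tryCatch(
      fista_solve(ts_fit, lambdas[j], ctl, W_init = W, b_init = b),
      error = function(e) stop("path fit failed at lambda index ", j,
                               " (lambda = ", signif(lambdas[j], 4), "): ",
                               conditionMessage(e)))
    sol$lambda <- lambdas[j]
    sol$scaling <- scaling
    sol$control <- control
    sol$feature_names <- ts$feature_names
    sol$task_names <- task_names(ts)
    sol$task_types <- task_types(ts)
    class(sol) <- "mtlcomb"
    fits[[j]] <- sol
    W <- sol$W; b <- sol$intercepts
  }
  structure(
    list(lambdas = lambdas, fits = fits,
         support_sizes = vapply(fits, function(f) length(f$support), integer(1)),
         objectives = vapply(fits, `[[`, numeric(1), "objective"),
         meta = list(control = control, standardized = control$standardize,
                     fingerprint = fingerprint_task_set(ts),
                     feature_names = ts$feature_names,
                     task_names = task_names(ts))),
    class = "mtlcomb_path")
}

#' @export
print.mtlcomb_path <- function(x, ...) {
  cat(sprintf("mtlcomb_path: %d lambdas in [%.4g, %.4g], support 0 -> %d features\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas),
              max(x$support_sizes)))
  invisible(x)
}

#' Long-format table of nonzero path coefficients
#'
#' One row per (lambda, feature, task) with a nonzero coefficient — the
#' export format for downstream inspection of how features enter the path.
#'
#' @param path An `mtlcomb_path`.
#' @return A data.frame with columns `lambda_index`, `lambda`, `feature`,
#'   `task`, `coefficient`.
#' @export
path_table <- function(path) {
  stopifnot(inherits(path, "mtlcomb_path"))
  rows <- list()
  for (j in seq_along(path$lambdas)) {
    W <- path$fits[[j]]$W
    nz <- which(W != 0, arr.ind = TRUE)
    if (nrow(nz)) {
      rows[[length(rows) + 1L]] <- data.frame(
        lambda_index = j, lambda = path$lambdas[j],
        feature = path$meta$feature_names[nz[, 1L]],
        task = path$meta$task_names[nz[, 2L]],
        coefficient = W[nz])
    }
  }
  if (!length(rows))
    return(data.frame(lambda_index = integer(), lambda = numeric(),
                      feature = character(), task = character(),
                      coefficient = numeric()))
  do.call(rbind, rows)
}

#' Per-lambda path summary
#'
#' @param path An `mtlcomb_path`.
#' @return A data.frame with columns `lambda`, `objective`, `support_size`,
#'   `n_iter`, `converged`.
#' @export
path_summary <- function(path) {
  stopifnot(inherits(path, "mtlcomb_path"))
  data.frame(lambda = path$lambdas,
             objective = path$objectives,
             support_size = path$support_sizes,
             n_iter = vapply(path$fits, `[[`, integer(1), "n_iter"),
             converged = vapply(path$fits, `[[`, logical(1), "converged"))
}

# Path index at which each feature first enters (NA if never selected).
first_entry_index <- function(path) {
  p <- length(path$meta$feature_names)
  entry <- rep(NA_integer_, p)
  for (j in seq_along(path$lambdas)) {
    sel <- path$fits[[j]]$support
    new <- sel[is.na(entry[sel])]
    entry[new] <- j
  }
  entry
}
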