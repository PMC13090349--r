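# Weighted mixed-loss objective, its smooth-part gradient, and the loss
# weighting that aligns the two loss types at the all-zero coefficients.

# Numerically stable softplus: log(1 + exp(z)) without overflow.
softplus <- function(z) {
  pmax(z, 0) + log1p(exp(-abs(z)))
}

#' Mean logistic loss of one classification task
#'
#' `(1/n) sum_i log(1 + exp(-y_i <x_i, w>))` with `y` in {-1, +1}, evaluated
#' through a stable softplus so large margins do not overflow.
#'
#' @param task A classification [task_data].
#' @param w Coefficient vector of length `p` (the task's column of `W`).
#' @param intercept Optional unpenalized intercept (default 0).
#' @return Nonnegative scalar.
#' @export
logit_loss <- function(task, w, intercept = 0) {
  stopifnot(inherits(task, "task_data"))
  if (task$type != "classification")
    stop("logit_loss expects a classification task, got '", task$type, "'")
  if (!all(task$y %in% c(-1, 1)))
    stop("classification outcomes must be coded -1/+1")
  eta <- drop(task$X %*% w) + intercept
  mean(softplus(-task$y * eta))
}

#' Mean squared-error loss of one regression task
#'
#' `(1/n) ||y - X w||_2^2`.
#'
#' @inheritParams logit_loss
#' @param task A regression [task_data].
#' @return Nonnegative scalar.
#' @export
least_squares_loss <- function(task, w, intercept = 0) {
  stopifnot(inherits(task, "task_data"))
  if (task$type != "regression")
    stop("least_squares_loss expects a regression task, got '", task$type, "'")
  r <- task$y - drop(task$X %*% w) - intercept
  mean(r^2)
}

check_W <- function(W, ts) {
  W <- as.matrix(W)
  if (nrow(W) != ts$p || ncol(W) != ts$t)
    stop("coefficient matrix must be ", ts$p, " x ", ts$t,
         ", got ", nrow(W), " x ", ncol(W))
  W
}

# Smooth part of the objective: weighted losses + mean-regularized + ridge
# penalties (everything except the L2,1 term).
smooth_value <- function(W, b, ts, ctl) {
  v <- 0
  for (i in seq_len(ts$t)) {
    tk <- ts$tasks[[i]]
    if (tk$type == "classification") {
      v <- v + ctl$weight_class * logit_loss(tk, W[, i], b[i])
    } else {
      v <- v + ctl$weight_reg * least_squares_loss(tk, W[, i], b[i])
    }
  }
  if (ctl$alpha > 0) v <- v + ctl$alpha * sum((W %*% ts$G)^2)
  if (ctl$beta > 0) v <- v + ctl$beta * sum(W^2)
  v
}

l21_norm <- function(W) sum(sqrt(rowSums(W^2)))

row_norms <- function(W) sqrt(rowSums(W^2))

# Gradient of the smooth part w.r.t. W (p x t) and the intercepts (length t).
smooth_grad <- function(W, b, ts, ctl) {
  GW <- matrix(0, ts$p, ts$t)
  gb <- numeric(ts$t)
  for (i in seq_len(ts$t)) {
    tk <- ts$tasks[[i]]
    n <- length(tk$y)
    eta <- drop(tk$X %*% W[, i]) + b[i]
    if (tk$type == "classification") {
      # d/d eta of softplus(-y eta) = -y * sigma(-y eta)
      u <- -tk$y * stats::plogis(-tk$y * eta)
      GW[, i] <- (ctl$weight_class / n) * drop(crossprod(tk$X, u))
      gb[i] <- (ctl$weight_class / n) * sum(u)
    } else {
      r <- eta - tk$y
      GW[, i] <- (ctl$weight_reg * 2 / n) * drop(crossprod(tk$X, r))
      gb[i] <- (ctl$weight_reg * 2 / n) * sum(r)
    }
  }
  if (ctl$alpha > 0) GW <- GW + 2 * ctl$alpha * (W %*% ts$G)
  if (ctl$beta > 0) GW <- GW + 2 * ctl$beta * W
  list(W = GW, b = gb)
}

#' Full weighted objective
#'
#' \deqn{w_c Z(W) + w_r R(W) + \lambda \sum_j \|w_{(j)}\|_2 +
#'   \alpha \|WG\|_F^2 + \beta \|W\|_F^2}
#' where `Z` sums the per-task mean logistic losses of the classification
#' tasks and `R` the per-task mean squared errors of the regression tasks.
#' All penalty terms vanish at `W = 0`.
#'
#' @param W Coefficient matrix, `p` rows (features) by `t` columns (tasks).
#' @param ts A [mixed_task_set].
#' @param control An [mtl_control] carrying the weights and penalties.
#' @param intercepts Optional length-`t` vector of unpenalized intercepts.
#' @return Nonnegative scalar.
#' @export
mtl_objective <- function(W, ts, control = mtl_control(), intercepts = NULL) {
  W <- check_W(W, ts)
  b <- if (is.null(intercepts)) numeric(ts$t) else intercepts
  smooth_value(W, b, ts, control) + control$lambda * l21_norm(W)
}

#' Gradient of the smooth objective part
#'
#' Gradient of `w_c Z + w_r R + alpha ||WG||_F^2 + beta ||W||_F^2` with
#' respect to `W` (the L2,1 term is handled by its proximal operator, not by
#' gradients). Per classification column: `(w_c/n) X' (-y * sigma(-y * X w))`;
#' per regression column: `(2 w_r/n) X' (X w - y)`; plus `2 alpha W G` and
#' `2 beta W`.
#'
#' @inheritParams mtl_objective
#' @return A `p x t` matrix. When `intercepts` is supplied, the intercept
#'   gradient is attached as attribute `"intercept_gradient"`.
#' @export
smooth_gradient <- function(W, ts, control = mtl_control(), intercepts = NULL) {
  W <- check_W(W, ts)
  b <- if (is.null(intercepts)) numeric(ts$t) else intercepts
  g <- smooth_grad(W, b, ts, control)
  out <- g$W
  if (!is.null(intercepts)) attr(out, "intercept_gradient") <- g$b
  out
}

#' Smooth gradient at the all-zero coefficients
#'
#' The quantity from which `lambda_max` is read. Under the default weights
#' (2, 0.5) every column equals `-(1/n_i) X_i' y_i` for *both* task types:
#' the unweighted least-squares gradient at zero is `-(2/n) X'y` and the
#' unweighted logistic gradient is `-(1/(2n)) X'y` (since `sigma(0) = 1/2`),
#' a fixed factor of 4 that the weighting cancels. This alignment is what
#' lets classification and regression tasks share one lambda scale.
#'
#' @param ts A [mixed_task_set].
#' @param control An [mtl_control].
#' @return A `p x t` matrix. With `control$intercept = TRUE` the gradient is
#'   taken at `W = 0` with each intercept at its unpenalized optimum.
#' @export
gradient_at_zero <- function(ts, control = mtl_control()) {
  W0 <- matrix(0, ts$p, ts$t)
  b <- numeric(ts$t)
  if (control$intercept) b <- optimal_null_intercepts(ts)
  smooth_grad(W0, b, ts, control)$W
}

# Closed-form intercepts of the null (W = 0) model: the outcome mean for
# regression, the log-odds of the positive fraction for classification.
optimal_null_intercepts <- function(ts) {
  vapply(ts$tasks, function(tk) {
    if (tk$type == "regression") return(mean(tk$y))
    pos <- mean(tk$y > 0)
    stats::qlogis(min(max(pos, 1e-12), 1 - 1e-12))
  }, numeric(1))
}
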