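# Accelerated proximal gradient (FISTA) solver for the weighted mixed-loss
# objective with the row-wise L2,1 penalty.

#' Row-wise group soft-thresholding
#'
#' Proximal operator of `tau * sum_j ||w_(j)||_2`: each row of `V` is scaled
#' by `max(0, 1 - tau / ||v_(j)||_2)`, so rows with Euclidean norm at most
#' `tau` become exactly zero. This is where the exact zeros that define the
#' selected support come from; no post-hoc thresholding is applied anywhere.
#'
#' @param V Numeric matrix (features x tasks).
#' @param tau Nonnegative threshold.
#' @return A matrix of the same shape.
#' @examples
#' proximal_l21(rbind(c(3, 4), c(0.5, 0)), 2.5)
#' @export
proximal_l21 <- function(V, tau) {
  if (tau < 0) stop("tau must be nonnegative")
  V <- as.matrix(V)
  if (tau == 0) return(V)
  rn <- sqrt(rowSums(V^2))
  scale <- ifelse(rn > tau, 1 - tau / rn, 0)
  V * scale
}

# One backtracking proximal step from the extrapolation point (V, bv).
# Halves the step until the smooth part at the candidate is bounded by its
# quadratic majorizer; the intercept block is unpenalized, so it takes a
# plain gradient step inside the same majorizer.
backtrack_prox <- function(V, bv, g, fV, ts, ctl, lambda, step, with_b) {
  repeat {
    C <- proximal_l21(V - step * g$W, step * lambda)
    bc <- if (with_b) bv - step * g$b else bv
    dW <- C - V
    db <- bc - bv
    lin <- sum(g$W * dW) + sum(g$b * db)
    quad <- (sum(dW^2) + sum(db^2)) / (2 * step)
    fC <- smooth_value(C, bc, ts, ctl)
    if (fC <= fV + lin + quad + 1e-12 * abs(fV)) {
      return(list(W = C, b = bc, f = fC, step = step))
    }
    step <- step / 2
    if (step < 1e-20) stop("backtracking step size underflow; objective may be non-finite")
  }
}

#' Fit the mixed-task model at one fixed lambda
#'
#' Minimises the weighted objective (see [mtl_objective()]) by accelerated
#' proximal gradient descent: Nesterov extrapolation with the momentum
#' sequence `t_{k+1} = (1 + sqrt(1 + 4 t_k^2)) / 2`, a backtracking line
#' search on the smooth part (halving, restarting from the previously
#' accepted step), and a monotone safeguard — if the accelerated candidate
#' increases the objective, momentum is restarted and a plain proximal step
#' is taken instead, so the trace of accepted objective values is
#' non-increasing. Convergence is declared when the relative objective change
#' `|f_k - f_{k-1}| / max(1, f_{k-1})` drops to `control$tol`.
#'
#' @param ts A [mixed_task_set].
#' @param lambda Sparsity strength; defaults to `control$lambda`.
#' @param control An [mtl_control].
#' @param W_init,b_init Optional warm start (standardized scale when
#'   `control$standardize` is `TRUE`); zero otherwise.
#' @return An object of class `mtlcomb`: coefficient matrix `W` (features x
#'   tasks, on the fitting scale), `intercepts`, selected `support` (rows
#'   with nonzero norm), `objective`, `objective_trace`, `n_iter`,
#'   `converged`, the `control` used, and the standardization parameters
#'   when `control$standardize` is `TRUE`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(300), 30, 10)
#' ts <- mixed_task_set(list(
#'   task_data(X, X[, 1] - X[, 2] + rnorm(30, sd = 0.3), "regression", name = "r1"),
#'   task_data(X, sign(X[, 1] + rnorm(30, sd = 0.5)), "classification", name = "c1")))
#' fit <- mtlcomb(ts, lambda = 0.1)
#' fit$support
#' @export
mtlcomb <- function(ts, lambda = NULL, control = mtl_control(),
                    W_init = NULL, b_init = NULL) {
  stopifnot(inherits(ts, "mixed_task_set"))
  if (is.null(lambda)) lambda <- control$lambda
  if (lambda < 0) stop("lambda must be nonnegative")
  scaling <- NULL
  if (control$standardize) {
    std <- standardize_task_set(ts)
    ts_fit <- std$ts
    scaling <- std$scaling
  } else ts_fit <- ts
  sol <- fista_solve(ts_fit, lambda, control, W_init, b_init)
  structure(
    c(sol,
      list(lambda = lambda, control = control, scaling = scaling,
           feature_names = ts$feature_names, task_names = task_names(ts),
           task_types = task_types(ts))),
    class = "mtlcomb")
}

# Core iteration on an already-standardized task set.
fista_solve <- function(ts, lambda, ctl, W_init = NULL, b_init = NULL) {
  p <- ts$p; t <- ts$t
  W <- if (is.null(W_init)) matrix(0, p, t) else check_W(W_init, ts)
  b <- if (is.null(b_init)) numeric(t) else as.numeric(b_init)
  with_b <- ctl$intercept
  if (!with_b) b <- numeric(t)
  W_prev <- W
  b_prev <- b
  tk <- 1
  step <- 1
  F_cur <- smooth_value(W, b, ts, ctl) + lambda * l21_norm(W)
  trace <- F_cur
  converged <- FALSE
  k <- 0L
  while (k < ctl$max_iter) {
    k <- k + 1L
    tk_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    mom <- (tk - 1) / tk_next
    V <- W + mom * (W - W_prev)
    bv <- b + mom * (b - b_prev)
    g <- smooth_grad(V, bv, ts, ctl)
    fV <- smooth_value(V, bv, ts, ctl)
    if (!is.finite(fV)) stop("non-finite objective encountered at iteration ", k)
    cand <- backtrack_prox(V, bv, g, fV, ts, ctl, lambda, step, with_b)
    F_cand <- cand$f + lambda * l21_norm(cand$W)
    if (F_cand > F_cur) {
      # monotone safeguard: drop momentum, plain proximal step from W
      tk_next <- 1
      g <- smooth_grad(W, b, ts, ctl)
      fW <- smooth_value(W, b, ts, ctl)
      cand <- backtrack_prox(W, b, g, fW, ts, ctl, lambda, cand$step, with_b)
      F_cand <- cand$f + lambda * l21_norm(cand$W)
      if (F_cand > F_cur) {
        # no descent direction left at machine precision: stop at W
        converged <- TRUE
        break
      }
    }
    W_prev <- W; b_prev <- b
    W <- cand$W; b <- cand$b
    step <- cand$step
    tk <- tk_next
    trace <- c(trace, F_cand)
    if (abs(F_cand - F_cur) / max(1, abs(F_cur)) <= ctl$tol) {
      F_cur <- F_cand
      converged <- TRUE
      break
    }
    F_cur <- F_cand
  }
  if (!converged)
    warning("solver reached max_iter = ", ctl$max_iter, " without converging")
  rn <- row_norms(W)
  list(W = W, intercepts = b, objective = F_cur, objective_trace = trace,
       n_iter = k, converged = converged, support = which(rn > 0))
}

#' @export
print.mtlcomb <- function(x, ...) {
  cat(sprintf("mtlcomb fit: lambda = %.4g, %d/%d features selected, %s after %d iterations\n",
              x$lambda, length(x$support), nrow(x$W),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Extract coefficients
#'
#' @param object An `mtlcomb` fit.
#' @param unstandardize If `TRUE` and the model was fitted on z-scored
#'   features, return coefficients on the original feature scale (each column
#'   divided by the task's column scales, intercepts adjusted accordingly).
#' @param ... Unused.
#' @return A `p x t` matrix with feature and task dimnames; intercepts (if
#'   fitted) attached as attribute `"intercepts"`.
#' @export
coef.mtlcomb <- function(object, unstandardize = FALSE, ...) {
  W <- object$W
  b <- object$intercepts
  if (unstandardize && !is.null(object$scaling)) {
    for (i in seq_len(ncol(W))) {
      sc <- object$scaling[[i]]
      W[, i] <- W[, i] / sc$scale
      b[i] <- b[i] - sum(W[, i] * sc$center)
    }
  }
  dimnames(W) <- list(object$feature_names, object$task_names)
  attr(W, "intercepts") <- b
  W
}
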