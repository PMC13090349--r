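# Independent oracles, implemented with no code shared with the package's
# solver: cyclic coordinate descent for the single-task lasso and the
# l1-penalized logistic regression, and a per-sample loop evaluation of the
# losses.

soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# Minimises (1/(2n)) ||y - X w||^2 + lambda ||w||_1 by cyclic coordinate
# descent with exact univariate updates.
cd_lasso <- function(X, y, lambda, tol = 1e-12, max_sweeps = 50000) {
  n <- nrow(X); p <- ncol(X)
  w <- rep(0, p)
  xx <- colSums(X^2) / n
  r <- y
  for (s in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(p)) {
      wj_old <- w[j]
      rho <- sum(X[, j] * r) / n + xx[j] * wj_old
      w[j] <- soft(rho, lambda) / xx[j]
      if (w[j] != wj_old) {
        r <- r - X[, j] * (w[j] - wj_old)
        delta <- max(delta, abs(w[j] - wj_old))
      }
    }
    if (delta < tol) break
  }
  w
}

# Minimises (1/n) sum softplus(-y X w) + lambda ||w||_1 by proximal
# coordinate descent with per-coordinate curvature bound (1/(4n)) sum x_ij^2
# (the logistic second derivative is at most 1/4).
cd_logistic <- function(X, y, lambda, tol = 1e-12, max_sweeps = 200000) {
  n <- nrow(X); p <- ncol(X)
  w <- rep(0, p)
  L <- colSums(X^2) / (4 * n)
  eta <- rep(0, n)
  for (s in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(p)) {
      g <- -sum(y * plogis(-y * eta) * X[, j]) / n
      wj_new <- soft(w[j] - g / L[j], lambda / L[j])
      if (wj_new != w[j]) {
        eta <- eta + X[, j] * (wj_new - w[j])
        delta <- max(delta, abs(wj_new - w[j]))
        w[j] <- wj_new
      }
    }
    if (delta < tol) break
  }
  w
}

# Per-sample loop evaluation of the two losses (no matrix algebra).
loop_logit_loss <- function(X, y, w) {
  tot <- 0
  for (i in seq_len(nrow(X))) {
    z <- sum(X[i, ] * w)
    tot <- tot + log(1 + exp(-y[i] * z))
  }
  tot / nrow(X)
}

loop_ls_loss <- function(X, y, w) {
  tot <- 0
  for (i in seq_len(nrow(X))) {
    tot <- tot + (y[i] - sum(X[i, ] * w))^2
  }
  tot / nrow(X)
}

# Central finite differences of the smooth objective part.
fd_gradient <- function(W, ts, ctl, h = 1e-6) {
  G <- matrix(0, nrow(W), ncol(W))
  for (j in seq_len(nrow(W))) for (i in seq_len(ncol(W))) {
    Wp <- W; Wp[j, i] <- Wp[j, i] + h
    Wm <- W; Wm[j, i] <- Wm[j, i] - h
    fp <- mtl_objective(Wp, ts, ctl) - ctl$lambda * sum(sqrt(rowSums(Wp^2)))
    fm <- mtl_objective(Wm, ts, ctl) - ctl$lambda * sum(sqrt(rowSums(Wm^2)))
    G[j, i] <- (fp - fm) / (2 * h)
  }
  G
}
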