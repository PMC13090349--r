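test_that("losses match closed forms and a per-sample loop oracle", {
  set.seed(10)
  X <- matrix(rnorm(24), 8, 3)
  ycls <- ifelse(runif(8) < 0.5, 1, -1); ycls[1:2] <- c(-1, 1)
  yreg <- rnorm(8)
  cls <- task_data(X, ycls, "classification")
  reg <- task_data(X, yreg, "regression")

  expect_equal(logit_loss(cls, rep(0, 3)), log(2))
  one <- task_data(matrix(c(1, 1), 2, 1), c(1, 1), "classification")
  expect_equal(logit_loss(one, 10), log(1 + exp(-10)))

  expect_equal(least_squares_loss(
    task_data(matrix(0, 4, 1), c(1, -1, 1, -1), "regression"), 0), 1)
  w_fit <- c(0.3, -1, 2)
  exact <- task_data(X, drop(X %*% w_fit), "regression")
  expect_equal(least_squares_loss(exact, w_fit), 0)

  w <- rnorm(3)
  expect_equal(logit_loss(cls, w), loop_logit_loss(X, ycls, w), tolerance = 1e-12)
  expect_equal(least_squares_loss(reg, w), loop_ls_loss(X, yreg, w), tolerance = 1e-12)

  expect_error(logit_loss(reg, w), "classification")
  expect_error(least_squares_loss(cls, w), "regression")
})

test_that("softplus evaluation stays finite at extreme margins", {
  tk <- task_data(matrix(c(1, -1), 2, 1), c(1, -1), "classification")
  expect_true(is.finite(logit_loss(tk, 1e4)))
  expect_true(is.finite(logit_loss(tk, -1e4)))
  expect_equal(logit_loss(tk, -1e4), 1e4, tolerance = 1e-9)
})

test_that("the weighted objective reduces to the weighted losses at W = 0", {
  set.seed(11)
  ts_c <- mixed_task_set(list(rand_task(12, 4, "classification")))
  h <- ctl_raw(lambda = 3, alpha = 2, beta = 5)
  expect_equal(mtl_objective(matrix(0, 4, 1), ts_c, h), 2 * log(2))

  ts_r <- mixed_task_set(list(
    task_data(matrix(rnorm(8), 2, 4), c(2, -2), "regression")))
  expect_equal(mtl_objective(matrix(0, 4, 1), ts_r, h), 0.5 * 4)

  expect_error(mtl_objective(matrix(0, 3, 1), ts_r, h), "must be 4 x 1")
})

test_that("the mean-regularized term annihilates coefficients shared across tasks", {
  ts <- rand_mixed(n = 20, p = 6, cls = 1, reg = 2, seed = 12)
  w <- rnorm(6)
  W <- cbind(w, w, w)
  h0 <- ctl_raw(alpha = 0)
  h1 <- ctl_raw(alpha = 50)
  expect_equal(mtl_objective(W, ts, h1), mtl_objective(W, ts, h0), tolerance = 1e-10)
  # and a non-constant row is penalized
  W2 <- W; W2[1, 1] <- W2[1, 1] + 1
  expect_gt(mtl_objective(W2, ts, h1), mtl_objective(W2, ts, h0))
})

test_that("smooth_gradient matches central finite differences on random instances", {
  set.seed(13)
  worst <- 0
  for (rep in 1:50) {
    ts <- rand_mixed(n = sample(10:25, 1), p = sample(3:6, 1),
                     cls = sample(0:2, 1), reg = sample(1:2, 1),
                     seed = 100 + rep)
    h <- ctl_raw(alpha = runif(1), beta = runif(1))
    W <- matrix(rnorm(ts$p * ts$t, sd = 0.5), ts$p, ts$t)
    g <- smooth_gradient(W, ts, h)
    g_fd <- fd_gradient(W, ts, h)
    rel <- max(abs(g - g_fd)) / max(1, max(abs(g_fd)))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("gradient at zero has the closed per-type forms and a zero-signal null", {
  set.seed(14)
  X <- matrix(rnorm(80), 20, 4)
  y <- ifelse(runif(20) < 0.5, 1, -1); y[1:2] <- c(-1, 1)
  ts <- mixed_task_set(list(task_data(X, y, "classification", name = "c"),
                            task_data(X, y, "regression", name = "r")))
  g0 <- gradient_at_zero(ts, ctl_raw(alpha = 3, beta = 4)) # alpha, beta vanish at 0
  target <- -drop(crossprod(X, y)) / 20
  expect_equal(g0[, 1], target, tolerance = 1e-12)
  expect_equal(g0[, 2], target, tolerance = 1e-12)

  # regression task with y = 0: zero gradient at zero
  ts0 <- mixed_task_set(list(task_data(X, rep(0, 20), "regression")))
  expect_equal(gradient_at_zero(ts0, ctl_raw()), matrix(0, 4, 1))

  # feature orthogonal to the outcome gets a zero row
  v <- rnorm(20); v <- v - y * sum(v * y) / sum(y * y) # orthogonal to y
  Xo <- cbind(X[, 1:3], v)
  tso <- mixed_task_set(list(task_data(Xo, y, "regression")))
  expect_equal(gradient_at_zero(tso, ctl_raw())[4, 1], 0, tolerance = 1e-12)
})

test_that("default weights align the two loss gradients; unweighted they differ by 4", {
  for (seed in 1:10) {
    ps <- paired_sets(n = 30, p = 6, seed = seed)
    both <- mixed_task_set(c(ps$cls$tasks, ps$reg$tasks))
    g <- gradient_at_zero(both, ctl_raw())
    expect_lt(max(abs(g[, 1] - g[, 2])), 1e-12)
    gu <- gradient_at_zero(both, ctl_raw(weight_class = 1, weight_reg = 1))
    expect_equal(gu[, 2] / gu[, 1], rep(4, 6), tolerance = 1e-10)
  }
})

test_that("the objective is nonnegative and midpoint-convex along random segments", {
  set.seed(15)
  ts <- rand_mixed(n = 15, p = 4, cls = 1, reg = 1, seed = 16)
  h <- ctl_raw(lambda = 0.3, alpha = 0.2, beta = 0.1)
  for (rep in 1:100) {
    Wa <- matrix(rnorm(8), 4, 2)
    Wb <- matrix(rnorm(8), 4, 2)
    fa <- mtl_objective(Wa, ts, h)
    fb <- mtl_objective(Wb, ts, h)
    fm <- mtl_objective((Wa + Wb) / 2, ts, h)
    expect_gte(fa, 0)
    expect_lte(fm, (fa + fb) / 2 + 1e-9)
  }
})
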