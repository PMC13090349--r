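test_that("row-wise group soft-thresholding matches its variational definition", {
  V <- rbind(c(3, 4), c(0.5, 0), c(-1, 2))
  expect_identical(proximal_l21(V, 0), V)
  expect_equal(proximal_l21(rbind(c(3, 4)), 5), rbind(c(0, 0)))
  expect_equal(proximal_l21(rbind(c(3, 4)), 2.5), rbind(c(1.5, 2.0)))
  expect_error(proximal_l21(V, -1), "nonnegative")

  # numeric oracle for one row: the minimiser of 0.5||w-v||^2 + tau||w||
  # lies on the segment c*v, c in [0,1], so a 1-D search suffices
  set.seed(20)
  for (rep in 1:10) {
    v <- rnorm(3)
    tau <- runif(1, 0, 2)
    obj <- function(cc) 0.5 * sum((cc * v - v)^2) + tau * sqrt(sum((cc * v)^2))
    cc <- optimize(obj, c(0, 1), tol = 1e-12)$minimum
    num <- if (obj(0) <= obj(cc)) 0 * v else cc * v
    expect_equal(drop(proximal_l21(rbind(v), tau)), num, tolerance = 1e-6)
  }
})

test_that("lambda at or above lambda_max yields the exact zero solution", {
  for (seed in 1:5) {
    ts <- rand_mixed(n = 25, p = 6, cls = 1, reg = 1, seed = 30 + seed)
    lm <- lambda_max(ts, ctl_raw())
    fit <- mtlcomb(ts, lambda = lm * 1.000001, control = ctl_raw())
    expect_true(all(fit$W == 0))
    expect_length(fit$support, 0)
  }
})

test_that("single regression task reduces to the lasso (coordinate-descent oracle)", {
  set.seed(40)
  n <- 40; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:3] %*% c(1, -1, 0.5)) + rnorm(n, sd = 0.5)
  ts <- mixed_task_set(list(task_data(X, y, "regression")))
  ctl <- ctl_raw(tol = 1e-12, max_iter = 20000)
  for (lam in c(0.4, 0.1, 0.02)) {
    fit <- mtlcomb(ts, lambda = lam, control = ctl)
    w_cd <- cd_lasso(X, y, lam)
    expect_lt(max(abs(drop(fit$W) - w_cd)), 1e-5)
  }
})

test_that("single-task special case agrees with glmnet as an independent cross-check", {
  set.seed(41)
  n <- 60; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:2] %*% c(1.5, -1)) + rnorm(n, sd = 0.5)
  ts <- mixed_task_set(list(task_data(X, y, "regression")))
  lam <- 0.15
  fit <- mtlcomb(ts, lambda = lam, control = ctl_raw(tol = 1e-12, max_iter = 20000))
  gn <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                       intercept = FALSE, thresh = 1e-14)
  expect_lt(max(abs(drop(fit$W) - as.numeric(gn$beta))), 1e-4)
})

test_that("single classification task matches an l1-logistic coordinate-descent oracle", {
  set.seed(42)
  n <- 60; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- ifelse(runif(n) < plogis(X[, 1] - X[, 2]), 1, -1)
  ts <- mixed_task_set(list(task_data(X, y, "classification")))
  ctl <- ctl_raw(tol = 1e-12, max_iter = 50000)
  for (lam in c(0.1, 0.04)) {
    # solver minimises 2 Z + lam ||w||_1  <=>  Z + (lam/2) ||w||_1
    fit <- mtlcomb(ts, lambda = lam, control = ctl)
    w_cd <- cd_logistic(X, y, lam / 2)
    expect_lt(max(abs(drop(fit$W) - w_cd)), 1e-4)
  }
})

test_that("strong mean-regularization ties identical tasks together", {
  set.seed(43)
  n <- 30; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:2] %*% c(1, -1)) + rnorm(n, sd = 0.3)
  ts <- mixed_task_set(list(task_data(X, y, "regression", name = "a"),
                            task_data(X, y, "regression", name = "b")))
  fit <- mtlcomb(ts, lambda = 0.05,
                 control = ctl_raw(alpha = 1e4, tol = 1e-12, max_iter = 20000))
  expect_lt(max(abs(fit$W[, 1] - fit$W[, 2])), 1e-6)
})

test_that("accepted objective traces never increase and warm starts do not hurt", {
  for (seed in 1:5) {
    ts <- rand_mixed(n = 30, p = 8, cls = 1, reg = 1, seed = 50 + seed)
    ctl <- ctl_raw(tol = 1e-10, max_iter = 10000)
    lam <- 0.3 * lambda_max(ts, ctl)
    cold <- mtlcomb(ts, lambda = lam, control = ctl)
    expect_true(all(diff(cold$objective_trace) <= 1e-12))
    # warm start from a nearby solution reaches the same objective
    warm <- mtlcomb(ts, lambda = lam, control = ctl,
                    W_init = mtlcomb(ts, lambda = lam * 1.3, control = ctl)$W)
    expect_lt(abs(warm$objective - cold$objective), 1e-6)
  }
})

test_that("converged solutions satisfy the L2,1 subgradient optimality conditions", {
  set.seed(60)
  for (rep in 1:20) {
    ts <- rand_mixed(n = sample(20:40, 1), p = sample(4:8, 1),
                     cls = sample(0:1, 1), reg = sample(1:2, 1),
                     seed = 600 + rep)
    ctl <- ctl_raw(alpha = runif(1, 0, 0.5), beta = runif(1, 0, 0.5),
                   tol = 1e-11, max_iter = 30000)
    lam <- runif(1, 0.1, 0.6) * lambda_max(ts, ctl)
    fit <- mtlcomb(ts, lambda = lam, control = ctl)
    g <- smooth_gradient(fit$W, ts, ctl)
    rn <- sqrt(rowSums(fit$W^2))
    for (j in seq_len(ts$p)) {
      if (rn[j] > 0) {
        res <- sqrt(sum((g[j, ] + lam * fit$W[j, ] / rn[j])^2))
        expect_lt(res, 1e-4 * max(1, lam))
      } else {
        expect_lte(sqrt(sum(g[j, ]^2)), lam * (1 + 1e-4))
      }
    }
  }
})

test_that("solver objective matches dense random-restart direct minimisation on tiny problems", {
  set.seed(70)
  for (rep in 1:20) {
    p <- sample(3:8, 1); t <- sample(1:3, 1)
    cls <- sample(0:min(1, t - 1), 1)
    ts <- rand_mixed(n = 20, p = p, cls = cls, reg = t - cls, seed = 700 + rep)
    ctl <- ctl_raw(tol = 1e-11, max_iter = 30000)
    lam <- 0.3 * lambda_max(ts, ctl)
    fit <- mtlcomb(ts, lambda = lam, control = ctl)
    obj <- function(wvec) mtl_objective(matrix(wvec, p, ts$t), ts,
                                        ctl_raw(lambda = lam))
    best <- Inf
    for (s in 1:8) {
      start <- rnorm(p * ts$t, sd = 0.5)
      best <- min(best, optim(start, obj, method = "Nelder-Mead",
                              control = list(maxit = 5000, reltol = 1e-12))$value)
    }
    expect_lte(fit$objective, best + 1e-6)
  }
})

test_that("unpenalized intercepts absorb outcome shifts", {
  set.seed(80)
  n <- 60; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- 10 + drop(X[, 1:2] %*% c(1, -1)) + rnorm(n, sd = 0.3)
  ts <- mixed_task_set(list(task_data(X, y, "regression")))
  fit <- mtlcomb(ts, lambda = 0.05,
                 control = ctl_raw(intercept = TRUE, tol = 1e-11, max_iter = 20000))
  expect_equal(fit$intercepts[1], 10, tolerance = 0.3)
  # without an intercept the shifted outcome is fit poorly
  fit0 <- mtlcomb(ts, lambda = 0.05, control = ctl_raw(tol = 1e-10))
  expect_gt(fit0$objective, fit$objective)
})
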