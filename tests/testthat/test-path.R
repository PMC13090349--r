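test_that("lambda sequences are geometric with the stated endpoints", {
  expect_equal(lambda_sequence(1, 0.01, 3), c(1, 0.1, 0.01))
  s <- lambda_sequence(2.7, 0.05, 23)
  expect_equal(s[1], 2.7)
  expect_equal(s[23], 0.05 * 2.7, tolerance = 1e-12)
  r <- s[-1] / s[-23]
  expect_lt(diff(range(r)), 1e-12)
  expect_error(lambda_sequence(1, 0.01, 1), "at least 2")
  expect_error(lambda_sequence(1, 1.2, 5), "\\(0, 1\\)")
  expect_error(lambda_sequence(-1, 0.5, 5), "positive")
})

test_that("lambda_max has the closed form for a single regression task", {
  set.seed(90)
  n <- 30; p <- 7
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  ts <- mixed_task_set(list(task_data(X, y, "regression")))
  expect_equal(lambda_max(ts, ctl_raw()), max(abs(crossprod(X, y))) / n,
               tolerance = 1e-12)
  # duplicating every sample leaves lambda_max unchanged (1/n normalisation)
  ts2 <- mixed_task_set(list(task_data(rbind(X, X), c(y, y), "regression")))
  expect_equal(lambda_max(ts2, ctl_raw()), lambda_max(ts, ctl_raw()),
               tolerance = 1e-12)
  # all-zero outcome is degenerate
  ts0 <- mixed_task_set(list(task_data(X, rep(0, n), "regression")))
  expect_error(lambda_max(ts0, ctl_raw()), "degenerate")
})

test_that("task-restricted lambda_max coincides across task types (bisection oracle)", {
  ps <- paired_sets(n = 50, p = 8, seed = 91)
  lm_c <- lambda_max(ps$cls, ctl_raw())
  lm_r <- lambda_max(ps$reg, ctl_raw())
  expect_equal(lm_c, lm_r, tolerance = 1e-12)
  # bisection oracle: smallest lambda giving an all-zero fit, per task type
  null_at <- function(ts, lam)
    length(mtlcomb(ts, lambda = lam, control = ctl_raw())$support) == 0L
  for (ts in list(ps$cls, ps$reg)) {
    lo <- 0.5 * lm_c; hi <- 1.5 * lm_c
    for (i in 1:30) {
      mid <- (lo + hi) / 2
      if (null_at(ts, mid)) hi <- mid else lo <- mid
    }
    expect_equal(hi, lm_c, tolerance = 1e-6 * lm_c)
  }
})

test_that("warm-started paths start empty, grow support, and match cold starts", {
  ts <- rand_mixed(n = 40, p = 12, cls = 1, reg = 1, seed = 92)
  ctl <- ctl_raw(n_lambda = 15, tol = 1e-9)
  path <- mtlcomb_path(ts, ctl)
  expect_equal(length(path$lambdas), 15)
  expect_equal(path$lambdas[1], lambda_max(ts, ctl))
  expect_equal(path$lambdas[15], 0.01 * path$lambdas[1], tolerance = 1e-12)
  expect_equal(path$support_sizes[1], 0L)
  # support grows as lambda shrinks (trend, not strict monotonicity)
  expect_lte(cor(path$lambdas, path$support_sizes, method = "spearman"), 0)
  # cold refits at each lambda do no better
  for (j in c(4, 8, 12)) {
    cold <- mtlcomb(ts, lambda = path$lambdas[j], control = ctl)
    expect_lte(path$objectives[j], cold$objective + 1e-8)
  }
})

test_that("on pure noise large lambdas select nothing", {
  set.seed(93)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- rnorm(40) # independent of X
  ts <- mixed_task_set(list(task_data(X, y, "regression")))
  path <- mtlcomb_path(ts, ctl_raw(n_lambda = 10, lambda_ratio = 0.5))
  expect_lte(max(path$support_sizes[1:5]), 3)
})

test_that("true-support features enter the path before noise features", {
  sim <- generate_mixed_tasks(sim_config(t = 2, c = 1, p = 30, n_per_task = 120,
                                         k_support = 3, effect_scale = 0.8,
                                         seed = 94))
  path <- mtlcomb_path(sim$ts, mtl_control(n_lambda = 25))
  entry <- mtlcomb:::first_entry_index(path)
  truth <- sim$truth$support
  noise <- setdiff(seq_len(30), truth)
  expect_lt(max(entry[truth]), min(c(entry[noise], Inf), na.rm = TRUE))
})

test_that("default weights align path entry points across task types; unit weights do not", {
  ps <- paired_sets(n = 60, p = 10, seed = 95)
  entry_idx <- function(ts, ctl, lambdas) {
    path <- mtlcomb_path(ts, ctl, lambdas = lambdas)
    min(mtlcomb:::first_entry_index(path), na.rm = TRUE)
  }
  ctl <- ctl_raw(n_lambda = 30, tol = 1e-9)
  lam <- lambda_sequence(1.05 * lambda_max(ps$reg, ctl), 0.01, 30)
  expect_lte(abs(entry_idx(ps$cls, ctl, lam) - entry_idx(ps$reg, ctl, lam)), 1)

  ctl_u <- ctl_raw(weight_class = 1, weight_reg = 1, n_lambda = 30, tol = 1e-9)
  lam_u <- lambda_sequence(1.05 * lambda_max(ps$reg, ctl_u), 0.01, 30)
  expect_gte(abs(entry_idx(ps$cls, ctl_u, lam_u) - entry_idx(ps$reg, ctl_u, lam_u)), 3)
})

test_that("path export tables carry the nonzero coefficients and per-lambda summary", {
  ts <- rand_mixed(n = 30, p = 6, cls = 1, reg = 1, seed = 96)
  path <- mtlcomb_path(ts, ctl_raw(n_lambda = 8))
  tab <- path_table(path)
  expect_true(all(tab$coefficient != 0))
  expect_setequal(unique(tab$task), c("c1", "r1"))
  smry <- path_summary(path)
  expect_equal(nrow(smry), 8)
  expect_equal(smry$support_size, path$support_sizes)
  # every nonzero in the table is accounted for by the summary support sizes
  counts <- table(factor(tab$lambda_index, levels = 1:8))
  expect_true(all(as.integer(counts) >=  smry$support_size))
})
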