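# Small random problem builders used across the suite. All draws are seeded
# by the caller.

rand_task <- function(n, p, type = "regression", seed = NULL, signal = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  w <- if (signal) c(rnorm(min(3, p)), rep(0, p - min(3, p))) else rep(0, p)
  eta <- drop(X %*% w)
  if (type == "classification") {
    y <- ifelse(runif(n) < plogis(eta), 1, -1)
    if (length(unique(y)) < 2L) y[1:2] <- c(-1, 1)
  } else {
    y <- eta + rnorm(n)
  }
  task_data(X, y, type, name = paste0(type, "_", n, "x", p))
}

# A mixed set with cls classification + reg regression tasks, each its own X.
rand_mixed <- function(n = 30, p = 8, cls = 1, reg = 1, seed = 1) {
  set.seed(seed)
  tasks <- c(
    lapply(seq_len(cls), function(i) {
      tk <- rand_task(n, p, "classification")
      tk$name <- paste0("c", i); tk
    }),
    lapply(seq_len(reg), function(i) {
      tk <- rand_task(n, p, "regression")
      tk$name <- paste0("r", i); tk
    }))
  mixed_task_set(tasks)
}

# Paired single-task sets built from the same (X, y in {-1,+1}): one reads y
# as class labels, the other as a continuous outcome.
paired_sets <- function(n = 40, p = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- ifelse(runif(n) < plogis(X[, 1] - X[, 2]), 1, -1)
  if (length(unique(y)) < 2L) y[1:2] <- c(-1, 1)
  list(
    cls = mixed_task_set(list(task_data(X, y, "classification", name = "c"))),
    reg = mixed_task_set(list(task_data(X, y, "regression", name = "r"))),
    X = X, y = y)
}

ctl_raw <- function(...) mtl_control(standardize = FALSE, ...)
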