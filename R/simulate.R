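# Seeded generator of mixed-task data with a known shared support, emulating
# sparse linear signals shared across tasks with controllable dimensionality
# ratio, label imbalance and task count.

#' Generator configuration
#'
#' Defines one simulated study condition. Features are iid standard normal;
#' a base coefficient vector with entries `+/- effect_scale` lives on a
#' random support of size `k_support` shared by all tasks, each task adding
#' Gaussian jitter of scale `share_noise` (so supports coincide across tasks
#' while magnitudes vary mildly). Regression outcomes are the linear signal
#' plus Gaussian noise `noise_sd`; classification labels are drawn +1 with
#' probability `sigma(x'w + b)`, the per-task offset `b` bisected so the
#' realised positive fraction is within `max(0.01, 1/n)` of
#' `imbalance_ratio` (1/n being the resolution of an n-sample fraction).
#'
#' @param t Task count. @param c Number of classification tasks (first `c`).
#' @param p Feature count. @param n_per_task Samples per task.
#' @param k_support True support size.
#' @param effect_scale Base coefficient magnitude.
#' @param share_noise Per-task coefficient jitter scale.
#' @param noise_sd Regression noise standard deviation.
#' @param imbalance_ratio Target positive-label fraction, in (0, 0.5].
#' @param dim_ratio Optional n/p convenience parameter; when set,
#'   `n_per_task` is `round(dim_ratio * p)`.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(t = 4L, c = 2L, p = 100L, n_per_task = 50L,
                       k_support = 10L, effect_scale = 0.5, share_noise = 0.05,
                       noise_sd = 1, imbalance_ratio = 0.5, dim_ratio = NULL,
                       seed = 1L) {
  if (!is.null(dim_ratio)) n_per_task <- as.integer(round(dim_ratio * p))
  stopifnot(t >= 1, c >= 0, c <= t, k_support >= 1, k_support <= p,
            n_per_task >= 2, effect_scale >= 0, share_noise >= 0, noise_sd >= 0)
  if (imbalance_ratio <= 0 || imbalance_ratio > 0.5)
    stop("imbalance_ratio must lie in (0, 0.5]; r = 0 is degenerate (no positives)")
  structure(
    list(t = as.integer(t), c = as.integer(c), p = as.integer(p),
         n_per_task = as.integer(n_per_task), k_support = as.integer(k_support),
         effect_scale = effect_scale, share_noise = share_noise,
         noise_sd = noise_sd, imbalance_ratio = imbalance_ratio,
         dim_ratio = dim_ratio, seed = as.integer(seed)),
    class = "sim_config")
}

# Offset making the realised positive fraction hit the target: with the
# uniform draws fixed, frac(b) = mean(u < sigma(eta + b)) is a monotone step
# function of b, so bisection lands within 1/n of r deterministically.
bisect_offset <- function(eta, u, r, tol = max(0.01, 1 / length(u))) {
  frac <- function(b) mean(u < stats::plogis(eta + b))
  lo <- -50; hi <- 50
  if (frac(lo) > r || frac(hi) < r)
    stop("cannot bracket the target positive fraction r = ", r)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    f <- frac(mid)
    if (abs(f - r) <= tol && f > 0 && f < 1) return(mid)
    if (f < r) lo <- mid else hi <- mid
  }
  stop("bisection failed to reach positive fraction within ", tol, " of r = ", r)
}

#' Generate one mixed-task dataset with known ground truth
#'
#' @param cfg A [sim_config].
#' @param truth Optional ground truth from a previous call (same `t`, `c`,
#'   `p`): its coefficients and support are reused so the new draw — e.g. an
#'   independent test set — comes from the *same* data-generating model,
#'   with fresh features, noise and labels from `cfg$seed`.
#' @return A list: `ts` (the [mixed_task_set], classification tasks first),
#'   `truth` (ground truth: `W_star` p x t, `support` indices, `intercepts`
#'   used for imbalance control, the `config`).
#' @examples
#' sim <- generate_mixed_tasks(sim_config(t = 2, c = 1, p = 20, n_per_task = 40,
#'                                        k_support = 3, seed = 7))
#' sim$truth$support
#' @export
generate_mixed_tasks <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- cfg$p; n <- cfg$n_per_task; k <- cfg$k_support
  if (is.null(truth)) {
    support <- sort(sample.int(p, k))
    base <- sample(c(-1, 1), k, replace = TRUE) * cfg$effect_scale
    W_star <- matrix(0, p, cfg$t)
    for (i in seq_len(cfg$t)) {
      W_star[support, i] <- base + stats::rnorm(k, 0, cfg$share_noise)
    }
  } else {
    stopifnot(nrow(truth$W_star) == p, ncol(truth$W_star) == cfg$t)
    support <- truth$support
    W_star <- truth$W_star
  }
  fn <- sprintf("f%03d", seq_len(p))
  intercepts <- numeric(cfg$t)
  tasks <- vector("list", cfg$t)
  for (i in seq_len(cfg$t)) {
    w <- W_star[, i]
    X <- matrix(stats::rnorm(n * p), n, p)
    eta <- drop(X %*% w)
    if (i <= cfg$c) {
      u <- stats::runif(n)
      b <- if (is.null(truth)) bisect_offset(eta, u, cfg$imbalance_ratio) else
        truth$intercepts[i]
      y <- ifelse(u < stats::plogis(eta + b), 1, -1)
      if (length(unique(y)) < 2L)
        stop("generated task ", i, " has a single class; increase n_per_task")
      intercepts[i] <- b
      tasks[[i]] <- task_data(X, y, "classification",
                              name = sprintf("cls%02d", i), feature_names = fn)
    } else {
      y <- eta + stats::rnorm(n, 0, cfg$noise_sd)
      tasks[[i]] <- task_data(X, y, "regression",
                              name = sprintf("reg%02d", i), feature_names = fn)
    }
  }
  list(ts = mixed_task_set(tasks),
       truth = list(W_star = W_star, support = support,
                    intercepts = intercepts, config = cfg))
}

#' Dimensionality-sweep study grid
#'
#' One configuration per subjects-to-features ratio in 0.1, 0.2, ..., 0.8 at
#' fixed `p`, with `n_per_task = round(dim_ratio * p)` — progressively less
#' high-dimensional conditions.
#'
#' @param base_cfg A [sim_config] providing all other parameters.
#' @param ratios Dimensionality ratios (default `seq(0.1, 0.8, by = 0.1)`).
#' @return List of `sim_config`s.
#' @export
analysis1_grid <- function(base_cfg = sim_config(), ratios = seq(0.1, 0.8, by = 0.1)) {
  lapply(ratios, function(r) {
    cfg <- base_cfg
    cfg$dim_ratio <- r
    cfg$n_per_task <- as.integer(round(r * cfg$p))
    cfg
  })
}

#' Imbalance-by-task-count study grid
#'
#' Cross-product of imbalance ratios `{0.05, 0.1, 0.2, 0.3, 0.4, 0.5}` and
#' task counts `{4, 8, 12, 16, 20}` (a ratio of exactly 0 is excluded as
#' degenerate — it admits no positive labels). Each configuration uses half
#' classification, half regression tasks.
#'
#' @param base_cfg A [sim_config] providing the remaining parameters.
#' @param ratios Imbalance ratios.
#' @param task_counts Task counts (even, so `c = t/2`).
#' @return List of `sim_config`s.
#' @export
analysis2_grid <- function(base_cfg = sim_config(),
                           ratios = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                           task_counts = c(4L, 8L, 12L, 16L, 20L)) {
  stopifnot(all(ratios > 0))
  out <- list()
  for (r in ratios) for (t in task_counts) {
    cfg <- base_cfg
    cfg$imbalance_ratio <- r
    cfg$t <- as.integer(t)
    cfg$c <- as.integer(t %/% 2)
    out[[length(out) + 1L]] <- cfg
  }
  out
}
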