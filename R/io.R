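# Delimited-text data exchange, JSON manifests and model serialization, and
# the repeat-and-average experiment harness.

MODEL_FORMAT_VERSION <- "1.0"

# Doubles are serialized as "%.17g" strings: 17 significant digits round-trip
# IEEE doubles exactly, which plain JSON number formatting does not guarantee.
encode_num <- function(x) {
  if (is.matrix(x)) list(values = sprintf("%.17g", x), dim = dim(x))
  else sprintf("%.17g", x)
}

decode_num <- function(obj) {
  if (is.list(obj) || is.data.frame(obj)) {
    m <- as.numeric(obj$values)
    dim(m) <- as.integer(obj$dim)
    m
  } else as.numeric(obj)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a task set (and optional ground truth) to a directory
#'
#' Per task: a features CSV (first column `sample_id`, then one column per
#' feature) and an outcome CSV (`sample_id`, `outcome`); plus `manifest.json`
#' tying them together and, when supplied, `ground_truth.json`.
#'
#' @param ts A [mixed_task_set].
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth list from [generate_mixed_tasks()].
#' @param options Optional named list of global options stored in the
#'   manifest (e.g. seed, alpha, beta).
#' @return The manifest path, invisibly.
#' @export
write_task_set <- function(ts, dir, truth = NULL, options = list()) {
  stopifnot(inherits(ts, "mixed_task_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", ts$t)
  for (i in seq_len(ts$t)) {
    tk <- ts$tasks[[i]]
    fx <- file.path(dir, paste0(tk$name, "_features.csv"))
    fy <- file.path(dir, paste0(tk$name, "_outcome.csv"))
    ids <- sprintf("s%04d", seq_along(tk$y))
    Xdf <- data.frame(sample_id = ids, tk$X, check.names = FALSE)
    names(Xdf)[-1L] <- tk$feature_names
    utils::write.csv(Xdf, fx, row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(sample_id = ids, outcome = tk$y), fy,
                     row.names = FALSE, quote = FALSE)
    entries[[i]] <- list(name = tk$name, type = tk$type,
                         features_path = basename(fx),
                         outcome_path = basename(fy))
  }
  manifest <- list(tasks = entries, options = options)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(support = truth$support, W_star = truth$W_star,
           intercepts = truth$intercepts),
      file.path(dir, "ground_truth.json"), digits = NA)
  }
  invisible(mp)
}

#' Load a task set from a manifest
#'
#' Reads the JSON manifest written by [write_task_set()] (or assembled by
#' hand): a `tasks` array of `{name, type, features_path, outcome_path}`
#' entries with paths relative to the manifest, plus an optional `options`
#' block. Classification tasks are reordered first (stable otherwise) by
#' [mixed_task_set()]; every validation error names the offending task.
#'
#' @param path Path to `manifest.json`.
#' @return A [mixed_task_set] with the manifest `options` attached as
#'   attribute `"options"`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  mf <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(mf$tasks) || !nrow(as.data.frame(mf$tasks)))
    stop("manifest has no tasks")
  entries <- as.data.frame(mf$tasks)
  base <- dirname(path)
  tasks <- lapply(seq_len(nrow(entries)), function(i) {
    e <- entries[i, ]
    if (!e$type %in% c("classification", "regression"))
      stop("task '", e$name, "': unknown type '", e$type, "'")
    Xdf <- read_delim_auto(file.path(base, e$features_path))
    ydf <- read_delim_auto(file.path(base, e$outcome_path))
    if (nrow(Xdf) != nrow(ydf))
      stop("task '", e$name, "': features and outcome row counts differ")
    X <- as.matrix(Xdf[, -1L, drop = FALSE])
    task_data(X, ydf[[2L]], e$type, name = e$name,
              feature_names = colnames(X))
  })
  ts <- mixed_task_set(tasks)
  attr(ts, "options") <- mf$options
  ts
}

#' Serialize a fitted model to JSON
#'
#' Stores coefficients (full precision), intercepts, hyperparameters,
#' per-task standardization parameters, the training-data fingerprint and a
#' format version, so a reloaded model reproduces predictions bit for bit.
#'
#' @param fit An `mtlcomb` fit.
#' @param path Output path.
#' @param fingerprint Optional training-data fingerprint to embed.
#' @return `path`, invisibly.
#' @export
save_model <- function(fit, path, fingerprint = NULL) {
  stopifnot(inherits(fit, "mtlcomb"))
  scaling <- NULL
  if (!is.null(fit$scaling)) {
    scaling <- list(
      center = encode_num(vapply(fit$scaling, `[[`, numeric(nrow(fit$W)), "center")),
      scale = encode_num(vapply(fit$scaling, `[[`, numeric(nrow(fit$W)), "scale")))
  }
  obj <- list(
    format_version = MODEL_FORMAT_VERSION,
    feature_names = fit$feature_names,
    task_names = fit$task_names,
    task_types = fit$task_types,
    W = encode_num(fit$W),
    intercepts = encode_num(fit$intercepts),
    lambda = fit$lambda,
    control = unclass(fit$control),
    scaling = scaling,
    objective = fit$objective,
    n_iter = fit$n_iter,
    converged = fit$converged,
    fingerprint = fingerprint)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the reconstructed `mtlcomb` fit.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != MODEL_FORMAT_VERSION)
    stop("model format version mismatch: file has '", obj$format_version,
         "', this build reads '", MODEL_FORMAT_VERSION, "'")
  W <- decode_num(obj$W)
  ctl <- do.call(mtl_control, obj$control[names(obj$control) %in%
    names(formals(mtl_control))])
  scaling <- NULL
  if (!is.null(obj$scaling) && length(obj$scaling)) {
    ctr <- decode_num(obj$scaling$center)
    scl <- decode_num(obj$scaling$scale)
    scaling <- lapply(seq_len(ncol(W)), function(i)
      list(center = ctr[, i], scale = scl[, i]))
  }
  structure(
    list(W = W, intercepts = decode_num(obj$intercepts),
         objective = obj$objective, n_iter = obj$n_iter,
         converged = obj$converged, support = which(row_norms(W) > 0),
         lambda = obj$lambda, control = ctl, scaling = scaling,
         feature_names = obj$feature_names, task_names = obj$task_names,
         task_types = obj$task_types, fingerprint = obj$fingerprint),
    class = "mtlcomb")
}

# One cell of the comparison harness: generate train/test data for a config
# and seed, CV-fit the joint mixed-loss model and the median-binarization
# baseline, and score both on the independent test draw. The prediction
# metric mirrors the (pseudo-)explained-variance reporting: regression tasks
# are scored by explained variance for the mixed-loss model and by
# pseudo-explained variance against the (train-threshold) binarized test
# labels for the baseline; classification tasks by pseudo-explained variance
# for both.
compare_cell <- function(cfg, seed, n_folds = 5L, n_test = 500L,
                         control = mtl_control()) {
  cfg$seed <- as.integer(seed)
  train <- generate_mixed_tasks(cfg)
  cfg_te <- cfg
  cfg_te$seed <- as.integer(seed + 104729L)
  cfg_te$n_per_task <- as.integer(n_test)
  test <- generate_mixed_tasks(cfg_te, truth = train$truth)

  score_method <- function(cv, binarization = NULL) {
    fit <- best_fit(cv)
    vals <- numeric(train$ts$t)
    for (i in seq_len(train$ts$t)) {
      tk <- test$ts$tasks[[i]]
      s <- predict_task(fit, tk$X, i)
      if (tk$type == "classification") {
        vals[i] <- pseudo_explained_variance(tk$y, s)
      } else if (is.null(binarization)) {
        vals[i] <- explained_variance(tk$y, s)
      } else {
        thr <- binarization[[test$ts$tasks[[i]]$name]]$threshold
        yb <- ifelse(tk$y > thr, 1, -1)
        vals[i] <- if (length(unique(yb)) < 2L) 0 else
          pseudo_explained_variance(yb, s)
      }
    }
    reg <- task_types(train$ts) == "regression"
    list(pred_mean = mean(vals),
         pred_reg = if (any(reg)) mean(vals[reg]) else NA_real_,
         pred_cls = if (any(!reg)) mean(vals[!reg]) else NA_real_,
         recovery = as.numeric(feature_recovery(fit, train$truth$support)),
         lambda_best = cv$lambda_best,
         support_size = length(fit$support))
  }

  cv_a <- cv_mtlcomb(train$ts, control, n_folds = n_folds, seed = seed)
  a <- score_method(cv_a)
  cv_b <- cv_mtlbin(train$ts, control, n_folds = n_folds, seed = seed)
  b <- score_method(cv_b, binarization = cv_b$binarization)

  data.frame(seed = seed, t = cfg$t, c = cfg$c, p = cfg$p,
             n_per_task = cfg$n_per_task, imbalance = cfg$imbalance_ratio,
             method = c("mtlcomb", "mtlbin"),
             pred_mean = c(a$pred_mean, b$pred_mean),
             pred_reg = c(a$pred_reg, b$pred_reg),
             pred_cls = c(a$pred_cls, b$pred_cls),
             recovery = c(a$recovery, b$recovery),
             lambda_best = c(a$lambda_best, b$lambda_best),
             support_size = c(a$support_size, b$support_size))
}

#' Run a repeat-and-average experiment grid
#'
#' For every configuration in `grid` and every seed, generates training and
#' independent test data, CV-fits the mixed-loss model and the
#' median-binarization baseline, scores both, and writes one CSV per cell
#' under `out_dir` plus a pooled `results.csv` and an across-seed
#' `summary.csv` (means and sds per configuration and method). A
#' reproducibility block (`run_info.json`: seeds, grid size, package
#' version) is written alongside. Completed cells are skipped on rerun, so
#' interrupted grids resume.
#'
#' @param grid List of [sim_config]s (e.g. from [analysis1_grid()] or
#'   [analysis2_grid()]).
#' @param out_dir Output directory.
#' @param seeds Integer vector of replicate seeds.
#' @param n_folds CV folds per fit. @param n_test Test samples per task.
#' @param control An [mtl_control].
#' @return The pooled results data.frame, invisibly.
#' @export
run_experiment <- function(grid, out_dir, seeds, n_folds = 5L, n_test = 500L,
                           control = mtl_control()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(seeds = seeds, n_configs = length(grid), n_folds = n_folds,
         n_test = n_test,
         package_version = as.character(utils::packageVersion("mtlcomb"))),
    file.path(out_dir, "run_info.json"), auto_unbox = TRUE, pretty = TRUE)
  rows <- list()
  for (g in seq_along(grid)) {
    for (s in seeds) {
      cell <- file.path(out_dir, sprintf("cell_g%03d_s%d.csv", g, s))
      if (file.exists(cell)) {
        rows[[cell]] <- utils::read.csv(cell)
        next
      }
      res <- tryCatch(
        compare_cell(grid[[g]], s, n_folds = n_folds, n_test = n_test,
                     control = control),
        error = function(e) {
          warning("cell (config ", g, ", seed ", s, ") failed: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(res)) next
      res$config <- g
      utils::write.csv(res, cell, row.names = FALSE)
      rows[[cell]] <- res
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  utils::write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
  agg <- stats::aggregate(
    cbind(pred_mean, recovery) ~ config + method + t + imbalance + n_per_task,
    data = results,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  agg <- do.call(data.frame, agg)
  utils::write.csv(agg, file.path(out_dir, "summary.csv"), row.names = FALSE)
  invisible(results)
}
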