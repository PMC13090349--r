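---
title: "Joint feature selection across mixed regression and classification tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint feature selection across mixed regression and classification tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlcomb)
```

## The problem

Biomedical studies often collect several related outcomes over one feature
space: a diagnosis (binary) next to severity scores or laboratory
measurements (continuous) in a clinical cohort, or a disease label next to
age in an expression cohort. When the scientific question is *which features
carry signal for all of these outcomes*, fitting each outcome separately and
intersecting the results wastes the shared structure, while naive joint
fitting of mixed outcome types is biased: the least-squares loss of a
regression task and the logistic loss of a classification task live on
different scales, so a single sparsity penalty prunes one task type long
before the other.

`mtlcomb` fits all tasks jointly as one linear multi-task model,

$$\min_{W}\; 2\,Z(W) \;+\; 0.5\,R(W) \;+\; \lambda\,\|W\|_{2,1}
\;+\; \alpha\,\|WG\|_F^2 \;+\; \beta\,\|W\|_F^2,$$

where column $w^{(i)}$ of $W \in \mathbb{R}^{p\times t}$ holds task $i$'s
coefficients,

* $Z(W) = \sum_{i=1}^{c} \frac{1}{N_i}\sum_n \log(1+e^{-y_n x_n^\top w^{(i)}})$
  is the mean logistic loss over the $c$ classification tasks
  ($y \in \{-1,+1\}$),
* $R(W) = \sum_{i=c+1}^{t} \frac{1}{N_i}\|y^{(i)} - X^{(i)} w^{(i)}\|_2^2$
  the mean squared error over the regression tasks,
* $\|W\|_{2,1} = \sum_j \|w_{(j)}\|_2$ sums the Euclidean norms of the
  *feature rows*, so a feature is dropped or kept for **all** tasks at once,
* $G = I_t - \tfrac1t \mathbf{1}\mathbf{1}^\top$ is the task-centering
  operator: $\|WG\|_F^2$ penalises the dispersion of each feature's
  coefficients around their cross-task mean and vanishes when a feature acts
  identically in every task,
* $\beta\|W\|_F^2$ is an ordinary ridge term that stabilises correlated
  features.

$\lambda$ is chosen by cross-validation; $\alpha$ and $\beta$ are user
priors (default 0).

## Why the weights 2 and 0.5

At $W = 0$ the gradient of one task's *unweighted* mean squared error is
$-\tfrac{2}{N} X^\top y$, while the logistic gradient is
$-\tfrac{1}{N} X^\top y\,\sigma(0) = -\tfrac{1}{2N} X^\top y$: for the same
$(X, y \in \{-1,+1\}^N)$ the least-squares gradient is exactly **four times**
the logistic gradient. Since the smallest penalty that keeps $W = 0$ optimal
— $\lambda_{\max}$, the start of the regularization path — is the largest
row norm of this zero-point gradient, the two task types would otherwise
start (and traverse) their paths on scales a factor 4 apart, and joint
selection at any single $\lambda$ would be dominated by the regression
tasks. Multiplying the logistic loss by 2 and the least-squares loss by 0.5
cancels the factor: both gradients become $-\tfrac1N X^\top y$, the
zero-point gradients coincide entrywise, and one $\lambda$ scale drives both
task types.

```{r alignment}
set.seed(1)
X <- matrix(rnorm(600), 60, 10)
y <- sign(X[, 1] - X[, 2] + rnorm(60, sd = 0.5))
both <- mixed_task_set(list(task_data(X, y, "classification", name = "cls"),
                            task_data(X, y, "regression",     name = "reg")))
g <- gradient_at_zero(both, mtl_control(standardize = FALSE))
max(abs(g[, 1] - g[, 2]))  # 0: columns identical under the default weights
gu <- gradient_at_zero(both, mtl_control(weight_class = 1, weight_reg = 1,
                                         standardize = FALSE))
range(gu[, 2] / gu[, 1])   # exactly 4 without the weighting
```

## Solver

The objective is convex: a smooth part (weighted losses + quadratic
penalties) plus the non-smooth $\ell_{2,1}$ term, whose proximal operator is
row-wise group soft-thresholding — each row of $W$ is shrunk by
$\max(0, 1 - \tau/\|w_{(j)}\|_2)$ and rows with norm below the threshold
become *exactly* zero. Selected supports are read off these exact zeros; no
post-hoc thresholding is ever applied.

`mtlcomb()` minimises by accelerated proximal gradient descent with the
Nesterov momentum sequence $t_{k+1} = (1+\sqrt{1+4t_k^2})/2$, which has the
$O(1/k^2)$ objective decay of first-order accelerated methods. Two
engineering choices matter:

* **Backtracking line search.** No cheap global Lipschitz constant exists
  for the logistic term, so the step is found by halving from the previously
  accepted step until the smooth part is bounded by its quadratic majorizer
  at the extrapolation point.
* **Monotone safeguard.** Plain accelerated steps are not monotone; if the
  accelerated candidate increases the objective, momentum is restarted and a
  plain proximal step is taken from the current iterate. The trace of
  accepted objective values is therefore non-increasing, which the tests
  assert.

Convergence is declared when the relative objective change
$|f_k - f_{k-1}|/\max(1, f_{k-1})$ falls below `tol` (default `1e-6`);
hitting `max_iter` (default 5000) returns the current iterate with
`converged = FALSE` and a warning rather than an error. The solver itself is
deterministic — all randomness in the package lives in data generation and
fold assignment.

Optional unpenalized per-task intercepts (`intercept = TRUE`) are updated by
plain gradient steps inside the same majorizer; the default is off, which
reproduces the bare objective above.

## The regularization path

The $\lambda$ sequence is estimated from the data in three steps:
$\lambda_{\max}$ is the largest row norm of the zero-point gradient (the
$\alpha$ and $\beta$ terms vanish at $W=0$ and do not enter); the smallest
value is $\lambda_{\text{ratio}} \cdot \lambda_{\max}$ (default ratio 0.01);
the sequence of `n_lambda` (default 50) values interpolates between them on
the log scale. `mtlcomb_path()` fits in decreasing order with warm starts,
so the first model is exactly null and support grows as $\lambda$ shrinks.

Per-task column z-scoring is on by default (`standardize = TRUE`) and is
applied *before* $\lambda_{\max}$ is computed, because scaling changes the
zero-point gradient; the choice is recorded in the path metadata and the
stored per-task centers/scales are re-applied at prediction time.
Coefficients are reported on the standardized scale;
`coef(fit, unstandardize = TRUE)` maps them back. Standardization also
mitigates the residual difference in coefficient *magnitudes* between task
types that the loss weighting does not remove.

## Selecting $\lambda$ and evaluating models

`cv_mtlcomb()` draws per-task folds (stratified over the two classes for
classification tasks; fold sizes within a task differ by at most one) from a
single seed, refits the warm-started path on each training portion at the
full-data $\lambda$ sequence, and accumulates the held-out weighted loss
$2Z + 0.5R$ summed over tasks — the training weighting, so both task types
contribute on one scale. The selected $\lambda$ minimises the mean CV loss;
ties prefer the larger (sparser) value, and a one-standard-error rule is
available (`one_se = TRUE`, default off). The CV criterion is this package's
choice, made once and used everywhere.

Metrics follow the field's conventions: AUC (Mann–Whitney, ties half) for
classification, explained variance $1 - SS_{res}/SS_{tot}$ for regression.
Where the two must be reported on one scale, the *pseudo*-explained variance
of a binary task is defined here as the squared Pearson correlation between
the linear score and the 0/1-coded labels (constant scores give 0 by
convention). Feature recovery against a known support of size $k$ is the
fraction of the support found among the top-$k$ features by coefficient row
norm, with precision/recall of the exact selected support attached for
transparency. Reproducibility across cohorts is measured by the Pearson
correlation of flattened coefficient matrices (`model_similarity`) and the
top-10 row-norm overlap (`top_k_overlap`). `nested_cv()` provides the
repeated nested-CV driver; when all tasks score the same subjects it also
evaluates the mean of the per-task z-scored predictors as a single
shared-marker score (z-scoring first, because the tasks' linear predictors
are on different scales).

## The median-binarization baseline

`as_mtlbin()`/`cv_mtlbin()` implement the conventional alternative: every
continuous outcome is split at its median (+1 strictly above, −1 at or
below — the tie rule is this package's explicit choice) and the resulting
all-classification task set runs through the identical machinery. The
classification loss weight stays at 2 so $\lambda$ scales remain comparable;
with a single loss type the relative balance is unaffected. The baseline
never sees the continuous values beyond the split, which is exactly the
information loss the mixed-loss model avoids.

## What the synthetic generator emulates

`generate_mixed_tasks()` draws iid standard-normal features, a base
coefficient vector with entries $\pm$`effect_scale` on a random shared
support of size `k_support`, and per-task Gaussian jitter (`share_noise`) so
supports coincide across tasks while magnitudes vary mildly — the structure
the joint $\ell_{2,1}$ penalty assumes. Regression outcomes add Gaussian
noise (`noise_sd`); classification labels are drawn $+1$ with probability
$\sigma(x^\top w + b_i)$, with the per-task offset $b_i$ bisected against
the realised uniform draws so the empirical positive fraction lands within
$\max(0.01, 1/n)$ of the target `imbalance_ratio` deterministically given
the seed. A ground-truth object (coefficients, support, offsets) accompanies
every draw and can be re-used to generate independent test data from the
same model.

Defaults are chosen once as a realistic mid-difficulty condition: `t = 4`
tasks (half classification), `p = 100` features, `n_per_task = 50`
(dimensionality ratio 0.5), `k_support = 10`, `effect_scale = 0.5` with
jitter 0.05, `noise_sd = 1` (regression signal-to-noise about 2.5:1),
balanced labels. `analysis1_grid()` sweeps the subjects-to-features ratio
0.1–0.8 at fixed `p`; `analysis2_grid()` crosses imbalance ratios
0.05–0.5 with task counts 4–20 (a ratio of exactly 0 is excluded as
degenerate — it admits no positive labels), with `c = t/2`.

What the generator does **not** emulate: correlated features (expression
data is strongly co-expressed), heavy-tailed or heteroscedastic noise,
task-specific supports, confounding, and batch structure. Tests passing on
these data certify the estimator's behaviour under its own assumptions —
shared sparse linear signal — not performance on any particular real
cohort.

The experiment harness (`run_experiment()`, `compare_cell`) scores models
on an independent test draw of 500 samples per task (300 in the scaled-down
test settings) from the training ground truth, comparing the mixed-loss
model's explained variance on continuous outcomes against the baseline's
pseudo-explained variance on the binarized ones, and both types' pseudo-
explained variance on classification tasks. The study sizes used in the
package's own checks — e.g. `p = 50`, `n = 100`, `k = 5` for the imbalance
comparison and `p = 100`, `n = 1000` for recovery under CV selection — are
the package's scaled-down renditions of the two simulation designs, chosen
to make the qualitative contrasts (joint selection beats binarization,
gains grow with task count, robustness to severe imbalance) reproducible as
trends.

## Numerical choices and degenerate inputs

* Softplus is evaluated as $\max(z,0) + \log(1+e^{-|z|})$, so margins up to
  $10^4$ in magnitude do not overflow.
* $\lambda_{\max}$ on data with no feature–outcome covariance (e.g. an
  all-zero outcome) raises a degenerate-input error rather than returning 0.
* Ties among rows sharing the maximal zero-point gradient norm need no
  tie-break: $\lambda_{\max}$ is their common value.
* Constant feature columns survive standardization (scale forced to 1,
  centred to zero) and are then never selected.
* Backtracking aborts with a numerical error if the step underflows
  ($<10^{-20}$), which only occurs for non-finite objectives.
* Model JSON stores doubles as 17-significant-digit strings so predictions
  survive a save/load round trip bit for bit.

## Limitations

The model is linear and its advantage concentrates in high-dimensional
regimes; in low dimensions it tracks ridge-type baselines. Only logistic
and squared-error losses are implemented — count outcomes (Poisson) and
more aggressive $\ell_{2,0}$-style selection are out of scope. The
$\ell_{2,1}$ penalty assumes the support is shared across tasks; features
relevant to only a subset of tasks are border cases the mean-regularized
term can soften but not remove. Missing values must be handled upstream.
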