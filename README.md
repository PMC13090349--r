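# mtlcomb

Joint feature selection across **mixed regression and classification tasks**
by linear multi-task learning.

Clinical and molecular studies routinely pair binary outcomes (diagnosis,
case/control status) with continuous ones (lab measurements, severity
scores, age) over the same feature space, and ask which features carry
signal for *all* of them. Fitting the tasks jointly with a row-wise sparsity
penalty answers that question directly — but mixing least-squares and
logistic losses naively biases the selection, because the two losses live on
different scales and one task type is pruned long before the other.

`mtlcomb` fits the convex objective

$$\min_W\; 2\,Z(W) + 0.5\,R(W) + \lambda \|W\|_{2,1}
  + \alpha \|WG\|_F^2 + \beta \|W\|_F^2$$

over the coefficient matrix $W \in \mathbb{R}^{p \times t}$ (features ×
tasks), where $Z$ sums the per-task mean logistic losses, $R$ the per-task
mean squared errors, $\|W\|_{2,1} = \sum_j \|w_{(j)}\|_2$ selects whole
feature rows jointly, $G = I - \tfrac1t \mathbf{1}\mathbf{1}^\top$ shrinks
each feature's coefficients toward their cross-task mean, and
$\beta\|W\|_F^2$ is a ridge stabiliser. The fixed weights (2 on the logistic
loss, 0.5 on the least-squares loss) are analytic, not tuned: at $W = 0$ the
unweighted least-squares gradient $-\tfrac2N X^\top y$ is exactly four times
the unweighted logistic gradient $-\tfrac1{2N} X^\top y$, and the weighting
cancels the factor, so both task types share one $\lambda$ scale and one
aligned regularization path.

The package provides:

* an accelerated proximal-gradient solver (Nesterov momentum, backtracking
  line search, monotone safeguard) with exact zero rows from group
  soft-thresholding — `mtlcomb()`;
* data-driven path estimation ($\lambda_{\max}$ from the zero-point
  gradient, log-scale interpolation, warm starts) — `mtlcomb_path()`,
  `lambda_max()`;
* cross-validated $\lambda$ selection and repeated nested CV —
  `cv_mtlcomb()`, `nested_cv()`;
* the median-binarization baseline that converts continuous outcomes to
  classes — `cv_mtlbin()`, `binarize_median()`;
* a seeded mixed-task generator with known shared support and controllable
  dimensionality ratio, label imbalance and task count —
  `generate_mixed_tasks()`, `analysis1_grid()`, `analysis2_grid()`;
* metrics: AUC, explained variance, pseudo-explained variance, feature
  recovery, cross-cohort model similarity and top-k overlap;
* CSV/JSON I/O, model serialization, a repeat-and-average experiment
  harness (`run_experiment()`), and a thin CLI
  (`inst/cli/mtlcomb.R`, verbs `simulate | fit | path | cvfit | predict |
  evaluate | compare`).

## Worked example

Four tasks (two classification, two regression) simulated with ten truly
informative features shared by all tasks:

```r
library(mtlcomb)
sim <- generate_mixed_tasks(sim_config(t = 4, c = 2, p = 100, n_per_task = 150,
                                       k_support = 10, seed = 42))
cv  <- cv_mtlcomb(sim$ts, mtl_control(n_lambda = 30), n_folds = 5, seed = 42)
cv
#> cv_mtlcomb: 5-fold CV over 30 lambdas; lambda_best = 0.1553 (index 13), CV loss 3.672
fit <- best_fit(cv)
fit
#> mtlcomb fit: lambda = 0.1553, 34/100 features selected, converged after 8 iterations
feature_recovery(fit, sim$truth$support)
#> [1] 1
evaluate_model(fit, sim$ts)$tasks
#>    task           type             metric value
#> 1 cls01 classification                auc 0.919
#> 2 cls02 classification                auc 0.858
#> 3 reg03     regression explained_variance 0.720
#> 4 reg04     regression explained_variance 0.746
```

The CV-selected model keeps 34 of 100 features; all ten planted features are
recovered (`feature_recovery = 1` means the top-10 rows by coefficient norm
are exactly the true support), and the same coefficient matrix predicts both
outcome types well — AUCs around 0.9 for the binary tasks and about 73%
explained variance for the continuous ones. The five largest coefficient
rows all lie in the planted support.

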