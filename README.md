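# nrlrl — noise-robust low-rank learning for EEG signal classification

Classifiers trained on raw biosignal samples are fragile: in clinical EEG a
sizeable fraction of recorded segments is corrupted outright by artifacts
and measurement noise, and those corrupted samples drag both the learned
representation and the decision boundary. `nrlrl` implements a joint
representation-and-classification model for exactly this setting —
epileptic-seizure EEG classification under sample-wise Gaussian corruption —
for researchers benchmarking noise-robust classifiers on Bonn-format
single-channel recordings or on structurally similar synthetic data.

## The model

Training samples `X` (features × samples, d × n) are coded over a
dictionary `A` of m training atoms, with whole-sample corruption diverted
into a column-sparse error matrix, label-aware neighbourhood shaping of the
codes, and an expectile-loss SVM trained on the codes, all in one problem:

```
min_{C,E,W,b}  λ‖E‖₂,₁ + γ Σₖ[ Σᵢ ℓ_p(u_{k,i}) + α‖wₖ‖² ] + Tr(C(ηL_eff + I)Cᵀ)
s.t.           X = AC + E,    1ᵀC = 1ᵀ
```

* `‖E‖₂,₁` (sum of column norms) removes whole corrupted samples, not
  scattered entries; its proximal operator zeroes columns below `λ/μ`.
* `L_eff` combines within-class and between-class k-NN heat-kernel graphs:
  minimising `Tr(C L_eff Cᵀ)` pulls same-class codes together and pushes
  different-class codes apart.
* `ℓ_p(u) = p·u²` on one branch of the margin residual
  `u = y(wᵀc + b) − 1` and `(1−p)·u²` on the other — the squared pinball
  (expectile) loss; `p = 0.5` recovers the symmetric LS-SVM.
* The Frobenius term (the `I` in the trace) is the rank surrogate: every
  subproblem stays a linear solve.

The constrained problem is optimised by ADMM: an exact joint stationarity
solve for `C` (the locality term couples all columns; the solver
diagonalises the Sylvester structure and folds the classifier blocks in by
a Woodbury correction), the exact ℓ₂,₁ proximal step for `E`, an IRLS
refit of the multi-class aLS-SVM, and dual ascent with growing penalty.
New samples are encoded by equality-constrained ridge regression over the
same dictionary and classified by one-vs-rest argmax.

The methods vignette (`vignettes/nrlrl-methods.Rmd`) documents every
numerical choice — the convexity shift on the locality operator, the two
sign and branch conventions and their trade-offs, convergence scaling —
and the model's known limitations.

## Worked example

Generate the desk-scale synthetic fixture (3 EEG-like classes × 10 traces
× 4,097 points, segmented into three 1,365-feature blocks), corrupt half
of the samples at 15% relative noise variance, fit on a stratified half,
and evaluate held out:

```r
library(nrlrl)

data <- synthetic_fixture(seed = 42)
data
#> Labeled dataset: 1365 features x 90 samples, 3 classes
#>   samples per class: 30, 30, 30

noisy <- inject_noise(data, noise_spec(0.5, 0.15, seed = 42))
split <- stratified_split(noisy$y, prop = 0.5, seed = 42)
train <- subset_samples(noisy, split$train)
test  <- subset_samples(noisy, split$test)

fit <- nrlrl(train, m = 45, k = 7)
fit
#> NRLRL model: 3 classes, dictionary 1365 x 45
#>   lambda = 1, gamma = 1, eta = 1, alpha = 1, p = 0.95
#>   ADMM: 65 iterations, converged; training accuracy 1.000

pred  <- predict(fit, test$X)
rates <- classification_rates(confusion_matrix(test$y, pred, 3))
c(rates$accuracy, rates$sensitivity, rates$specificity)
#> [1] 1 1 1
```

The fit report says the ADMM loop reached both feasibility tolerances
(reconstruction and unit column sums) in 65 iterations; the rates are the
held-out accuracy and the macro-averaged one-vs-rest sensitivity and
specificity, here all 1.0 — with half the samples corrupted, the
column-sparse error term absorbs the corruption and the 45 held-out
samples are all classified correctly. `run_experiment()` repeats this
pipeline over the full 6-cell noise grid (20/50% of samples × 5/10/15%
variance) with repeated splits and emits the benchmark-style results
table; `nrlrl_grid_search()` sweeps hyperparameters over their protocol
grids.

A command-line wrapper with `simulate` / `fit` / `predict` / `evaluate` /
`experiment` verbs is installed at
`system.file("cli/nrlrl.R", package = "nrlrl")`.

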