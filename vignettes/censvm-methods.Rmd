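---
title: "Censoring-aware SVM classification: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censoring-aware SVM classification: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censvm)
```

## The outcome being classified

Every model in this package predicts the binary outcome *event by the
administrative horizon τ* (coded y = +1) against *event-free at τ*
(y = −1). A right-censored record — follow-up ended before τ with no event —
has an unknown label; the package's purpose is to use such records anyway.
`binarize()` fixes the package-wide convention: events are records with
δ = 1 and T ≤ τ; nonevents completed follow-up (T ≥ τ, any δ); everything
else is censored. The positive class for sensitivity, specificity and F1 is
the event class, and the tie rule at a decision value of exactly zero (or a
predicted survival of exactly 0.5 for the Cox-type models) assigns +1.

## Censoring weights

The conditional-survival rule weights a record censored at $t_i$ by

$$\hat S_z(t_i) = \frac{\hat S(t_i + z)}{\hat S(t_i)},$$

the Kaplan–Meier estimate of remaining event-free for a further $z$ time
units given survival to $t_i$. The look-ahead is not dictated by the theory;
we set $z = \tau - t_i$, so the weight is exactly the probability of the
*event-free-at-τ* label being correct — the same label the classifier is
trained to produce. `z` is overridable in `assemble_training_sets()`.
Ratios that exceed 1 by floating-point error are clipped. The weight is
undefined when $\hat S(t_i) = 0$ and the code refuses it. Ties among event
times are aggregated into a single product-limit factor, and the curve is
evaluated right-continuously (the value *just after* the last event at or
before the query time). The proportional alternative $W_i = T_i/\tau$ is
retained for comparison.

The per-method sample construction follows from the weight:

* **wSVM** — the censored record joins its most probable class at weight
  equal to that probability ($y=-1$, $W=\hat S_z$ when $\hat S_z \ge 0.5$,
  else $y=+1$, $W = 1-\hat S_z$). An alternative reading — duplicating the
  record into both classes — changes the effective cost landscape very
  little for weights near 0 or 1 and is not implemented.
* **pSVM** — the censored record becomes an *uncertain* point with event
  probability $p = 1-\hat S_z$. The mapping from $p$ to decision-value
  bounds is a design choice: we use the linear margin map $m = 2p-1$ with a
  symmetric tube $m \pm \epsilon$ (default ε = 0.1), which sends $p = 0,
  0.5, 1$ to the −1 margin, the boundary and the +1 margin respectively.
* **LUPI** — censored records keep the label −1 (their observed state) and
  the censoring information travels in the privileged vector:
  $x^* = \hat S_z(t_i)$ under the conditional scheme (events pinned at 0,
  nonevents at 1) or $x^* = (T_i, W_i)$ under the proportional scheme with
  event weight pinned at 0.
* **inSVM** — censored records become the unlabeled set of a semi-supervised
  fit.

## The four trainers

All trainers are convex QPs solved deterministically. The weighted and
probabilistic SVMs and the invariance SVM are solved in the dual (box
constraints plus one equality) by the interior-point solver
`kernlab::ipop`; the LUPI trainer's primal has its slacks defined *as* the
correcting-function outputs, which makes the constraint rows rank-deficient
and breaks interior-point KKT systems, so it is solved by the active-set
solver `pracma::quadprog` over the kernel expansions of both spaces. Each
trainer's optimum is checked in the test suite against a generic QP typed
independently from the optimization problems (objective agreement to 1e-5).

The bias is recovered exactly rather than from averaged
Karush–Kuhn–Tucker conditions: given the optimal expansion, the primal
objective is convex piecewise-linear in $b$, so its minimizer lies at a kink
and is found by direct search. This removes the last meaningful gap between
the implementation and the QP oracles.

The invariance SVM constrains linear functionals of the decision function —
partial derivatives (gradient invariance) or the difference between the
local Gaussian-weighted average and the point value (averaging invariance) —
to an ε-tube at anchor points. Both functionals have closed-form RKHS
representers for the Gaussian kernel. For the averaging representers the
package uses the Gaussian-convolution identity, in which *variances* add:

$$z_{x_i}(x) = \Big(\tfrac{\sigma_k^2}{\sigma_k^2+\sigma_p^2}\Big)^{d/2}
  e^{-\|x-x_i\|^2/2(\sigma_k^2+\sigma_p^2)} - e^{-\|x-x_i\|^2/2\sigma_k^2},$$

with the pairwise inner product
$A - B_{ij} - B_{ji} + k(x_i,x_j)$, where $A$ smooths at total variance
$\sigma_k^2 + 2\sigma_p^2$. A width-sum variant of these formulas circulates
in the literature; it disagrees with direct numerical quadrature of the
defining integrals, so the convolution form is the default and the variant
is retained only behind `as_printed = TRUE` for auditing. Both gradient and
averaging closed forms are validated against finite-difference and adaptive
quadrature oracles in the tests. The bias term is carried inside the
invariance constraints (the tube constrains $\langle g, z_i\rangle + b$);
since the functionals annihilate constants this is a modelling convention,
kept for fidelity to the QP as posed.

Anchors default to *all* training points (labeled and unlabeled); the
censored-only choice and a seeded `anchor_subsample` are exposed because the
gradient invariance attaches $d$ representers per anchor and its QP grows
accordingly.

Degenerate inputs are handled explicitly: one-class labeled sets are
errors; weight-0 samples are provably inert (their dual box collapses to
zero); an empty anchor or unlabeled set reduces the invariance SVM to an
ordinary soft-margin SVM; a very large ε deactivates the invariance block.
`gamma_lupi` must be strictly positive — the standard-SVM limit is reached
numerically by small values (the tests verify monotone convergence over
γ ∈ {1, 0.1, 0.01, 0.001} with a well-conditioned correcting kernel; with a
near-singular correcting Gram the limit exists mathematically but slack
interpolation requires unboundedly large coefficients, so convergence
stalls at the conditioning floor).

Numerical floors: every Gram matrix used inside a QP carries 1e-8 diagonal
jitter (representer Grams are near-singular for close anchors); the LUPI
correcting block uses 1e-8 on both kernel blocks; `solve_qp` boxes unbounded
variables at ±1e4 and warns if a solution presses against that artificial
box.

## Comparators

`cox_fit` wraps the Breslow-tie partial-likelihood fit of the survival
package and attaches the Breslow baseline cumulative hazard, so
classification thresholds $\hat S(\tau\mid x) = \exp(-\hat\Lambda_0(\tau)
e^{x'\beta})$ at 0.5 and the ROC score is $-\hat S(\tau\mid x)$. Separation
(common at n ≈ 50 with 30 covariates) is caught and refit under an
escalating ridge penalty (θ = 1e-6, 1e-2, 1), with the fallback recorded on
the returned object.

Kernel Cox minimizes the penalized *negative* log partial likelihood
$-\ell(f) + \xi\|f\|_H^2$ over $f = \sum_i \alpha_i k(\cdot, x_i)$ by BFGS
with the analytic gradient from a zero start. The intercept is not
identifiable inside a partial likelihood and is absorbed into the baseline.
When the tuning protocol drives kernel Cox, the cost grid is reused as
inverse regularization, ξ = 1/C; the benchmark's source never prints its ξ
values, so this mapping keeps a single grid across methods.

## The synthetic benchmark generator

The generator emulates a biomedical cohort: 30 covariates in four
equicorrelation blocks (sizes 8, 8, 7, 7; correlations 0, 0.2, 0.5, 0.8),
means drawn once per dataset from U(0.03, 0.06), Gompertz event times
$T = \frac1\alpha\log\!\big(1-\frac{\alpha\log U}{\gamma e^{\langle\beta,
x\rangle}}\big)$ (a printed variant lacking the outer logarithm survives
behind `as_printed = TRUE`; only the standard inversion yields
Gompertz-distributed times, which the tests confirm against the closed-form
survival function), an 18-month administrative horizon, and dropout times
drawn from a scaled Beta on (0, τ): Beta(1,1) uniform, Beta(2,5) early
(positively skewed), Beta(5,2) late. The dropout admixture probability is
calibrated by bisection against a fixed-seed Monte-Carlo draw so the
expected censored-before-τ fraction hits the configured target (10–30%)
within 0.01. Non-proportional scenarios multiply the hazard by a shared
mean-1 gamma frailty (default variance 1, 5 equal groups; log-normal
alternative).

Two constants were frozen once at design time: the coefficient vector
(six entries of magnitude 1.277 — two in the independent block, two in the
ρ = 0.2 block, two in the ρ = 0.8 block), chosen by numerical integration so
the Bayes-optimal accuracy of the event-by-τ classifier is ≈ 0.90; and the
default Gompertz rate at shape α = 0.1 giving marginal survival 0.60 at 18
months. `calibrate_gompertz()` re-derives the rate at run time by bisection
(Monte-Carlo marginal over 20000 covariate draws, tolerance 0.0025) so the
calibration claim is always recomputed, never assumed. A Schoenfeld-type
check in the tests confirms the frailty configuration measurably violates
proportional hazards (rejection on the true risk score well above the
no-frailty null rate; the violation is real but not overwhelming at
variance 1 with five groups, so the test asserts separation from the null
rather than near-certain rejection).

What the generator does *not* emulate: informative or covariate-dependent
censoring, competing risks, non-Gaussian covariates, measurement error.
Passing benchmarks here show the estimators and protocols behave as
designed under the stated sampling model, not that any method is superior
on arbitrary clinical data.

## Evaluation protocols

`two_step_protocol()` implements the simulation protocol: step 1 fits every
grid combination on 10 fresh training draws and scores each on 10 fresh
labeled validation draws (the draws are shared across combinations, and the
selection statistic is the mean over the 100 validation accuracies — pooled
versus averaged selection coincide here since all validation sets have equal
size); ties prefer the smallest cost, then the smallest kernel width. Step 2
refits the winner on 10 new draws and reports mean and standard deviation
over 10 × 10 test evaluations. Test sets are drawn at the training-set size.

`nested_cv()` is the real-data protocol: outer 5-fold cross-validation with
inner 5-fold selection per outer fold, repeated on 10 bootstrap resamples.
The KM curve used for weighting is always fit on the training portion only
(weighting a fold with a curve that saw its test records would leak the
outcome). Records censored before τ in a test fold have unknown labels and
are excluded from metrics, with exclusion counts logged on the result.

Metrics: accuracy, Matthews correlation, normalized mutual information
(normalized by the arithmetic mean of the two label entropies; the geometric
alternative is a flag on the internal routine), rank-statistic AUC with ties
at 0.5, sensitivity/specificity with event = positive, and F1 of the event
class. Quantities undefined for single-class truth are reported as `NA`,
never as zero.

## Problem sizes used by the shipped checks

The test suite runs the full two-step protocol (10 × 10 tuning, 10 × 10
testing) for the desk-scale benchmark rows — Cox and linear pSVM at n = 300
and n = 50, averaging-invariance inSVM at n = 300 (60 subsampled anchors)
and n = 50 under frailty, gradient-invariance inSVM at n = 50 (10 anchors) —
with the tuning grid reduced to C ∈ {1, 10} and σ ∈ {2, 4} where tuning is
active. Monte-Carlo calibration checks use 5000–10000 draws. The acceptance
script reruns the Cox protocol at full scale and the survival calibration at
n = 10000. These sizes keep every shipped check reproducible on a single
CPU in minutes while leaving the estimators themselves unreduced.

## Known limitations

* The conditional weight assumes the training cohort's KM curve transfers
  to the population being classified; strong covariate shift breaks this.
* The invariance SVM is Gaussian-kernel only (the representers are derived
  for it), and the gradient variant's QP grows with n·d representers —
  subsampling anchors is the practical mitigation.
* Kernel Cox classification inherits the Breslow baseline's step
  granularity; beyond the last event time the cumulative hazard is frozen.
* Weighted variants of the invariance SVM (censoring weights entering the
  ε-tube costs) are deliberately not implemented: the semi-supervised QP as
  posed takes its unlabeled points unweighted, and grafting weights onto it
  would change the model rather than reproduce it.
* Left truncation, interval censoring, competing risks and covariate-
  dependent censoring are out of scope throughout.
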