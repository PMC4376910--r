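---
title: "Shift-intervention variable importance: model, estimators, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift-intervention variable importance: model, estimators, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(shiftvim)
```

# The problem

Longitudinal cohort data often record many time-varying covariates, any of
which might be a candidate "exposure" whose importance for a later outcome
we want to quantify.  Two features complicate this:

1. **Informative missingness.** A covariate at interval $j$ is measured only
   for a subset of subjects, and whether it is measured may depend on the
   subject's history (e.g., sicker patients get measured more often).
2. **Continuous exposures.** For a continuous variable there is no natural
   "treated vs. untreated" contrast; static interventions like "set
   $A = a_0$ for everyone" may be unsupported by the data.

`shiftvim` defines variable importance through *stochastic shift
interventions*, which stay close to the observed exposure distribution and
therefore require far weaker positivity conditions than static
interventions.

# Data structure and model

For a given cross-section (exposure variable $k$, measurement interval $j$,
outcome interval $j' \ge j$) the observed unit is

$$O = (W, C, CA, Y),$$

where $W$ are baseline covariates together with the *observation
indicators and observed values* of all covariates from the previous
interval, $C \in \{0, 1\}$ indicates whether the exposure $A$ was measured,
$CA$ is the exposure (observed only when $C = 1$), and $Y$ is the binary
outcome (e.g., death by end of interval $j'$).  Subjects who died before
interval $j$ are excluded from the cross-section; the at-risk count is
reported with every fit.

The nuisance parameters are

- $\bar Q(a, w) = E(Y \mid A = a, C = 1, W = w)$ — outcome regression among
  the observed;
- $g(a \mid w) = p(A = a \mid C = 1, W = w)$ — exposure density (continuous)
  or probability (binary) among the observed;
- $\varphi(w) = P(C = 1 \mid W = w)$ — observation (non-missingness)
  mechanism.

## Target parameters

**Continuous exposure (shift intervention).** For a shift $\delta > 0$,
the importance of $A$ is

$$\psi_c(\delta) = E_W\, E_g\{\bar Q(A + \delta, W) \mid W\} - E(Y),$$

the change in mean outcome if every observed exposure were increased
by $\delta$, holding everything else fixed.  For small $\delta$,
$\psi_c(\delta) \approx \delta \cdot E\{\partial_a \bar Q(A, W)\}$, a
nonparametric analogue of an adjusted regression coefficient.

**Binary exposure (probability shift).** The intervention replaces
$g(1 \mid w)$ with $g(1 \mid w) + \delta$, giving

$$\psi_b(\delta) = E_W\{ \tilde m(W) \} - E(Y), \qquad
\tilde m(w) = (g(1 \mid w) + \delta)\, \bar Q(1, w) +
              (1 - g(1 \mid w) - \delta)\, \bar Q(0, w).$$

This is well defined only when $\delta < \min_w \{1 - g(1 \mid w)\}$; the
package enforces this bound strictly and refuses to extrapolate
(`positivity` error).

## Identification assumptions

- **Missingness at random given $W$:** $C \perp Y \mid W$ within the
  cross-section (all common causes of measurement and outcome are in $W$).
- **Positivity of observation:** $\varphi(w) > 0$; in practice
  `positivity_check()` flags cells where $\hat\varphi$ is very small.
- **Exposure positivity:** for the continuous case, the shifted value
  $a + \delta$ stays in the support; for the binary case, the bound
  above.  Shift interventions are chosen precisely because these
  conditions are mild for small $\delta$.

The parameter is a *statistical* functional; it has the causal
interpretation "effect of the shift" only under the usual
no-unmeasured-confounding conditions for the exposure itself.

# Estimators

All four estimators are available from `shiftvim()` and the lower-level
`vim_*()` functions.

## Efficient influence function

The canonical gradient of $\psi_c$ at $P$ is

$$D(O) = \frac{C}{\varphi(W)}\left\{
  \frac{g(A - \delta \mid W)}{g(A \mid W)}\,(Y - \bar Q(A, W))
  + \bar Q(A + \delta, W) - m(W)\right\} + m(W) - Y - \psi_c,$$

with $m(w) = E_g\{\bar Q(A + \delta, W) \mid W = w\}$; the binary case
replaces the density ratio by $g^*(A \mid W) / g(A \mid W)$ and $m$ by
$\tilde m$.  The influence function has three parts: a weighted outcome
residual, an exposure-score term, and a derivative in the direction of the
marginal distribution of $W$.

## Estimating equations (EE)

`vim_ee()` plugs the fitted nuisances into $D$ and solves
$\frac1n \sum_i D(O_i) = 0$ in $\psi$, which is available in closed form.
The estimator is doubly robust: consistent if either $\bar Q$ or the pair
$(g, \varphi)$ is consistent, and efficient if all are.

## Targeted minimum loss-based estimation (TMLE)

`vim_tmle()` iterates two fluctuation steps until the empirical mean of the
influence function is below $\hat\sigma / (\sqrt n \log n)\cdot \sqrt n$
(i.e., $|\bar D_n| < \hat{\mathrm{se}} / \log n$):

1. An **outcome fluctuation**: logistic regression of $Y$ on the clever
   covariate $\frac{C}{\varphi}\frac{g(A - \delta \mid W)}{g(A \mid W)}$
   with $\mathrm{logit}\,\bar Q$ as offset, updating $\bar Q$ everywhere it
   is evaluated (at $A$, at $A + \delta$, and on the quadrature grid).
2. A **density tilt**: a one-parameter exponential tilt
   $g_\eta(a \mid w) \propto g(a \mid w)\, e^{\eta\, \bar Q(a + \delta, w)}$
   fitted by weighted maximum likelihood (weights $C/\varphi$).  For the
   binary case this is a logistic tilt of $g(1 \mid w)$ in the direction
   $\bar Q(1, w) - \bar Q(0, w)$.

The final estimate is the plug-in under the updated nuisances, so it always
respects the parameter space ($E(Y^{\text{shift}}) \in [0, 1]$ for a binary
outcome), unlike the EE estimator.

## Comparison estimators

- `vim_gcomp_ipmw()`: G-computation with inverse-probability-of-missingness
  weights, with stepwise main-terms parametric nuisance models.  Not
  doubly robust; included as the "standard practice" comparator.
- `vim_unadjusted()`: difference of the empirical shifted mean among the
  observed and the empirical outcome mean; ignores $W$ entirely.

## Nuisance estimation

Nuisances are fitted by a discrete-plus-convex **super learner**
(`sl_fit()`): cross-validated risk over a library (GLM, stepwise GLM,
Bayesian-flavoured GLM with ridge-type shrinkage, GAM via `mgcv`, a
piecewise-linear adaptive regression candidate, and the marginal mean),
combined by simplex-constrained weight optimisation on the CV risk.
The continuous exposure density is fitted by `density_fit()`:
cross-validated stacking of histogram candidates (number of bins $\times$
bin placement), each fitted by sequential hazard logistic regressions, with
stacking weights maximising the CV log-density.

# Numerical choices

**Union-cell representation.** The stacked histogram density is piecewise
constant on the union of the candidates' bin edges, so all integrals
against $g(\cdot \mid w)$ are *exact* sums over union cells — no quadrature
error in $m(W)$ or in the tilt's normalising constant.

**Node-cell refinement.** $\bar Q(a + \delta, w)$ is *not* piecewise
constant, so each union cell is subdivided into `nodes_per_bin` equal
sub-cells (default 10, via `shiftvim_control()`) carrying equal probability
shares, and $\bar Q$ is evaluated at sub-cell midpoints.  Working at
sub-cell resolution makes the density tilt's sufficient statistic coincide
with the pointwise $\bar Q(A_i + \delta, W_i)$ appearing in the influence
function, so the TMLE can actually drive $\bar D_n$ to zero rather than
stalling at the within-bin discretisation gap.

**Memory.** $\bar Q$ grid evaluation is chunked so temporaries stay near
$5 \times 10^6$ rows regardless of $n$; large-sample checks use coarser
controls (`grid_cells`, `nodes_per_bin`).

**Stability.** Probabilities are clipped away from $\{0, 1\}$ only when the
outcome is binary; density evaluations are floored; the binary-case tilt
keeps $g(1 \mid w)$ inside $[\epsilon, 1 - \delta - \epsilon]$ so the
shifted probability remains valid.

# The longitudinal orchestration layer

`run_study()` forms every cross-section (variable $k$, measurement
interval $j$, outcome interval $j' \ge j$) via `extract_cross_section()`,
fits the requested estimators per cell with per-cell derived seeds, and
collects a long estimates table plus a failures table (degenerate cells —
constant exposure, single-class outcome — are recorded, not fatal).
`rank_vims()` then ranks variables within each outcome interval by the
absolute TMLE estimate among those significant at level $\alpha$, in the
spirit of a screening analysis; `write_vim_table()` renders the report.

# Simulation designs shipped with the package

The generators in `generate_worked_example()`, `generate_confounded()` and
`generate_longitudinal()` are the package's own verification designs:

- *Worked examples* (`worked_linear`, `worked_logistic`): a continuous
  exposure $A_1 \sim 0.1 + 0.8\,\mathrm{Beta}(2,2)$, a dependent binary
  $A_2 \mid A_1 \sim \mathrm{Bern}(A_1)$, and a linear or logistic outcome.
  The linear design gives $\psi_c = \psi_b = \delta$ *exactly*, an
  analytical anchor; the logistic design's truth is computed by
  `true_psi()` via quadrature or $\ge 10^6$-draw Monte Carlo.
- *Confounded design*: two uniform baseline covariates driving missingness,
  exposure, and outcome through a nonlinear ($z = 4(w - \tfrac12)^2$)
  pattern, so that main-terms working models are genuinely wrong.  Used for
  the double-robustness grid: estimators fed (right, right), (right,
  wrong), (wrong, right) and (wrong, wrong) nuisance pairs should be
  unbiased in the first three cells only, while Gcomp/IPMW is biased and
  less efficient.
- *Longitudinal generator* (`dgp_spec()`): a sequential NPSEM with
  history-dependent missingness, covariate drift, and a discrete-time
  hazard; post-death rows are structurally unobserved.

Replication sizes used in the package's own tests (200 replicates at
$n = 2000$ for bias/coverage; 100 replicates for the robustness grid) were
chosen by a priori power calculations so that the pass/fail thresholds
(bias within twice the Monte Carlo standard error; coverage in
$[0.92, 0.98]$; $|t| > 3$ for the cells designed to be biased) have high
power without being knife-edge.

# Limitations

- The MAR-given-$W$ assumption uses only the *previous* interval's
  covariates by default (`history = 1`); richer histories enlarge $W$ and
  the positivity burden.
- Inference is per-cell Wald inference from the influence function;
  no multiplicity adjustment is applied across the variable/interval grid
  (the ranking is intended as screening, not confirmatory testing).
- The continuous-density model is piecewise constant; very spiky exposure
  densities would need a larger candidate grid.
- Sample-splitting (cross-fitting) of nuisances is not implemented; the
  super learner's cross-validated selection mitigates, but does not
  replace, Donsker-type conditions.
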