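---
title: "Markov chains with rewards: moments and sensitivity of lifetime reproductive output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov chains with rewards: moments and sensitivity of lifetime reproductive output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrostats)
```

## The model

Lifetime reproductive output (LRO) — the total number of offspring an
individual produces before it dies — is a random variable even when every
individual experiences exactly the same vital rates. Two lotteries drive
it: the random *pathway* an individual takes through the stages of its
life cycle (when it grows, how long it survives), and the random
*per-step reproduction* it realizes at each stage along that pathway.
`lrostats` computes the exact distribution summaries of LRO implied by any
age- or stage-classified matrix population model, separates those two
sources of variance, and differentiates everything analytically with
respect to the underlying rates.

The life cycle is a finite-state, discrete-time absorbing Markov chain.
The transient (living) stages are governed by the column-oriented
transition matrix $U$ ($\tau \times \tau$; column $j$ gives the
probabilities of moving from stage $j$ to each stage in one time step);
death is one or more absorbing states. The full chain is column-stochastic,

$$P = \begin{pmatrix} U & 0 \\ M & I_\alpha \end{pmatrix},
\qquad M = \mathbf{1}^\top - \mathbf{1}^\top U \ \ (\alpha = 1),$$

and we require the spectral radius of $U$ to be strictly below 1, so every
individual is eventually absorbed. The fundamental matrix
$N = (I - U)^{-1}$ collects expected stage occupancy times; its column
sums are life expectancies.

Each transition $j \to i$ (including the transition into death, unless
reproduction is conditioned on parental survival) carries a random
reproductive reward whose raw moments are stored in matrices $R_k$
($s \times s$, $s = \tau + \alpha$). With stage-specific fertility the
rows of $R_1$ all equal the padded mean-fertility vector
$(f^\top \mid 0)$. Higher moments come from one of four models:

| model      | per-step second moment        | when appropriate                     |
|------------|-------------------------------|--------------------------------------|
| Bernoulli  | $R_2 = R_1$                   | single offspring; $f$ = probability  |
| Poisson    | $R_2 = R_1 + R_1 \circ R_1$   | multiple offspring, equal chances    |
| fixed      | $R_2 = R_1 \circ R_1$         | deterministic mean output            |
| empirical  | supplied                      | measured clutch-size moments         |

## Moments of LRO

Writing $\tilde\rho_k$ for the $\tau$-vector of $k$-th raw moments of
remaining LRO by starting stage, $Z = (I_\tau \mid 0)$ for the selection
matrix, and $\tilde R_k = Z R_k Z^\top$, the moments satisfy the exact
closed-form recursion implemented in `lro_moment_vectors()`:

$$\tilde\rho_m = N^\top Z (P \circ R_m)^\top \mathbf{1}_s
 + \sum_{k=1}^{m-1} \binom{m}{k} N^\top
   (U \circ \tilde R_{m-k})^\top \tilde\rho_k .$$

The direct term accumulates the $m$-th reward moment of the next
transition (the dying step included); the cross terms propagate products
of lower-order accumulations along surviving transitions — which is why
they use the transient submatrices $\tilde R_k$ rather than $R_k$. For
$m = 1$ the recursion collapses to the familiar net reproductive rate
accounting, $\tilde\rho_1(1) = f^\top N e_1 = R_0$, an identity the test
suite asserts to $10^{-10}$.

From $\tilde\rho_1, \tilde\rho_2$ (and $\tilde\rho_3$ for skewness) come
the variance $V = \tilde\rho_2 - \tilde\rho_1 \circ \tilde\rho_1$, SD, CV,
and Crow's opportunity for selection $\mathcal I = CV^2 = V / \tilde\rho_1^2$
— the maximum proportional per-generation selective gain *if* all the
variance were heritable. Because the model contains no heterogeneity at
all, the $\mathcal I$ it produces quantifies the *apparent* opportunity
for selection created by individual stochasticity alone: a neutral
baseline against which observed variance should be judged before invoking
genetic differences.

Where the mean is zero, CV and $\mathcal I$ are reported as `NaN` markers
rather than errors, so downstream tabulation keeps working.

### Partitioning the variance

By the law of total variance, $V = V_\text{between} + V_\text{within}$.
`partition_variance()` computes $V_\text{between}$ by re-running the
variance calculation under the *fixed* reward model — same mean
fertilities, zero per-step noise — which retains exactly the variance due
to pathway differences; the within-pathway component follows by
subtraction. The decomposition is additive to $10^{-10}$ relative by
construction, and the fixed model's own partition has
$V_\text{within} = 0$ identically.

## Sensitivity analysis

Let $\theta$ be any parameter vector (length $p$). A
`perturbation_map` carries $d\,\mathrm{vec}\,U / d\theta^\top$
($\tau^2 \times p$) and $d\,\mathrm{vec}\,R_i / d\theta^\top$
($s^2 \times p$); with a single absorbing state,
$d\,\mathrm{vec}\,P$ follows automatically because the death row absorbs
whatever the columns of $U$ lose. Differentiating the moment recursion
gives, per order $m$,

$$\frac{d\tilde\rho_m}{d\theta^\top} = N^\top \Big[ V_m
 + \sum_{k=1}^{m-1} \binom{m}{k} W_{k,m-k} + X_m \Big],$$

where $V_m$ carries the direct effect through $P$ and $R_m$, $X_m$ the
effect of $U$ on the fundamental matrix, and $W_{k,j}$ — which contains
the lower-order sensitivities, making the computation bottom-up — the
effect through surviving transitions. The terms are standard
matrix-calculus contractions involving the vec-permutation matrix
$K_{m,n}$ (`vec_permutation()`); internally every product of the form
$(v^\top \otimes I)K\,B$ or $(\mathbf 1^\top \otimes Z)K\,A$ is evaluated
by reshaping columns back into matrices, so no $s^2 \times s^2$ operator
is ever materialized and $\tau$ in the hundreds stays tractable.

Statistic derivatives follow by the chain rule
(`statistic_sensitivity()`):
$dV = d\tilde\rho_2 - 2\mathcal D(\tilde\rho_1)\, d\tilde\rho_1$,
$dSD = \tfrac12 \mathcal D(SD)^{-1} dV$,
$dCV = \mathcal D(\tilde\rho_1)^{-1} dSD - \mathcal D(SD)\mathcal
D(\tilde\rho_1)^{-2} d\tilde\rho_1$, and
$d\mathcal I = 2\,\mathcal D(CV)\, dCV$. Elasticities are
$\mathcal D(\xi)^{-1} (d\xi/d\theta^\top) \mathcal D(\theta)$, defined for
positive outputs and nonnegative parameters; columns with $\theta_j = 0$
are set to the limiting value 0 and flagged by construction.

### Ready-made perturbation maps

* **Age-classified mortality** (`age_classified_pmap(, "mu")`): survival
  sits on the subdiagonal as $e^{-\mu_x}$, so
  $dU_{x+1,x}/d\mu_x = -e^{-\mu_x}$ and each hazard touches exactly one
  column. Fertility maps under Bernoulli reproduction share one
  broadcasting derivative across all moment orders.
* **Stage-classified survival** (`stage_classified_pmap()`): via the
  factorization $U = G\Sigma$ (survival $\sigma$ on the diagonal of
  $\Sigma$, conditional transitions in column-stochastic $G$),
  $dU[,j]/d\sigma_j = G[,j]$ and $dU[,j]/d\mu_j = -\sigma_j G[,j]$.
  When no survival vector is given, `decompose_stage_model()` takes
  $\sigma$ as the column sums of $U$ — the unique choice making $G$
  column-stochastic, stated explicitly because the factorization is
  otherwise non-unique.
* **Compensated growth** (`compensated_growth_pmap()`): $G$ is
  column-stochastic, so perturbing $g_{ij}$ alone is meaningless; the
  rest of column $j$ absorbs the change in proportion to its current
  size, $dg_{kj} = -g_{kj}/(1 - g_{ij})$ for $k \neq i$. Every direction
  keeps the column sums at 1 to first order. If the perturbed entry
  itself equals 1 the rest of the column is zero and there is nothing to
  compensate with; the proportional rule then degenerates smoothly to the
  plain unit perturbation (each would-be compensating entry has weight
  zero), which is the convention applied — it is exactly what is needed
  to ask "what if a class that currently never grows retained
  individuals slightly less?".
* **Fertility moments** (`fertility_pmap()`): three views. Holding
  variance fixed while moving the mean forces $df_2 = 2 f_1 \circ df_1$;
  holding the mean fixed while moving the variance gives $dR_1 = 0$ — so
  mean LRO is *exactly* insensitive to fertility variance — and
  $df_2 = dv$; the linked mode follows the parametric model (for Poisson,
  $dR_2 = (I + 2\mathcal D(\mathrm{vec}R_1))\,dR_1$, and similarly for
  the third moment). The two moment-decoupled modes are defined for
  orders 1–2 and the map refuses higher orders rather than silently
  treating the third-moment derivative as zero; the Bernoulli model ties
  mean and variance together, so its variance-fixed mode is an error by
  construction.

A useful structural check that falls out of the machinery: mean LRO is
degree-1 homogeneous in $R_1$, so the elasticities of the mean to the
stage fertilities sum to exactly 1 from every starting stage.

## Validation strategy

Every analytic result is checked against an independent route:

* the fundamental matrix against truncated Neumann series
  $\sum_k U^k$;
* the single-stage model (survival $p$, Bernoulli fertility $\varphi$)
  against direct enumeration over the geometric lifetime, including the
  closed forms $E = \varphi/(1-p)$ and
  $V = \varphi(1-\varphi)/(1-p) + \varphi^2 p/(1-p)^2$ and the
  conditional-variance partition, to $10^{-10}$;
* all moments and the variance partition against an individual-based
  simulator (`simulate_trajectories()`) that replays the chain literally —
  draw a reward from the current stage's distribution, then move by the
  corresponding column of $P$ — with 3-standard-error agreement bands at
  $10^5$ trajectories;
* every sensitivity, for every perturbation map, against finite
  differences of the *rebuilt* pipeline on 50 random small life cycles
  ($\tau \le 5$), at $10^{-5}$ relative with a $10^{-8}$ absolute floor.

The finite-difference oracle uses Richardson-extrapolated central
differences, $(4D(h/2) - D(h))/3$ with base step
$2\times10^{-4}\max(1, |\theta_j|)$, halved automatically if a step
leaves the feasible region. The larger base step matters: with
$h = 10^{-6}$, double-precision roundoff ($\varepsilon |f| / h$) on
statistics of magnitude $10^3$–$10^4$ (Crow's index on random models)
leaves absolute noise around $5\times10^{-7}$, which swamps
small-derivative entries and would make a $10^{-5}$ relative bar
unattainable *for a correct implementation*; the extrapolation removes
the truncation penalty the larger step would otherwise pay.

### The synthetic generator

`generate_synthetic_model()` draws random valid life cycles for the
property suites. The `stage_like` profile draws the columns of $G$ from a
flat Dirichlet, stage survival $\sigma \sim U(0.2, 0.99)$, and mean
fertility $\sim U(0.05, 0.95)$ in every stage — positive everywhere so
that CV and $\mathcal I$ are defined from every starting stage, and below
1 so the same draw is valid under Bernoulli and Poisson rewards. The
`age_like` profile draws hazards $\mu \sim U(0.05, 0.4)$ and a unimodal
Gaussian-window fertility schedule peaking mid-life (maximum
$\sim U(0.3, 0.9)$), with certain death at the end of the schedule.
These generators emulate the *structure* of real demographic inputs
(column-stochastic conditional transitions, sub-unit survival, smooth
fertility windows); they do not emulate empirical features such as
senescent mortality plateaus, strongly size-dependent fecundity spanning
orders of magnitude, or zero-fertility juvenile classes. Passing tests
therefore certify the mathematics on generic valid inputs, not the
demographic realism of any particular species model.

## Numerical choices and degenerate inputs

* $N$ is obtained by LU solves against identity columns
  (`solve(I - U, diag(tau))`), never by cofactor inversion; applications
  of $N^\top$ in the recursions are likewise solves against
  $(I - U)^\top$.
* The absorbing-chain requirement is a spectral-radius check with
  tolerance $10^{-10}$; near-singular $(I - U)$ (condition number above
  $10^{14}$) is refused rather than silently inverted.
* Validation tolerances: column-stochasticity to $10^{-12}$; the
  partition additivity and the $R_0$ identity to $10^{-10}$ relative.
* Zero-survival stages decompose with $G[,j] = e_j$ (unreachable by a
  survivor, any convention works; this one keeps $G$ stochastic).
* Tiny negative variances from cancellation (below $10^{-10}$ relative)
  are clamped to zero; anything larger raises a moment-inconsistency
  error.
* Rewards are collected on the dying transition by default — the
  convention consistent with broadcasting fertility across all
  destination rows — and `require_parental_survival = TRUE` zeroes the
  absorbing rows of every $R_k$ instead.
* Stage indexing is 1-based everywhere in the interface.

One caution worth stating for users of published projection matrices:
when a stasis probability of a highly fecund class is close to 1, the
expected residence time $1/(1 - u_{jj})$ — and with it every LRO
statistic — is extremely sensitive to its last printed digit. A matrix
rounded to two decimals with $u_{jj} = 0.99$ leaves the true mean LRO
uncertain by tens of percent across the rounding interval. Statistics
computed here are exact for the matrix *as given*; agreement with values
published from higher-precision source data should only be expected to
the precision the input matrix itself carries.

## Problem sizes used in the shipped validation

The test suite runs 50 random models ($\tau \in \{2,\dots,5\}$) through
all six perturbation maps in the finite-difference master check, and
Monte-Carlo comparisons at $10^5$ trajectories for the bundled hemlock
model plus three synthetic models; the whole suite completes in well
under a minute on a single core. These sizes were chosen to exercise
every code path with comfortable statistical power; all of the analytic
machinery itself is deterministic and scales to $\tau$ in the hundreds.

## Known limitations

* Skewness is computed from the third moment vectors; no formulas beyond
  the third moment's standardization are provided, though
  `reward_moments()` extends parametric reward models to arbitrary order.
* Multi-absorbing-state chains ($\alpha > 1$) are fully supported in the
  moment pipeline, but their perturbation maps require the caller to
  supply $d\,\mathrm{vec}\,P/d\theta^\top$ (there is no generic rule for
  how parameters move probability between competing absorbing states).
* Time-invariant environments only: one $U$ and one reward structure per
  analysis.
* The simulator supports Bernoulli, Poisson, fixed, and two-point
  empirical rewards; an empirical distribution specified only by moments
  beyond the second cannot be sampled (the analytics, of course, can use
  it).
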