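---
title: "Stage-structured survival from mark-recapture-recovery data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-structured survival from mark-recapture-recovery data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gyrsurv` estimates annual survival of long-lived raptors — written for
the Icelandic gyrfalcon (*Falco rusticolus*) ringing programme, but generic
over any single-site scheme with the same data structure — from capture
histories that mix rare live resightings with dead recoveries of ringed
birds. This vignette documents the model, the estimation machinery, the
synthetic-data generator used for validation, and the numerical and design
choices a maintainer should know about.

## The observation model

Each marked bird contributes one encounter code per calendar year from its
ringing year onward: `L` (seen, resighted, or physically recaptured alive),
`D` (ring recovered from a carcass), or `U` (not encountered). The true
state of the bird is hidden and follows a three-state Markov chain:

1. **alive**,
2. **recently dead** — a carcass still present in the field (Iceland's
   cold climate makes year-old carcasses recoverable),
3. **long dead** — no longer observable; absorbing.

Over one year the hidden state moves by

$$\Gamma(s, \eta) = \begin{pmatrix} s & 1-s & 0 \\ 0 & \eta & 1-\eta \\ 0 & 0 & 1 \end{pmatrix},$$

where $s$ is the bird's annual survival probability for that interval and
$\eta$ the annual carcass-persistence probability. Conditional on the
hidden state, the year's code is emitted by

$$O(p, r) = \begin{pmatrix} p & 0 & 1-p \\ 0 & r & 1-r \\ 0 & 0 & 1 \end{pmatrix}$$

over columns $(L, D, U)$: live birds are detected with probability $p$,
carcasses recovered with probability $r$. A dead recovery ends the
informative part of a history (the ring is collected); events recorded
after a `D` are treated as data errors and rejected at import rather than
silently dropped.

Survival is stage-structured: a bird ringed as a nestling survives its
first three annual transitions (ages 0, 1, 2) with the juvenile rate and
afterwards with the adult rate $s_2$ ("age 3 and above" is the adult
stage; `juvenile_transitions = 2` is exposed as a configuration switch
since the stage boundary could defensibly be read as two transitions).
Adult-trapped birds are assigned age 3 at trapping — their exact age is
unknown but they are territorial adults, and only the stage matters.

Four juvenile-survival structures are provided:

* **Model A** — constant $s_1$;
* **Model B** — $s_1(t) = \mathrm{logistic}(\mu_{s_1} + \beta x_{1,t})$
  with $x_1$ the standardized prey (rock ptarmigan) density index; an
  alternative *threshold* parameterization
  $s_1(t) = \mathrm{logistic}(-\gamma(x_{1,t} - \mu_x))$, $\gamma > 0$, is
  available;
* **Model C** — adds standardized winter (October–March) mean temperature
  $x_2$ and winter mean log-precipitation $x_3$;
* **Model S** — a deliberately wrong control with a single survival rate
  shared by juveniles and adults, used to verify that model comparison
  rejects a bad model decisively.

The likelihood of one history conditions on the marking event (the first
capture is not modelled, the universal convention for conditional
capture-recapture likelihoods) and is computed by the forward algorithm:
a three-vector of state masses is propagated through $\Gamma$ and weighted
by the observed code's emission column each year, with per-step
renormalization so 47-year histories cannot underflow. The recursion is
implemented in C++; identical histories are pooled (one forward pass per
distinct pattern, multiplicities applied afterwards), which reduces a
1,669-bird dataset to under 200 distinct patterns. A pure-R recursion
(`forward_loglik()`) is kept as the reference implementation and is tested
against exhaustive enumeration over all hidden-state paths.

## Covariates

The winter assigned to year $t$ spans October of $t$ through March of
$t+1$, so that it drives survival over the interval $(t, t+1)$ — the
winter a cohort hatched in year $t$ must get through. Monthly
log-precipitation is log-transformed *before* winter-averaging; zero
monthly totals are an error unless an explicit offset is opted into.
Yearly series are standardized (sample sd, $n-1$ denominator) after
winter-averaging, and the constants are stored for back-transformation.
Whether standardization happens before or after winter-averaging was an
open choice; standardizing the yearly winter series is the simpler
pipeline and makes the regression coefficients directly comparable across
covariates, which is their purpose.

## Priors and inference

The default weakly informative prior set: $\mathcal U(0,1)$ for survival
probabilities, $\mathcal U(0, 0.5)$ for $p$, $r$ and $\eta$ (all known to
be well below one half), $\mathcal N(0,1)$ for logit-scale intercepts and
regression coefficients, and half-$\mathcal N(0,1)$ for the positive
threshold slope $\gamma$ (the original analysis states only that the slope
is constrained positive; the half-normal is this package's choice). A
Beta-prior set with configurable shapes (default Beta(1,1), rescaled to
each support) is available for robustness checks; the exact Beta shapes
used in the original robustness analysis are not published, so none are
hard-coded.

Sampling is adaptive random-walk Metropolis on the unconstrained scale
(interval-logit for probabilities, log for $\gamma$, identity for
coefficients, with the Jacobian correction), targeting the exact posterior
$\propto$ likelihood $\times$ prior. During warmup the proposal covariance
is estimated recursively (Haario-style) and a global step size is tuned
toward 23% acceptance; both are frozen afterwards, so the retained chain
is a valid Markov chain. Chains initialize from independent prior draws,
and the initial proposal scale follows each parameter's prior scale so
that tightly concentrated priors (e.g. a coefficient sd of $10^{-3}$ in
nesting checks) adapt correctly. The default run — 3 chains, 1,000 warmup,
1,000 retained iterations — mirrors the published analysis, which used a
Hamiltonian sampler; a random-walk sampler needs more iterations for the
same effective sample size, so calibration experiments in the test suite
run 2,000 + 4,000 per chain (a fit of the full 47-year, 1,669-bird
scenario takes on the order of a few seconds).

Convergence is monitored with the split rank-normalized $\hat R$ (the
larger of the bulk and folded/tail statistics), with a pipeline warning at
1.01. Posterior summaries are pooled-chain means and central 95% quantile
intervals computed on the probability scale — note the mean of
logistic-transformed draws is not the logistic of the mean, so summaries
of derived survival curves are computed draw-wise.

## Model comparison

Marginal likelihoods are estimated by iterative bridge sampling with the
optimal (Meng–Wong) bridge function: the first half of each chain fits a
moment-matched multivariate-normal proposal on the unconstrained scale,
the second half and an equal number of fresh proposal draws enter the
bridge iteration, run to a relative tolerance of $10^{-8}$ (cap 1,000
iterations, flagged if not converged). The Monte-Carlo standard error uses
the standard relative-variance formula for the two bridge averages; chain
autocorrelation is not corrected for, so the reported SE is mildly
optimistic. The estimator is validated against closed-form evidence
(Beta-Binomial and Normal-Normal toys) in the tests.

Predictive comparison uses Pareto-smoothed importance-sampling
leave-one-out cross-validation: per-individual importance ratios
$1/p(y_i \mid \theta_s)$ are stabilized by fitting a generalized Pareto
distribution (profile-likelihood quadrature estimator with a weak prior on
the shape) to the top 20% of ratios and replacing them by the fit's
expected order statistics, truncated at the raw maximum. Shape diagnostics
$k > 0.7$ trigger a warning, not a failure.

## The synthetic-data generator

Because the ringing dataset is not redistributed, every stage is validated
on simulated data whose generative process is the exact mirror of
$\Gamma$ and $O$: hidden chains are simulated forward with age- and
covariate-specific survival, observations drawn yearly, histories
truncated after a recovery, and the hidden truth retained for oracle tests
(never shown to inference). The paper-scale scenario uses 47 study years,
35 nestlings ringed per year plus 24 adults trapped mid-study
(1,669 birds), and generating values matching the published estimates:
$s_1 = 0.40$, $s_2 = 0.83$, $p = 0.02$, $r = 0.14$, $\eta = 0.008$. Real
ringing effort varied across decades but is not tabulated in accessible
form, so cohort sizes are constant by default and configurable. Simulated
covariates are independent standard-normal yearly draws re-standardized to
exact mean 0 / sd 1.

What the generator does *not* emulate, and what that implies: uneven
ringing effort, spatial structure, emigration, and any heterogeneity in
$p$ or $r$. One visible consequence is that $\eta$ — identified only by
the timing of recoveries relative to deaths — has a nearly flat likelihood
on $[0, \sim 0.05]$ in constant-effort synthetic data, so its posterior
mean is pulled noticeably above a generating value of 0.008 by the
$\mathcal U(0, 0.5)$ prior even at full sample size, and its 95% interval
occasionally excludes so small a truth. Passing recovery tests on this
generator therefore demonstrates correctness of the machinery, not that
every parameter is sharply identified in the field data regime.

## Numerical choices and edge cases

* Histories with no post-marking occasions contribute log-likelihood 0
  and are accepted (final-year cohorts).
* Boundary parameter values ($p \in \{0,1\}$ etc.) give exact structural
  zeros; a history whose probability hits zero returns `-Inf` rather than
  erroring.
* Row-stochasticity of $\Gamma$ and $O$ is exact by construction;
  structural zeros are exact zeros.
* Standardization refuses constant series (zero variance) rather than
  returning NaNs.
* Ties in pooling are keyed on (ringing-year index, stage, code string);
  pooling is exact, not approximate.
* `rhat()` guards the zero-variance case (constant chains) to 1.
* Seeds: every stochastic entry point takes an explicit seed; chain seeds
  are derived by `sample.int` from the master seed, keeping all seeds
  within 32-bit integer range.

## Known limitations

Detection, recovery and carcass persistence are homogeneous (no time or
individual effects), matching the published model; multi-site states and
emigration are out of scope. The real-data reproduction in the acceptance
suite requires the archived ringing CSV to be placed under
`inst/extdata/real/` and is reported as failing, not skipped, when the
file is absent, so that its status is never silently green.
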