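---
title: "Designing and analyzing two-stage SMARTs with smartats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analyzing two-stage SMARTs with smartats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartats)
```

## The trial and its estimand

A sequential multiple assignment randomized trial (SMART) randomizes each
patient twice: at entry to a stage-1 treatment $A_1$, and — after an
intermediate evaluation $O_2$ (the *tailoring variable*, typically a binary
responder/non-responder classification) — to a stage-2 treatment $A_2$ drawn
from the options available in that patient's branch $(A_1, O_2)$.  A
completed patient contributes one record $\{A_1, O_2, A_2, Y\}$, where $Y$ is
the primary outcome.

An *adaptive treatment strategy* (ATS) is a decision rule
$D = (d_0;\ d_{0r}\ \text{per response category } r)$: start with $d_0$, then
give $d_{0r}$ on observing response category $r$.  Its *value* is
$\theta = \sum_r P(O_2 = r \mid A_1 = d_0)\,
 \mathbb{E}(Y \mid A_1 = d_0, O_2 = r, A_2 = d_{0r})$,
the mean outcome a population following the strategy would attain.  The trial
embeds every strategy formed, per arm, by the Cartesian product of the
stage-2 option sets over response categories; `ats_strategies()` enumerates
them in the conventional order (arm first, last response category varying
fastest).  A *degenerate* branch — a single stage-2 option, no
re-randomization — is permitted everywhere and simply contributes a
one-element factor to the product.

Because a patient's observed sequence is compatible with every strategy that
prescribes it (the patient's unobserved counterfactual branches are
unconstrained), one record typically supports several strategies at once.
This overlap is the characteristic feature of SMART inference: it makes the
estimated strategy values correlated within each stage-1 arm, with exact
independence across arms.

## Degrees of freedom of the global test

The global null $H_0: \theta_1 = \cdots = \theta_G$ is tested with a Wald
statistic whose asymptotic chi-squared degrees of freedom equal the dimension
of the space of *achievable* value contrasts, not $G - 1$.  Within one arm
the values are linear in the per-branch sequence means, so the arm
contributes $\sum_r |\text{options}(r)| - R + 1$ free dimensions ($R$ =
number of response categories); subtracting one overall level gives

$$\nu \;=\; \Big[\sum_{a_1}\Big(\sum_r |\text{options}(a_1,r)| - R(a_1) +
1\Big)\Big] - 1 .$$

For the canonical two-arm, binary-response, two-options-per-branch design
this yields $\nu = 5$ although $G - 1 = 7$: within each arm the four values
satisfy $\theta_{00} - \theta_{01} - \theta_{10} + \theta_{11} = 0$ exactly.
`smart_df()` implements the closed form; the test suite verifies it against a
brute-force rank computation of the contrast space on randomized designs.

## Sample size

**Global path.**  Under a local alternative the Wald statistic is
approximately noncentral chi-squared, so sizing reduces to two ingredients:

1. the noncentrality $\lambda^*$ at which a $\chi^2_\nu(\lambda)$ test of
   level $\alpha$ attains power $1 - \beta$, solved by `getncp()`.  No closed
   form exists; the solver brackets and bisects to the first $\lambda$
   (approaching from below) whose attained power is within `d` of the target.
   Reporting the lower edge of the tolerance band, rather than the exact
   root, mirrors the ascending-search convention of earlier SMART software;
   the two differ by at most `d` divided by the local power slope (about
   0.003 at the default `d = 1e-4`, df = 5), far inside any design-relevant
   margin, and the result does not depend on the starting value.
2. the standardized overall effect size
   $\Delta = (C\Theta^*)^\top (C\Sigma^* C^\top)^- (C\Theta^*)$ with
   $C = (1_{G-1} \mid -I_{G-1})$, computed from a *sequence information
   matrix* (SIM): per sequence, the randomization probabilities, expected
   response rates, and outcome mean and SD.

The total size is $n = \lceil \lambda^* / \Delta \rceil$.

**The design-stage covariance.**  $\Sigma^*$ is the per-subject-scaled
covariance of the G-computation estimator, obtained by the delta method
applied to $\hat\theta_g = \sum_r \hat p_r \bar Y_{g(r)}$: a sequence-mean
term $\sum_r P2_r^2\sigma_r^2/q_r$ shared between strategies that prescribe
the same sequence ($q_r = \pi_1 P2_r \pi_2$), plus a response-rate term
$\sum_{r,r'}\mu_g(r)\mu_{g'}(r')\,P2_r(1\{r=r'\}-P2_{r'})/\pi_1$ reflecting
that the $\hat p_r$ are estimated.  This was a genuinely open choice: a
simpler convention treats the response rates as known and drops the second
term, which enlarges $\Delta$ (for the worked depression-trial SIM below,
0.122 instead of 0.105) and so yields smaller sample sizes.  We keep the full
delta-method form because it is the actual sampling covariance of the
estimator the package uses at analysis time — the test suite confirms by
simulation both that the empirical covariance of $\hat\Theta$ matches it and
that the mean of the Wald statistic matches $n\Delta + \nu$ — making the
sizing path self-consistent with the analysis path: trials sized by
`smartsize(sim = ...)` attain their nominal power in simulation.  Users who
prefer a historical $\Delta$ can pass it directly via `delta`.

For a binary outcome (`family = "binomial"`) the sequence variance is
derived as $\mu(1-\mu)$ from the SIM means.  The IPW variant replaces the
delta-method form with the influence-function covariance of the weighted
estimator.

**Pairwise path.**  `smartsize(global = FALSE)` sizes a two-strategy
comparison like a classic two-arm RCT:
$n = \lceil 2(z_{1-\alpha/2} + z_{1-\beta})^2 / d^2 \rceil$ per strategy at
standardized difference $d$, with optional Bonferroni adjustment through
`ntest`.  No multiplicity adjustment is applied by default, matching common
practice when a single pre-specified pair is of interest.

```{r sizing}
smartsize(delta = 0.1213, df = 5)      # effect size supplied directly
smartsize(sim = codiacs_sim())         # effect size derived from the SIM
```

## Estimation

`seqmeans()` reports per-sequence counts and $n-1$ sample moments.
`atsmeans()` estimates every strategy value:

* **G-computation** (default): $\hat\theta_g = \sum_r \hat p_r(a_1)
  \bar Y(a_1, r, d_g(r))$ with empirical response proportions, covariance by
  the plug-in delta-method formula above.  `common = TRUE` pools the sequence
  variances across the whole trial, weighting by $n_k - 1$ (for the binomial
  family, the pooled response proportion).
* **IPW**: the weighted mean of consistent patients with
  $w_i = 1/(\pi_1\pi_2)$, using either the design's known randomization
  probabilities (`probs = "design"`) or observed frequencies
  (`"empirical"`); covariance from empirical influence-function
  cross-products.  With empirical weights on a full-factorial design the two
  estimators coincide exactly, which the tests exploit as a cross-check;
  with known weights they differ and are compared by simulation.

Confidence intervals use normal quantiles, in line with the large-sample
theory; `digits` affects printing only, never computation.  Requesting a
strategy whose required sequence has no patients is an error naming the
strategy — imputation is out of scope.

## Inference

`smartest()` assembles three blocks: the strategy listing (with
consistent-patient counts, which intentionally sum to more than $n$), the
global test, and all $n_p = G(G-1)/2$ pairwise comparisons.

The global statistic $Q = (C\hat\Theta)^\top (C\hat\Sigma C^\top)^-
(C\hat\Theta)$ uses the Moore–Penrose generalized inverse because
$C\hat\Sigma C^\top$ is rank-deficient by construction (rank $\nu < G-1$);
with the pseudoinverse, $Q$ is invariant to strategy order and reference
choice, which the suite checks numerically.  The reference distribution uses
the *design* degrees of freedom; if the numerical rank of the contrast
covariance disagrees (possible with degenerate data), a warning reports
both.  Pairwise intervals use
$\hat\theta_j - \hat\theta_k \pm z_{1-\alpha/(2 n_p)}\,\mathrm{se}_{jk}$;
reported p-values are deliberately unadjusted two-sided normal tails — the
multiplicity correction enters through the interval quantile and the
decision threshold $\alpha/n_p$, so the displayed p-values remain
interpretable per pair.  The global test acts as a gate-keeper: strategy
selection from the pairwise table is only read when the global test rejects.

## The simulator and what passing tests show

`sim_smart()` draws each patient in the fixed order $A_1, O_2, A_2, Y$ from
the SIM's categorical probabilities and a normal (or Bernoulli) outcome;
output is byte-identical for a fixed seed.  `smart_oc()` wraps it into an
operating-characteristics loop, counting rejections of the global (or
Bonferroni pairwise) test; replicates in which a required sequence is empty
or has a single patient cannot reject, a conservative convention that
matters only at very small $n$.

The generator emulates exactly the data-generating process the sizing
machinery assumes: correct randomization, complete follow-up, homoscedastic
normal (or Bernoulli) outcomes within sequence, and a response distribution
identical to the SIM.  Real trials deviate — dropout, outcome skewness,
baseline covariates that modify response, drifting randomization — and
passing simulation tests says nothing about those features; it demonstrates
internal consistency (estimators unbiased for the SIM truth, covariance
calibrated, type-I error and power at nominal level under the stated
model).

The worked depression-management SIM (`codiacs_sim()`: eight sequences,
equal 0.5 probabilities, means $1, 8, 11, 10, 9, 6, 20, 12$, common SD 10)
doubles as the default non-null test bed; the synthetic 108-patient dataset
`synthetic_codiacs()` mimics the *structure* of the published
depression-management trial (arms MED/PST, binary BDI response, BDI-reduction
outcome) but none of its values.

Monte Carlo problem sizes in the suite were chosen to make the tolerance of
each check explicit: power self-consistency uses 2000 replicates at the
computed $N$ (binomial SE $\approx 0.009$), the null rejection rate 5000
replicates at $n = 500$, parameter recovery 500 replicates at $n = 500$ with
$3\times$ Monte Carlo SE bias bands and a 15% Frobenius band for covariance
calibration, and the Wald-mean oracle for $\Delta$ 300 replicates at
$n = 1000$ with a $4\times$ SE band.  All stochastic tests fix their seeds.

## Numerical choices and limitations

* Probability-sum validation at tolerance $10^{-8}$; rank decisions at
  relative singular-value tolerance $10^{-8}$.
* Sample sizes always round *up*; sample variances use $n - 1$; a
  single-patient sequence has undefined variance (`NA`) rather than zero.
* Treatment and response codes are small non-negative integers; response
  categories are 0-based; strategy indices 1-based.
* Baseline adaptivity is not modeled: an `O1` column is accepted in data
  files but treated as a single stratum, matching two-stage designs whose
  first randomization ignores baseline category.
* Scope is two treatment stages; more stages, continuous tailoring
  variables, covariate adjustment, dropout handling, and regression-based
  optimization (Q-/A-learning) are out of scope.
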