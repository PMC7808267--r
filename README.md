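# smartats

Design and analysis of two-stage **sequential multiple assignment randomized
trials (SMARTs)** for comparing **adaptive treatment strategies (ATSs)** —
dynamic treatment regimes of the form "start with $d_0$; on observing
intermediate response category $r$, switch to $d_{0r}$".  The package is
aimed at trial statisticians and clinical investigators who need the whole
pipeline in one place: sample-size calculation, descriptive summaries,
strategy-value estimation, formal comparison with multiplicity control, and
a simulator for operating characteristics.

## The statistics in brief

A SMART randomizes twice (arms $A_1$; then, within each branch
$(A_1, O_2)$, options $A_2$) and embeds
$G = \sum_{a_1} \prod_r |\mathrm{options}(a_1, r)|$ strategies.  Each
strategy's value is
$\theta_g = \sum_r P(O_2 = r \mid a_1)\,E(Y \mid a_1, r, d_g(r))$,
estimated by **G-computation** (empirical response proportions × sequence
means) or **IPW** (weights $1/(\pi_1 \pi_2)$ over consistent patients).
Because one patient supports several strategies, $\hat\Theta$ has a singular,
block-diagonal covariance $\hat\Sigma$; the global test of
$H_0: \theta_1 = \cdots = \theta_G$ therefore uses the generalized-inverse
Wald statistic

$$Q = (C\hat\Theta)^\top (C\hat\Sigma C^\top)^- (C\hat\Theta),
  \qquad C = (1_{G-1} \mid -I_{G-1}),$$

asymptotically $\chi^2_\nu$ with
$\nu = [\sum_{a_1}(\sum_r |\mathrm{options}| - R + 1)] - 1$ (the rank of the
achievable contrast space — 5, not 7, for the canonical 2×2×2 design).
Pairwise differences get Bonferroni **simultaneous confidence intervals**
$\hat\theta_j - \hat\theta_k \pm z_{1-\alpha/(2n_p)}\,\mathrm{se}_{jk}$ with
$n_p = G(G-1)/2$.  Sample size for the global test solves the noncentral
chi-squared power equation $\chi^2_{\nu}(\lambda^*)$ vs
$\chi^2_{\nu,\alpha}(0)$ for $\lambda^*$ and sets
$n = \lceil \lambda^*/\Delta \rceil$ with effect size
$\Delta = (C\Theta^*)^\top (C\Sigma^* C^\top)^- (C\Theta^*)$ computed from a
sequence information matrix (SIM); pairwise sizing follows the classic
two-arm normal approximation.  See the methods vignette
(`vignettes/smart-trial-methods.Rmd`) for derivations and design choices.

## Worked example

Size a trial for the worked depression-management design (df = 5, effect
size 0.1213, α = 0.05, power 80%):

```r
library(smartats)
smartsize(delta = 0.1213, df = 5)
#> Sample size for a SMART (global test)
#>   NCP   = 12.8248
#>   delta = 0.1213
#>   df    = 5
#>   N     = 106 total patients
```

The noncentrality parameter alone: `getncp(df = 5, alpha = 0.05,
beta = 0.20, d = 1e-4, start = 5)` returns `12.82481`.  Passing the SIM
itself (`smartsize(sim = codiacs_sim())`) derives df and Δ from the design.

Analyze a (synthetic) 108-patient two-stage trial:

```r
dat <- synthetic_codiacs(seed = 2020)   # simulated; structure, not data
seqmeans(dat, digits = 2)
#>   SEQ A1 O2 A2  N  MEAN    VAR    SD
#> 1   1  0  0  0 19  1.74  59.54  7.72
#> 2   2  0  0  1 14  7.65  95.02  9.75
#> ...                                    (8 sequences, N sums to 108)

print(smartest(dat), digits = 3)
#> $Global.test
#>     N nATS df        Q    p.value
#> 1 108    8  5 12.57153 0.02774257
#>
#> $Pairwise.comparisons
#>    label   diff   lower  upper      Z p.value
#> 4    1-5 -6.526 -13.794  0.742 -2.805   0.005
#> ...                                    (28 pairs)
```

The global test rejects at 5% (Q = 12.57 on 5 df, p = 0.028), so the
pairwise block may be interpreted; no single pair clears the Bonferroni
threshold 0.05/28 = 0.0018 here — with 108 patients the gate-keeping global
test is considerably more powerful than any simultaneous pairwise claim,
which is exactly why it comes first.  `atsmeans(dat)` returns the eight
strategy values with standard errors, confidence limits and the full
block-diagonal covariance; `plot()` methods draw the design diagram,
per-sequence box plots and a forest plot of strategy values.

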