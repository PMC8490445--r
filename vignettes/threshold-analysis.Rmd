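---
title: "Probabilistic parameter thresholds by pairwise stochastic approximation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic parameter thresholds by pairwise stochastic approximation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(threshsa)
```

## The problem

Probabilistic sensitivity analysis for a *decision* model asks a different
question than it does for a single simulator.  Given a finite set of options
$D$ (in health economics: alternative treatments), a utility $f_d(\theta)$
per option on the net monetary benefit scale, and a joint distribution over
the uncertain inputs $\theta = (\theta_1, \dots, \theta_s)$, the baseline
choice is the prior optimum
$d_{\mathrm{opt}}(\emptyset) = \arg\max_d \mathbb{E}[f_d(\theta)]$.  The
interesting sensitivity question is: *if we learned one input exactly, for
which values would the optimal choice change?*

The **probabilistic parameter threshold** $K_j$ of input $\theta_j$ is the
set of values at which the conditionally optimal option
$d_{\mathrm{opt}}(\theta_j) = \arg\max_d
\mathbb{E}[f_d(\theta) \mid \theta_j]$ is not unique — the crossing points
of the conditional-expectation curves of the top two options.  Between
consecutive elements of $K_j$ the optimal option is constant, so $K_j$
partitions the axis of $\theta_j$ into decision regions.

Two scalar summaries ride on top of the threshold set:

* the **decision switching probability (DSP)**
  $P_j = \mathbb{P}[d_{\mathrm{opt}}(\theta_j) \ne
  d_{\mathrm{opt}}(\emptyset)]$, the marginal probability mass of the
  regions whose optimal option differs from the prior optimum;
* the **EVPPI**
  $\mathbb{E}[\max_d \mathbb{E}[f_d \mid \theta_j]] - \max_d
  \mathbb{E}[f_d]$, the expected utility gain from resolving $\theta_j$,
  bounded above by the **EVPI**
  $\mathbb{E}[\max_d f_d] - \max_d \mathbb{E}[f_d]$.

DSP and EVPPI are complementary: EVPPI weighs *how much utility* is at
stake, DSP *how likely* a switch is.  Both are zero exactly when the
threshold set never separates the prior optimum from an alternative
(equivalently, when $K_j$ is empty the conditionally optimal option is
constant and must equal the prior optimum, so the DSP of an empty set is 0
by construction, not by estimation).

## Root-finding instead of nested estimation

Each element of $K_j$ is a root of a pairwise conditional difference
$g^{(d_1,d_2)}(x) = \mathbb{E}[(f_{d_1} - f_{d_2})(\theta) \mid
\theta_j = x]$, and
$K_j \subseteq \bigcup_{d_1 \ne d_2} K_j^{(d_1,d_2)}$, so it suffices to
root-find each pair and then test which pairwise roots survive competition
from the remaining options.  The package's engine is the Robbins–Monro
recursion

$$\theta^{t+1} = \theta^t - \alpha_t \, \hat g(\theta^t), \qquad
\alpha_t = a\,t^{-\gamma},$$

where $\hat g$ is an *unbiased but rough* Monte Carlo estimate of the
pairwise difference — by default a single conditional sample per iteration
(`m_inner = 1`).  This sidesteps the inner-loop accuracy requirement of the
nested (double-loop) baseline entirely: no conditional expectation is ever
estimated accurately, only unbiasedly.  The reported estimate is the
Polyak–Ruppert running mean $\Theta^t = t^{-1}\sum_{u \le t} \theta^u$,
which attains the optimal $1/\sqrt{t}$ error rate and tolerates the slowly
decaying $\gamma = 1/2$ schedule used throughout (with averaging off the
package warns, since $\gamma \le 1/2$ violates the classical
summable-squares step condition).

Iteration happens entirely in each variable's *transform space* — log for
log-normal inputs, logit for logit-normal ones — where the marginal is
exactly normal.  Initial iterates are drawn from the marginal, step scales
default to $a = 3\sigma_j/(2 \times 10^4)$ with $\sigma_j$ the
transform-space marginal standard deviation, and thresholds are reported in
both spaces.

Per option pair the orchestration runs 20 independent searches
(`n_runs = 20`).  Multiple roots are separated by gap clustering of the
per-run finals (tolerance `max(5 * pooled SE, 0.05 * sigma_j)` — the pooled
factor tracks estimation noise, the floor prevents noise-level
micro-clusters; both are package choices).  An empty pairwise set makes the
recursion drift instead of converge, which `detect_divergence()` recognises
(next section).  Surviving candidates are then subjected to the membership
test: at candidate $\hat\theta$, for every competitor
$d \notin \{d_1, d_2\}$, one-sided tests of
$\mathbb{E}[f_d - f_{d_1}] > 0$ and $\mathbb{E}[f_d - f_{d_2}] > 0$ on $N =
10^4$ conditional samples; the candidate is kept only if no test rejects.
Each of the 20 per-run finals is tested and p-values are aggregated by
their maximum, so a candidate is discarded only when *every* run rejects
it.  In clear-cut geometry the p-values saturate at 0 or 1 and the
significance level is immaterial; the package defaults to 0.05 per
aggregated p-value without multiplicity correction, exposed in the
configuration, because the level only matters in marginal cases where a
conservative (retain-leaning) choice is the safer default.

### Divergence detection

How to operationalise "the estimate diverges when the pairwise set is
empty" is genuinely open; the package judges a 20-run collection empty when
any of three signals fires:

1. a run's iterates overflowed (flagged, never raised as an error);
2. the across-run standard error of the averaged iterates fails to shrink
   by a factor 1.5 between $t = T/10$ and $t = T$ (a converged collection
   shrinks by about $\sqrt{10} \approx 3.2$) *while most individual runs
   are still moving* — a non-shrinking spread over runs that have each
   settled indicates several distinct roots reached from different
   initialisation basins, which is a clustering outcome, not emptiness;
3. the across-run mean path moves monotonically away from the marginal
   mean, ends more than 8 marginal standard deviations out, *and* is still
   moving over the last half of the run (its increment over $[T/2, T]$
   exceeds a quarter of the one over $[T/10, T/2]$).

The still-moving clause in (3) matters: several genuine roots of the
built-in model sit 9–14$\sigma$ outside the marginal bulk, so "far from the
mean" alone does not indicate emptiness — unbounded drift does.  A
Polyak–Ruppert average of an unbounded drift keeps moving like $\sqrt{t}$
(its late increment is about 59% of its early one), while an average that
has found a root settles (late increments a few percent).  The factor 1.5,
the 8$\sigma$ guard and the quarter ratio are package choices validated on
constructed drifting and converged toys in the test suite.

### Sign of the recursion

The recursion above assumes the difference is negative below the root and
positive above; the mirrored geometry needs the sign-flipped update.
`determine_sign()` probes the difference at two marginal quantiles (5% and
95%, 2000 pilot samples each): confident opposite signs fix the direction,
confident equal signs report "no-crossing", and anything else falls back to
the sign of the slope between the probes.  The campaign treats
"no-crossing" as advisory and still runs the search with the slope-derived
sign — a far-outside root looks exactly like "no crossing" to the probes,
and the divergence detector is the component equipped to tell the two
apart after the fact.

## The built-in model

`three_treatment_model()` is a synthetic cost-effectiveness model
comparing a cost-free standard of care `d1` (no side-effect risk, high
event probability) with two costly treatments `d2`, `d3` (side-effect risk,
odds-ratio-reduced event probabilities) at a willingness to pay of 75,000
per QALY.  All twelve inputs, their distributions and the three correlated
bivariate blocks (treatment costs, event odds ratios, side-effect
probabilities) are listed in `?three_treatment_model`; the model is the
package's reference instance and every distribution parameter is part of
its definition, including the strikingly tight treatment-cost covariance
(standard deviations of ~17 and ~22 monetary units), which is used
verbatim.  Conditioning on one block member fixes the partner's underlying
normal to its exact closed-form conditional — done in transformed space
because exactness is free there.

The net benefit is multilinear in all inputs except the baseline event
probability and the odds ratios.  Linearly entering variables (`L`, `Q_E`,
`Q_SE`, `C_E`, `C_SE`, `C_T_d2`, `C_T_d3`) can therefore be replaced by
their exact means inside conditional-expectation estimates (plug-in /
Rao–Blackwellisation) without changing the estimand; the logit-normal mean
of `Q_E` has no closed form and is computed once by adaptive quadrature at
model construction.  Plug-in is ON for reference curves and EVPPI, OFF
inside the stochastic approximation (whose single-sample estimates are
meant to be rough).

```{r model}
model <- three_treatment_model()
model
```

## A small worked campaign

The published study settings are `n_runs = 20`, `n_iter = 1e4`; the chunk
below trims both to keep the vignette light — expect visibly wider spreads
than a full campaign.

```{r campaign}
camp <- threshold_campaign(model, "P_SE_d3", n_runs = 8, n_iter = 2000,
                           n_test = 2000, seed = 1)
glance(camp)
tidy(camp)
```

The logit-space threshold set of the side-effect probability of `d3`
separates a lower region where `d3` is optimal, the broad middle region of
the prior optimum `d2`, and a far upper tail where the cost-free `d1` wins;
the DSP is dominated by the lower region's mass.  `autoplot()` methods show
iterate histories (`sa_trace`, `pairwise_roots`), conditional-expectation
curves (`ce_curve`) and nested-MC scans.

## Value of information

`evpi()` uses the paired estimator on common samples — the mean of
$\max_d f_d(\theta) - f_{d^*}(\theta)$ with $d^*$ the prior optimum
estimated on the same draws.  Pairing does not change the estimand, but
with per-option utility standard deviations of order $10^5$ and an EVPI of
order $10^3$ the unpaired difference of two means would need orders of
magnitude more samples for the same error; the paired differences are
mostly zero and the standard error comes out near 15 monetary units at
$2^{18}$ samples.

`evppi_nested()` is the standard nested estimator ($2^{18}$ outer, $2^{10}$
inner at the published scale) with plug-in means in the inner loop and both
terms computed from the same inner means.  Finite inner samples bias it
upward (the inner max partly fits inner noise); the bias is documented and
left uncorrected, matching the estimator the reference values were
produced with, and shrinks with `n_inner`.

```{r voi}
evpi(model, n = 2^15, seed = 2)
evppi_nested(model, "P_SE_d3", n_outer = 2^12, n_inner = 2^8, seed = 3)
```

DSP, by contrast, needs no resampling at all once thresholds are known:
the marginal in transform space is exactly normal (or beta), so
`decision_switching_probability()` sums closed-form CDF masses of the
intervals labelled with a non-prior option.

## What the toys do and do not establish

The unit suite rests on constructed models with closed-form structure: a
linear-Gaussian pair (known root, known $1/\sqrt{t}$ RMSE law), a cubic
difference with two attracting roots (multi-root clustering), a dominated
option (empty-set behaviour), and a three-option model with analytically
placed crossings at 1, 1.5, 2 whose middle crossing must be rejected by the
membership test (end-to-end recovery, DSP $= 2\Phi(-0.5)$).  These validate
the estimators' *mechanics* under exactly known truth.  What they do not
emulate: real cost-effectiveness models with Markov structure (the utility
contract admits them, but no cohort engine ships), non-Gaussian heavy
tails, more-than-pairwise correlation, or multimodal conditional
differences beyond two roots.  Passing the suite says the algorithms do
what their theory claims under the stated distributional families, not
that any particular health economic model is well specified.

## Numerical choices and edge cases

* **Support clamping.**  An overshooting iterate is mapped back to just
  inside the family support (e.g. $10^{-300}$ for positive families)
  before conditioning, so a wild step degrades gracefully instead of
  erroring; genuine overflow flags the trace as diverged.
* **Zero estimates.**  $\hat g = 0$ leaves the iterate unchanged — the
  recursion needs no tie-breaking.
* **Interval labelling.**  Representative points are interval midpoints,
  and $3\sigma_j$ beyond the extreme elements for the unbounded tails;
  dominance is decided by $10^4$-sample conditional means with a
  2-standard-error margin, near-ties are flagged, and an element
  separating two identically labelled intervals is collapsed out with a
  warning.
* **Far roots.**  The step scale is deliberately proportional to
  $\sigma_j$; for roots many tens of $\sigma_j$ out (the treatment cost
  `C_T_d3` is the known case) the campaign exposes a per-variable
  `step_multiplier` (10 is a workable value for `C_T_d3`).  Because the
  appropriate factor is model-specific, those searches are treated as
  configuration-sensitive and excluded from the reproduction targets.
* **Argmax ties** in the nested baseline are broken by option order with a
  warning — this is the documented instability that makes the double-loop
  estimator report spurious extra thresholds near crossings, and it is
  deliberately preserved rather than patched.
* **Seeding.**  Every campaign derives per-(variable, pair, purpose)
  sub-seeds from the master seed by a stable label hash
  (`derive_seed()`), so any single run can be reproduced in isolation
  from the seeds recorded in the output files; identical configurations
  serialise byte-identically.

## Problem sizes used by the test suite

The acceptance-style tests reproduce the reference results at the
published settings where they are cheap (SA campaigns: 20 runs ×
$10^4$ iterations; EVPI: $2^{18}$ samples) and at a reduced outer size for
the nested EVPPI ($2^{14}$ instead of $2^{18}$ outer samples, the
published inner size $2^{10}$), with the stated tolerance widened by three
of the estimator's own Monte Carlo standard errors to absorb the extra
outer noise.  The brute-force cross-check oracle evaluates the pairwise
difference on a 25-point grid with $2^{15}$ common-random-number samples
per point and brackets each retained root by sign change; the full
$2^{18} \times 2^{10}$ EVPPI protocol runs in `scripts/acceptance.R`.

## Known limitations

* Thresholds are univariate: the threshold set of a *group* of inputs
  (a surface, not points) is out of scope, as is the expected value of
  sample information and a DSP analogue for it.
* The EVPPI inner bias is reported, not corrected (no multilevel or
  regression post-processing).
* Only pairwise correlation blocks are supported — no general copulas.
* One reference value resists reproduction: the log odds-ratio input's
  (d1, d2) crossing.  Three mutually independent routes — the SA engine,
  the brute-force grid oracle, and direct quadrature of the conditional
  difference — place it near 0.20 in log space under the stated input
  distributions, not at the published 0.45.  This pair has by far the
  flattest conditional-difference curve of the study (the dependence on
  the conditioning variable is only through the odds-ratio correlation),
  so its root amplifies any systematic offset roughly 25-fold relative to
  the other pairs, all of which reproduce to two or three significant
  figures.  The package reports its computed value.
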