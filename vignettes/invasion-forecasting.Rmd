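---
title: "Forecasting predator introductions from stable isotopes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting predator introductions from stable isotopes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `isoforecast`, the choices we
made where the design was genuinely open, and what the package's tests
do and do not establish about real data.

## The forecasting idea

Carbon and nitrogen stable isotope ratios (δ¹³C, δ¹⁵N, both in ‰)
summarise where an organism's energy comes from and how many trophic
steps it has passed through. If candidate source populations of a
predator have been isotopically characterised, their signatures can be
*superimposed* onto the recipient community's biplot without rescaling
— the "raw" approach, appropriate when donor and recipient values are
on the same reference scales and no reliable baseline standardisation
exists — and the usual toolkit then answers two forecasting questions:
what would the newcomer eat (a diet mixing model over the recipient's
prey), and whom would it compete with (trophic position and isotopic
niche overlap against the resident apex predator).

Superimposition assumes the introduced population's niche would settle
somewhere within the range spanned by the donor populations. It ignores
plasticity, prey switching after depletion, and any post-introduction
baseline shift; results are a first-order screening, not a population
forecast. `superimpose(standardize = TRUE)` optionally re-anchors donor
values by the difference between donor-system and recipient baseline
means when donor baselines are available.

## Two-baseline trophic position

For consumer individuals $i$:

$$\delta^{15}N_i \sim N(\alpha\,b1_N + (1-\alpha)\,b2_N +
\Delta_N (TP - \lambda),\; \sigma_N),$$
$$\delta^{13}C_i \sim N(\alpha\,b1_C + (1-\alpha)\,b2_C +
\Delta_C (TP - \lambda),\; \sigma_C).$$

$TP$ is the trophic position, $\alpha$ the proportion of baseline-1
carbon, $\Delta_N, \Delta_C$ the trophic discrimination factors (TDFs)
and $\lambda$ the trophic level of the baselines.

**Baselines.** Baseline 1 is detritus; baseline 2 pools the
phytoplankton and zooplankton rows by unweighted average of means and
root-mean-square of SDs (the source table reports them separately but
they act as one pelagic baseline). The pooled n is the total; baseline
means enter the model as latent parameters with prior
$N(\text{mean}, \text{SD}/\sqrt{n})$ — or SD as-is when $n < 3$, where
the $\sqrt{n}$ reduction would be spurious precision. Identifiability
of $\alpha$ requires the baselines to differ in δ¹³C; identical means
are rejected.

**TDFs.** Species-specific TDFs are rarely available, so they are
simulated: $\Delta_N \sim N(3.4, 0.98)$ and
$\Delta_C \sim N(0.39, 1.3)$ ‰ per step by default, the canonical
muscle/whole-organism literature values. Both are configurable
(`tdf_spec()`), and `simulate_tdf()` exposes the draws directly.

**$\lambda$.** The baselines are treated as primary consumers
($\lambda = 2$, configurable). Detritus arguably sits below level 2;
pooling it with plankton at a common $\lambda$ is the pragmatic choice
when the source data give no per-baseline levels, and $\lambda$ shifts
all TPs by a constant, leaving rankings and overlap untouched.

**Priors and sampling.** $TP \sim U(\lambda, 10)$,
$\alpha \sim \text{Beta}(1,1)$, $\sigma_N, \sigma_C$ half-normal with
scale 5 ‰. The sampler is adaptive random-walk Metropolis-within-Gibbs
(Robbins–Monro scale adaptation to 44% acceptance during burn-in only),
4 chains × 10,000 kept iterations after 2,000 burn-in by default,
matching the 10,000-step Monte-Carlo convention of this literature.
Because $TP$ and $\Delta_N$ enter the likelihood only through the
product $\Delta_N(TP-\lambda)$, the chain is parameterised on the
nitrogen enrichment $e_N = \Delta_N (TP - \lambda)$ — which the data
inform directly — together with $\Delta_N$ itself; the uniform prior on
$TP$ contributes a $1/\Delta_N$ Jacobian. This removes the ridge that
makes naive $(TP, \Delta_N)$ updates mix slowly. Convergence is
monitored by split-chain $\hat R$ (flagged above 1.1, not fatal) and
reported via `glance()`.

**Oracle.** With all SDs at zero the model collapses to the closed form

$$\alpha = \frac{\delta^{13}C_c - b2_C}{b1_C - b2_C}\ \text{(clipped to
[0,1])},\qquad TP = \lambda + \frac{\delta^{15}N_c - (\alpha b1_N +
(1-\alpha) b2_N)}{\Delta_N},$$

implemented in `tp_point_estimate()` and used by the tests as an
independent oracle (the suite checks the posterior median approaches it
as noise vanishes).

## Diet mixing model

For consumer $i$ and isotope $j$ with sources $k = 1,\dots,K$:

$$y_{ij} \sim N\Big(\sum_k p_k(\mu_{kj} + \Delta_j),\;
\sqrt{\sum_k p_k^2(\sigma_{kj}^2 + \tau_j^2) + \sigma_j^2}\Big).$$

The proportion vector $p$ lives on the simplex via independent standard
normal latent variables mapped through softmax: weakly informative,
symmetric, and strictly interior (no source is ever assigned exactly
zero). The TDF $(\Delta_j, \tau_j)$ is applied uniformly to all sources
and $\Delta_j$ is re-drawn per iteration; per-source TDFs would be a
configuration extension. A residual term $\sigma_j$ with a
half-normal(2 ‰) prior is included by default because group-level
consumers are typically overdispersed relative to the pure mixing
variance — and, in superimposition scenarios, because the consumer may
sit outside the source polygon entirely, which the residual absorbs.
Concentration dependence and elemental-concentration weighting are
deliberately omitted (no such data in the summary-table workflow).
Sampling: adaptive Metropolis on the latent vector (target acceptance
23%) with Metropolis-within-Gibbs on the residual SDs.

`summarize_diet()` orders sources by posterior mean; `rank_stability()`
reports the per-draw probability that each source is the single largest
diet component, a sharper statement than comparing posterior means.

With one source the fit degenerates to $p_1 = 1$ exactly; identical
source means raise a non-identifiability warning but still sample (the
posterior is then the prior, near-uniform).

## Niche ellipses and overlap

The standard ellipse of a bivariate normal cloud has area
$SEA = \pi\sqrt{\det\Sigma}$ and covers $1 - e^{-1/2} \approx 39.35\%$
of the distribution; its small-sample correction is
$SEAc = SEA\,(n-1)/(n-2)$. A "40% of central data" ellipse is read as
this $c = 1$ standard ellipse; the exact 0.40 level remains available
through the `coverage` argument ($q = \chi^2_2(\text{coverage})$).

The Bayesian version draws $(\mu, \Sigma)$ from the conjugate
normal–inverse-Wishart posterior under a vague proper prior: prior mean
equal to the sample mean with negligible weight $\kappa_0 = 10^{-3}$,
inverse-Wishart scale $10^{-3} I$ ‰², 3 degrees of freedom. Conjugacy
gives exact draws with no MCMC, so SEAb posteriors are cheap and
reproducible.

Ellipse–ellipse overlap intersects the two coverage-level boundary
polygons (360 vertices each by default) with Sutherland–Hodgman convex
clipping and the shoelace area formula. Because "percent overlap" is
ambiguous without a normalisation, all three are reported explicitly:
the fraction of each ellipse covered and the Jaccard fraction of the
union.

Directional overlap follows the probabilistic niche-region definition:
each Monte-Carlo step draws $(\mu, \Sigma)$ for both groups from their
posteriors, one individual from A's posterior predictive at the data
level, and tests whether it falls inside B's $\alpha$-level Mahalanobis
region. The default 10,000 steps follow the field's convention; the
estimate is genuinely asymmetric (a narrow niche nested in a wide one
overlaps strongly in one direction only), which the tests pin down.

## Synthetic data and pseudo-individuals

The generator produces bivariate-normal groups
(`group_spec()`/`generate_group()`) and consumers forward-simulated
from known diet proportions under exactly the mixing likelihood above
(`generate_consumer()`), so parameter-recovery tests have a ground
truth. Default isotope correlation is $\rho = 0$ — per-taxon
covariances are rarely published — but it is configurable because
ellipse orientation depends on it. A single integer seed feeds a
deterministic per-group stream, so one group's draws do not change when
another group's $n$ does.

`simulate_from_summaries()` bridges printed summary tables to
individual-level fits. By default it moment-matches: the drawn
individuals are affinely rescaled so their sample mean and SD equal the
reported values exactly. A published table *is* the observed sufficient
statistic, so conditioning the pseudo-data on it reproduces the table
instead of stacking a second layer of sampling noise on top of the
reported one; `exact = FALSE` gives plain draws. Donor populations known
only as site means are expanded to 10 pseudo-individuals per site with
an assumed SD of 1 ‰ per isotope — a typical within-population isotopic
spread for percids — and `donor_sd_sensitivity()` re-runs the donor
fits across 0.5/1/2 ‰ to show how much the choice matters.

What passing tests do *not* show: synthetic clusters are exactly
bivariate normal with known baselines, whereas real communities have
skewed, size-structured, seasonally drifting signatures and baselines
measured with error of their own. Recovery and coverage results
therefore validate the implementation, not the field applicability of
the model assumptions.

## Numerical choices

* Residual SDs are bounded below by $10^{-6}$ ‰ so that degenerate
  zero-noise test configurations cannot underflow the likelihood.
* MH proposal scales adapt only during burn-in (diminishing adaptation,
  $\gamma_t = \min(0.1, 5/\sqrt{t+10})$), so kept draws come from a
  fixed kernel.
* Ellipse polygons use 360 vertices; the polygon area then matches the
  analytic ellipse area to about $10^{-4}$ relative error, far below
  the Monte-Carlo noise of any overlap estimate. Clipping assumes both
  polygons convex, which ellipse boundaries always are.
* Ties in `rank_stability()` (measure-zero in continuous posteriors)
  resolve to the first source.
* Closed-form collapse tests use a tolerance of 0.01 TP units; sampler
  stochasticity at the default chain lengths is well inside that.

## Problem sizes

The test suite fits reduced chains (2 × 1,500–4,000 iterations) chosen
so that the posterior medians under test are stable to well within the
assertion tolerances; the packaged defaults (4 × 10,000 after 2,000
burn-in) follow the literature convention and are used by
`scripts/acceptance.R`. Moment-convergence checks run at $n = 10^5$
draws; Monte-Carlo coverage checks at $n = 2\times10^4$ with 3-standard-
error bands; the trophic-position coverage study uses 100 synthetic
replicates.

## Known limitations

* Two isotopes, two baselines: no one-baseline or multi-tracer models,
  no lipid correction of δ¹³C.
* The mixing model has no hierarchical structure across consumers and
  no concentration weighting.
* The gape-size argument is implemented only as an optional mean-length
  prey filter (`select_prey(size_threshold = ...)`), not a
  morphometric model; young-of-the-year prey are out of scope.
* Superimposition inherits all caveats above; where donor baselines
  exist, compare `standardize = TRUE` and `FALSE` as a sensitivity
  check.
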