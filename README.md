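# isoforecast

Forecasting the trophic consequences of a predator introduction from
carbon and nitrogen stable isotopes.

## The problem

Before an invasive or translocated predator arrives, managers often want
to know what it would eat and whom it would compete with. When
individuals from candidate source populations have been analysed for
δ¹³C and δ¹⁵N (‰), their signatures can be *superimposed* onto the
recipient community's isotope biplot and run through the standard
isotope-ecology toolkit as if the introduction had happened. This
package implements that full pipeline for a worked case study — the
hypothetical introduction of European perch (*Perca fluviatilis*) from
five Anatolian water bodies into İznik Lake (Turkey), whose resident
apex predator is the European catfish (*Silurus glanis*) — and for any
community supplied as a tidy table.

It is aimed at trophic ecologists working with bivariate
(δ¹³C, δ¹⁵N) data: every user-facing function takes a data frame and
returns a tibble, fitted objects have `tidy()`/`glance()` methods, and
each result type has an `autoplot()`.

## What it computes

* **Bayesian two-baseline trophic position.** For consumer individuals
  *i*,

  δ¹⁵Nᵢ ~ N(α·b1_N + (1−α)·b2_N + Δ_N·(TP − λ), σ_N),
  δ¹³Cᵢ ~ N(α·b1_C + (1−α)·b2_C + Δ_C·(TP − λ), σ_C),

  with trophic position TP, baseline-1 mixing proportion α, stochastic
  trophic discrimination factors Δ_N ~ N(3.4, 0.98) and
  Δ_C ~ N(0.39, 1.3) ‰ per trophic step (configurable), baseline means
  drawn under their sampling distributions, and λ the baseline trophic
  level (default 2). Priors: TP ~ U(λ, 10), α ~ Beta(1,1), σ ~
  half-normal(5 ‰). Sampled by adaptive Metropolis-within-Gibbs
  (4 chains × 10,000 iterations after 2,000 burn-in by default), with a
  closed-form point estimate (`tp_point_estimate()`) as oracle.
* **Bayesian diet mixing model** (`fit_mixing_model()`): posterior diet
  proportions **p** over K prey sources under
  y_ij ~ N(Σₖ pₖ(μ_kj + Δ_j), √(Σₖ pₖ²(σ_kj² + τ_j²) + σ_j²)),
  with a softmax-normal prior on **p**.
* **Isotopic niche ellipses** (`ml_ellipse()`, `bayesian_sea()`):
  SEA = π√det Σ, its small-sample correction SEAc = SEA·(n−1)/(n−2),
  and the Bayesian posterior SEAb from a conjugate
  normal–inverse-Wishart model (no MCMC needed).
* **Niche overlap** (`ellipse_overlap()`, `directional_overlap()`):
  polygon-clipped ellipse intersections at any coverage level, and the
  asymmetric Monte-Carlo probability that an individual of species A
  falls inside species B's α-level niche region (default 10,000 steps).
* **Invasion projection** (`run_projection()`): superimposes donor
  populations, fits trophic positions for every fish group, a diet model
  per donor over the automatically selected prey set
  (`select_prey()` drops the apex predator, non-fish groups, and
  optionally taxa above a gape-size length threshold), and overlap
  metrics donor-vs-apex — all in one reproducible report.
* **Synthetic communities** (`generate_group()`, `generate_consumer()`,
  `generate_community()`): bivariate-normal groups and forward-simulated
  consumers with known diets, so every stage is testable without any
  field data.

The case-study inputs ship as plain-text fixtures:
`load_fixture("iznik_community")` (19 group summaries: 12 fish species,
marsh frog, invertebrates, producers, detritus) and
`load_fixture("perch_sites")` (five donor perch site means).

## Worked example

```r
library(isoforecast)

community <- load_fixture("iznik_community")
community
#> <community> 0 measurements, 19 group summaries
#>   baseline1: Detritus
#>   baseline2: Phytoplankton + Zooplankton

# trophic position of the resident apex predator, rebuilt from its
# summary row (n = 10, 12.60 +/- 3.70 permil d15N)
baselines <- baseline_spec(community)
apex <- simulate_from_summaries(community, seed = 42, taxa = "Silurus glanis")
fit <- fit_two_baseline_tp(apex, baselines, seed = 7)
tidy(fit)
#> # A tibble: 4 × 6
#>   term   estimate  mean std.error conf.low conf.high
#> 1 tp        4.56  4.83      1.20    3.29       8.20
#> 2 alpha     0.255 0.321     0.256   0.0102     0.917
#> 3 sigmaN    3.89  4.08      1.04    2.60       6.57
#> 4 sigmaC    2.57  2.70      0.734   1.67       4.46
```

The posterior median trophic position of the catfish is about 4.6 — a
top-predator position roughly 2.6 enrichment steps above the pooled
plankton baseline. `alpha` is the share of its carbon routed through the
detrital baseline (weakly identified here because the catfish's δ¹³C
lies outside the baseline interval, so the posterior spans much of
[0, 1]).

```r
# forecast: what would introduced lake perch eat?
combined <- superimpose(perch_donor_groups(), community, seed = 11)
prey <- select_prey(community, apex_label = "Silurus glanis")  # 11 sources
perch <- combined$measurements[
  combined$measurements$group == "P. fluviatilis (lakes)", ]
diet <- fit_mixing_model(perch, prey, seed = 5)
head(summarize_diet(diet), 3)
#> # A tibble: 3 × 5
#>   source            mean median lower_95 upper_95
#> 1 Vimba vimba     0.593  0.726   0.00602    0.945
#> 2 Rutilus rutilus 0.171  0.0317  0.00129    0.876
#> 3 Atherina boyeri 0.0389 0.0182  0.00112    0.207

# would perch intrude on the catfish's niche?
directional_overlap(perch, apex, alpha = 0.95, nmc = 10000, seed = 3,
                    labels = c("P. fluviatilis (lakes)", "Silurus glanis"))
#> # A tibble: 1 × 6
#>   group_a                group_b        alpha  prob   mc_se   nmc
#> 1 P. fluviatilis (lakes) Silurus glanis  0.95 0.907 0.00290 10000
```

The mixing model puts most of the posterior diet mass on *Vimba vimba*
and *Rutilus rutilus* — the two soft-rayed cyprinids closest to the
perch in the biplot — and a random introduced perch would fall inside
the catfish's 95% niche region with probability about 0.9, flagging
strong potential competition.

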