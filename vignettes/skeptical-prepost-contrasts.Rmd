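---
title: "Skeptical Bayesian pre/post contrasts for hockey concussion surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeptical Bayesian pre/post contrasts for hockey concussion surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headcheck)
```

## The problem

When the NHL introduced Rule 48 (penalizing checks that target the head),
the natural epidemiological question was whether the *profile* of
concussions changed between the seasons before the rule (2006-2010, 4
seasons, 4920 regular-season games) and a stable period after it
(2014-2019, 5 seasons, 6232 games). The data are count tables: for each
injury characteristic (location on the ice, zone, period, mechanism of the
hit, position of the injured player, and so on), the number of
video-documented concussions bearing that characteristic in each cohort,
plus per-cohort totals of diagnosed concussions and games. Only events with
usable video are characteristic-coded, so proportion denominators are the
video-documented counts (and, for some variables, less than that because of
item-level missing data), while incidence denominators are full game
counts.

Two kinds of comparison are of interest, both reported as posterior
contrasts of the 2014-2019 cohort minus the 2006-2010 cohort:

* **proportions** — the share of video-documented concussions with a
  characteristic, contrasted in percentage points (pp);
* **incidence** — events per 100 games, contrasted in events/100 games.

## The model

Each (variable, cohort) cell is an intercept-only binomial-logit model:

$$y \sim \mathrm{Binomial}(n,\, \mathrm{logit}^{-1}(\alpha)), \qquad
  \alpha \sim \mathcal{N}(\mu, \sigma).$$

The posterior of $\mathrm{logit}^{-1}(\alpha)$ is the cohort's proportion
(or per-game event probability; multiplying by 100 gives the per-100-games
rate — at these incidences multiple events in one game are rare, so the
Bernoulli-per-game approximation is benign, and the generator in this
package can simulate the Poisson violation to check it). A contrast is
formed by independently pairing posterior draws from the two cohorts and
summarizing $d = 100\,(p_{\text{post}} - p_{\text{pre}})$: posterior mean,
equal-tailed 70% and 90% credible intervals, and the probability mass on
each side of zero.

## Skeptical priors tuned by prior-predictive simulation

The priors are the scientific crux. Both cohorts' intercepts are centered
at the **pre-period observed value** ($\mu = \mathrm{logit}(y_1/n_1)$), so
that a priori the expected between-group difference is exactly zero; the
width $\sigma$ is then *tuned by prior-predictive simulation*: draw two
independent intercepts from the prior, push them through the inverse logit,
and adjust $\sigma$ by bisection until the standard deviation of the
implied difference is a target value, by default 10 on the reporting scale
(10 pp, or 10 events/100 games). Every bisection evaluation reuses one set
of common random numbers (100 000 replicates), which makes the
prior-predictive SD exactly monotone in $\sigma$ and the bisection well
posed; the tolerance is 0.1 on the reporting scale.

Notes on this construction:

* On the probability scale the implied prior on $p$ is asymmetric whenever
  the center is away from 0.5, so the delta-method guess
  $\sigma_0 = (t/100/\sqrt2)/(p(1-p))$ is only the small-$\sigma$ limit;
  the simulation-based tuner is the definition.
* For rare characteristics (center of a few percent) a 10-unit target
  spread forces a wide, strongly right-skewed prior on $p$. The prior is
  then nearly uninformative relative to the likelihood, and the posterior
  essentially reproduces the raw difference. Published contrasts for the
  two smallest cells in the bundled fixture (glove hits, goalies) are
  visibly *more* shrunken than any prior satisfying the 10-unit rule can
  produce, so the per-variable priors behind those two published cells must
  have differed from the uniform rule; this package applies the single
  stated rule uniformly and documents the divergence rather than
  reverse-engineering per-cell prior widths.
* Degenerate centers (a zero or full cell) would put the logit at
  $\pm\infty$; the center is continuity-adjusted to $(y+0.5)/(n+1)$, which
  keeps the logit finite without materially moving it.
* The same tuning rule, with the same default target of 10, is applied on
  the incidence scale (10 events/100 games). The tuning target is a config
  knob (`target_sd_diff`) for users who want a different skepticism level,
  and `sensitivity_grid()` provides the documented robustness variants
  ($\sigma$ multipliers 0.5/1/2/5 and an uncentered $\mu = 0$ prior).

## Posterior computation: two engines

Because the model is one-dimensional, the package carries a deterministic
oracle alongside the sampler, and tests hold them to agreement within
Monte-Carlo error.

**Quadrature.** The log posterior kernel
$y\alpha - n\log(1+e^\alpha) - (\alpha-\mu)^2/2\sigma^2$ is evaluated on a
fixed grid of 8192 points centered at the posterior mode with half-width 12
posterior-scale units (scale from the Laplace approximation
$1/\sqrt{n\hat p(1-\hat p)+\sigma^{-2}}$). If the endpoint density is not
negligible relative to the mode ($<10^{-10}$) the grid is widened and the
evaluation retried. The normalized CDF is inverted at the midpoints of $D$
equal-probability bins, giving $D$ deterministic quantile-spaced
pseudo-draws (default 4000). The midpoint rule leaves a small tail
discretization bias in the pseudo-draw mean — about $2\times10^{-4}$ on
the probability scale at $D = 4000$, well below the sampler's Monte-Carlo
error — which is why pseudo-draws are also randomly permuted before
pairing in contrasts.

**Random-walk Metropolis.** Four chains of 2000 iterations; the first half
of each chain is warmup, during which the log step size is adapted by
stochastic approximation (gain $t^{-0.6}$) toward the one-dimensional
optimal acceptance rate 0.44, then frozen. Gradient-based samplers buy
nothing in one dimension; what matters is the behavioral contract around
convergence, which is preserved: the kept halves are gated by the
**rank-normalized split R-hat** (each chain split in half, pooled draws
rank-normalized via normal scores, classic between/within variance ratio),
with the conventional 1.01 threshold. Constant chains return `NA`
("undefined") rather than a number.

Initialization is over-dispersed around the *posterior* Laplace
location/scale (mode $\pm\,2\,\text{scale}$ plus draws from
$\mathcal N(\text{mode}, 2\,\text{scale})$). Dispersing relative to the
prior instead is pathological under a near-flat prior (chains would start
thousands of logit units from the mass and cannot recover within warmup),
and the flat-prior limit (posterior mean $\to y/n$) is part of the test
contract.

At 4000 kept draws the split R-hat itself is a noisy statistic: a
perfectly healthy model trips the 1.01 gate in roughly 1% of seeds, and a
33-model run amplifies that to a regular occurrence. The pipeline therefore
responds the way a practitioner would: a model failing the gate is refit
with doubled iterations (thinned back to the same kept-draw count, so
contrasts always pair equal counts), escalating twice before the run
refuses to summarize (`force = TRUE` overrides, flagged). `posterior_mcmc()`
itself never retries; it just reports.

## Contrasts

Draw pairing permutes both cohorts' draws with seeded permutations, then
takes $d_i = 100(p^{(2)}_i - p^{(1)}_i)$. Summaries are the mean (exactly
the difference of the cohort means, by linearity, regardless of the
permutation), equal-tailed percentile intervals with base R's type-7
interpolation, and the three-way sign split (below / at / above zero),
which partitions the draws exactly. Intervals are percentile rather than
highest-posterior-density: the posteriors here are near-symmetric, and the
percentile interval is the reproducible default. Differences are stored
signed (post minus pre) — reporting layers may flip the sign for "reduction"
phrasing, but storage never does.

## The synthetic season generator

`simulate_season()` emulates exactly the process the model assumes: per
game an event is Bernoulli(`incidence_per_game`); each event draws its
characteristics independently from categorical mixtures (location, zone,
period, a mechanism chain in which lateral contact is drawn only for hits
to the head, position, puck possession, penalty); each event carries a
Bernoulli video flag. `aggregate_events()` rebuilds count tables under the
real coding rules: no-video events are excluded from proportion numerators
and denominators, incidence uses all games and all events.
`calibrated_season_configs()` derives a config pair from the bundled
fixture (game counts, incidence, video rates, and mixtures matched to the
observed margins).

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: dependence among characteristics (only the
margins are known, so independence is imposed), within-season trends,
player-level exposure, missing-video informativeness (the video flag is
missing completely at random here, while real video availability improved
over time and may correlate with event type), and item-level missingness of
individual characteristics. A Poisson events-per-game variant exists
(`events_per_game = "poisson"`) for stress-testing the one-event-per-game
assumption.

`calibration_study()` closes the loop: simulate both cohorts, run the full
tuning/fitting/contrast pipeline, and record 90%-interval coverage of the
true difference and the signed bias. At a true null the skeptical prior
helps (coverage at or above nominal, ~0.93 in the bundled check at 200
replicates); under a true −20 pp shift at survey scale the estimate is
shrunk toward zero by roughly 1–3 pp and coverage drops toward ~0.8 —
the documented, intentional price of skepticism.

## Numerical and design choices

* Display rounding is half-away-from-zero at 1 decimal, applied only at
  render time; all stored artifacts keep full precision.
* The log-likelihood uses the `log1p(exp(-|alpha|))` decomposition, stable
  past $|\alpha| = 40$.
* Seeds: one master seed; every tuner run, chain, permutation, and
  simulation replicate uses a deterministic 32-bit substream
  (`(seed*1009 + i*9973) mod (2^31-1)`). Identical configurations produce
  byte-identical artifact bundles.
* Per-variable denominators are stored explicitly rather than inherited
  from the cohort, because item-level missing data make them differ; the
  bundled fixture records the denominator implied by each published
  percentage. No hierarchy constraint is enforced between nested mechanism
  rows — each variable is modeled marginally, and no multiplicity
  adjustment is applied across the 16 variables.
* Problem sizes in the shipped tests: tuner evaluations use $10^5$
  replicates, the engine-equivalence battery uses 20 randomized cells, and
  the calibration study uses 200 replicates at the two cohorts' real game
  counts — sizes at which every Monte-Carlo band in the tests is a small
  fraction of the scientific tolerances.

## Known limitations

* The published analysis's exact per-variable prior widths are not public;
  this package re-derives them from the single stated tuning rule. For
  large cells the reconstruction matches the published contrasts well
  within reporting tolerances; for the two smallest cells it provably
  cannot (see above), and for one published zone row whose modeled cell
  contradicts its own raw columns (it duplicates another row verbatim) the
  package trusts the arithmetic, not the duplicate.
* The overall-incidence 90% interval as published is wider than the
  binomial likelihood admits under any log-concave prior; the package
  reproduces the published mean but reports the likelihood-consistent
  interval.
* The sampler is a random-walk Metropolis specialized to one dimension; it
  is not intended for multi-predictor extensions.

## A worked example

```{r example, eval = FALSE}
library(headcheck)

fit <- fit_contrasts(rule48_counts(), scale = "pp", engine = "mcmc")
tidy(fit)          # one row per characteristic, full precision
render_table(fit)  # publication-style "y (pct) | mean (lo to hi)" rows
autoplot(fit)      # 70/90% interval chart

inc <- incidence_counts(rule48_counts(), rule48_cohorts())
fit_contrasts(inc, scale = "per_100_games") |> render_table()
```
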