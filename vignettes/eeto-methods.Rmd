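---
title: "Quantifying explore–exploit strategies in fleet movement data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying explore–exploit strategies in fleet movement data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Foraging agents trade off exploiting known resource patches against
exploring new ones. In a commercial fishery the trade-off is observable:
vessel-monitoring systems (VMS) record hourly positions, logbooks record
trip revenues, and a spatial closure provides a natural experiment in which
the portfolio of available options shrinks abruptly. `eetofleet` measures
each vessel's explore–exploit (EETO) strategy from its track and asks two
questions: does strategy predict performance in ordinary times, and does a
history of exploration buffer revenue when preferred grounds close?

Because the motivating data (VMS pings, observer labels, logbooks for a
bottom-longline fleet) are confidential, the package pairs the analysis
pipeline with a seeded synthetic-fleet generator that reproduces their
*structure*. The generator is first-class, tested code: every inferential
claim the package makes is demonstrated by recovering known quantities from
generated fleets.

## Strategy metrics

**Choice entropy.** Classified fishing pings are rasterized on an
`n × n` grid (default 30, i.e. 900 cells) fitted to the bounding box of the
fleet's fishing activity. Consecutive fishing pings in one cell form a visit
bout; a new element is appended to the vessel's chronological visitation
series when the cell changes or after any port call. For every prefix of
length `m` the Shannon entropy (base 2) of the empirical cell frequencies is

S_m = −Σ_j f(j) log₂ f(j),

yielding a trajectory that rises while new grounds are discovered and
plateaus as the choice distribution stabilizes. The strategy score `S` is
the mean of the trajectory after discarding the first half as burn-in
(`floor(length/2)`; the floor rule means an even-length series contributes
exactly its second half). Higher `S` = broader exploration. Vessels with
fewer than 20 visitation elements (configurable) are excluded as sparse.

**Patch residence time (PRT)** is the arithmetic mean bout duration, in
hours, with one ping interval added to each bout so single-ping bouts have
nonzero duration. Lower PRT = faster exploration.

**Displacement** is the fraction of a vessel's pre-closure fished cell
centres that fall inside the closure polygon (point-in-polygon via
`mgcv::in.out`); a vessel scoring 0.8 lost 80% of its grounds.

**Activity** is the sum of trip durations landing in a lagged window,
guarding against endogeneity between contemporaneous effort and revenue.

Grid resolution is a free choice, so `grid_sensitivity()` recomputes `S` on
grids from 20 × 20 to 95 × 95 and reports Spearman correlations against the
default; on generated fleets with well-separated strategies adjacent sizes
correlate above 0.9. `depth_entropy_check()` regresses `S` on mean fishing
depth — the generator draws strategy independently of location, so the
reported slope is a null diagnostic, not an assertion.

## The counterfactual revenue model

Trip revenue during the undisturbed period is modelled with vessel-identity
fixed effects,

Ru_it = P_i + β₁·D_it + β₂·F₋it + ε_it,

where `D` is trip duration (days) and `F₋it` the *fleet index*: the mean raw
revenue of all other vessels' trips landing in the half-open 14-day window
after trip *t*. The index absorbs shared temporal shocks (seasonality,
storms, prices) without using the vessel's own revenues.
`window_bias_check()` quantifies the skew-window approximation by
correlating the forward index against a symmetric ±7-day version. Absolute
per-vessel performance is the reference-coded vessel estimate plus the
intercept.

Two numerical choices deserve explanation:

* **The fleet index is centred inside the fit.** The raw index lives on the
  revenue scale (mean ≈ fleet-average revenue), so an uncentred fit would
  define `P_i` as an extrapolation to *zero fleet revenue* — typically
  negative. Centring makes `P_i` the vessel's expected performance at
  average fleet conditions; slopes are unchanged.
* **Identity link by default.** The deviance arithmetic below subtracts
  `β̂₁D + β̂₂F` linearly, which is coherent only on the identity scale. A
  `link_mode = "log"` option applies the entire chain to log revenue
  instead; neither mode is asserted to be the uniquely correct one.

During the closure, measured performance removes the duration and fleet
effects from disturbed revenue, `Md_it = Rd_it − β̂₁D_it − β̂₂F₋it`, expected
performance is the business-as-usual prediction of that same quantity —
the vessel's absolute undisturbed performance, `Ed_it = P_i` — and the
standardized deviance is `ΔP_it = Md_it/Ed_it − 1`: zero when the trip
earned exactly what the undisturbed model predicts, with like compared to
like on both sides of the ratio. Trips landing in the fortnight before the
closure are pruned (their index windows straddle the onset), and revenue
outliers are removed by an unattended rule (any value exceeding five times
the largest remaining other value, iteratively from the top) that
generalizes a manual dot-plot check.

## Inference

Continuous covariates are standardized to z-scores; quadratic terms are
squares of the standardized linear terms, so hump tests are centred on the
fleet mean. The pre-disturbance cross-section is ordinary least squares of
`P_i` on S, S², prt, prt², activity and length. Disturbed-period deviance is
a linear mixed model with a per-vessel random intercept (REML, `lme4`),
because trip counts vary across vessels; p-values use the normal
approximation to the Wald statistic and CIs are Wald intervals — the package
takes no position on mixed-model degrees of freedom.

Stepwise selection drops, one term at a time, the term whose removal lowers
(or leaves unchanged) **both** AIC and BIC, never removing a linear term
while its quadratic survives, with ties resolved toward the simpler model.
Mixed models are compared under maximum likelihood and refitted with REML
after selection.

The growing-window analysis refits the deviance model to nested subsets of
the closure period ([0, 10], [0, 20], … [0, 50] days). With
`select = TRUE` (used by the pipeline) each window's model is
stepwise-reduced with entropy and displacement protected, reflecting that
small early windows cannot support the full eight-term specification; with
the default `select = FALSE` the final window reproduces a direct full fit
exactly, which the tests assert.

Fleet-level strategy shifts (scores of all pre-closure vessels vs. vessels
still fishing during it) are compared with one-way ANOVA
(`fleet_shift_test()`); disturbance-period entropy is recomputed from
disturbance-period series under the same burn-in rule, behind a flag.

## The synthetic fleet generator

`generate_fleet()` draws, per vessel and from per-vessel sub-streams of one
master seed (so individual vessels are reproducible under fleet-size
changes): a portfolio of 3–25 candidate cells clustered around a home centre
(broad portfolios spread wider, so explorers also travel farther per unit
revenue); choice weights from a symmetric Dirichlet whose concentration
(log-uniform on 0.25–4) sets the vessel's entropy tendency; a mean bout
duration (4–16 h); a true mean performance (skill ~ N(10000, 1500²) revenue
units); and a hull length. Fleet effort concentrates around prime grounds so
that closing the most-used cells displaces some vessels far more than
others.

Trips alternate exponential port stays (mean 4 days, 1.5 days after the
closure — vessels cycle faster while re-establishing grounds, and port gaps
never enter revenue) with 2–15-day trips; within a trip, bout cells are
drawn from the weights with no immediate repeat and bout durations are
lognormal around the vessel's mean. Revenue is
`skill + 250·days + signal + N(0, 200)`, with a shared daily signal of a
2000-unit annual sinusoid plus weather-persistent AR(1) shocks
(`0.9`, innovation sd 300). Track expansion produces hourly pings: dockside
jitter in port, straight transit legs at ~5 m/s, and slow (< 2 m/s) jitter
around each bout's set location, confined to its cell — the two speed
regimes are separable, as in real longline tracks, which is what lets a
random forest reach high balanced accuracy. A configurable fraction of
trips (20%) carries ground-truth labels, standing in for observer coverage.

The disturbance closes the bounding rectangle of the most-used cells
(covering 35% of fleet fishing effort). Each vessel exits with probability
`plogis(−1.5 · S̃)` (S̃ = standardized true entropy), so broad explorers are
more likely to keep fishing — roughly half the fleet exits at the default
baseline. Survivors replace each closed cell with the nearest open cell,
inheriting its weight: portfolio breadth carries over while grounds shift,
which is what lets selection (not mechanical portfolio truncation) drive the
fleet-level entropy shift. Disturbed revenue perturbs the *performance
component*: `Rd = BAU + skill·δ`, with

δ_it = (0.8·S̃_i − 0.5·d̃_i) · 2^(−days/14) + N(0, 0.03),

so a trip's business-as-usual deviance equals δ by construction (duration
and fleet terms are controlled away by the counterfactual), the entropy
benefit and displacement penalty are interpretable per SD, and both halve
every 14 days.

### Calibration of the free parameters

No natural-scale effect sizes exist for the disturbance response, so the
generator's coefficients are free parameters chosen once for clear signal at
the design scale of ~100 vessels: large enough that sign recovery, the
dissipation trajectory, and the fleet-entropy shift are detectable in a
single simulated study, small enough that deviances stay in a plausible
range (roughly ±1 near the onset for extreme vessels).

Two interactions between the generator and the counterfactual method
required care, and they are genuine properties of the method, not artifacts:

* The fleet index is a *forward-window* mean, so it leads the shared signal
  by about half a window; if the closure sits on a steep seasonal slope the
  lead leaks into `Md` (the same skew-window approximation
  `window_bias_check()` measures).
* The index is also slightly attenuated (`β̂₂ < 1`), because a 14-day window
  mean cannot track fast shocks; at a seasonal extremum the unremoved level
  leaks with the opposite sign.

The default world therefore opens the closure on the late seasonal rise,
about two weeks before the annual revenue peak — as in a late-spring closure
ahead of a summer high season — where the two leaks offset and fleet-mean
deviance is centred under a business-as-usual null. Because the index error
is shared by all trips landing in the same window, the unit of replication
for that null check is the simulated study, not the trip: tests compare the
grand mean of per-study fleet means against the across-study standard error.

## What the tests do and do not show

Passing tests demonstrate that the pipeline's statistics do what they claim
on data whose generating process is known and favourable: activity classes
with separable speed regimes, a shared revenue signal that the fleet index
can largely remove, effects that are linear in standardized covariates, and
Gaussian noise. Real VMS and logbook data are harsher — transponder gaps,
speed regimes that overlap (drifting, searching), market dynamics that a
14-day leave-one-out mean does not span, strategy drift within vessels, and
revenue that is not a linear function of anything. Results on the synthetic
fleet bound what the method can do under its own assumptions; they do not
certify performance on any particular real fleet.

Known limitations: a single port and a single gear; no travel-cost term in
revenue (travel cost appears only through the revenue-per-km diagnostic);
exit is a one-shot decision at closure onset rather than a hazard over time;
and the closure is a rectangle. The confidentiality masking of real fishing
maps, and ingestion of real bathymetry, are out of scope — the synthetic
depth surface exists only to exercise the depth covariate and its
diagnostic.

## Problem sizes

Default study conditions are 100 vessels, one undisturbed year and a 60-day
closure (~876,000 hourly pings, ~2,700 undisturbed trips — comparable to the
logbook scale the design emulates). Property checks in the test suite run
tens of seeded replicates of the trip-level generator at these conditions
and reserve full track expansion (ping-level simulation plus the random
forest) for the classifier checks, where it is the object under test.
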