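# eetofleet

Explore–exploit strategies and disturbance response in fishing fleets.

Commercial fishing captains repeatedly face the explore–exploit trade-off
(EETO): keep working known grounds with predictable returns, or spend time
and fuel sampling new ones. `eetofleet` quantifies where each vessel sits on
that continuum from its movement track and estimates what the strategy is
worth — in ordinary times and during a spatial closure that abruptly removes
the fleet's most-used grounds.

The package implements the full analysis pipeline for vessel-monitoring
(VMS) position records, observer-labelled activity, and trip-level logbooks:

1. **Track processing** — clean hourly pings (extent filter, duplicate
   resolution, iterative deletion of >20 m/s position errors with rhumb-line
   speed derivation), derive movement features, and classify each ping as
   fishing / transit / port with a 500-tree random-forest ensemble validated
   on a held-out half of the observer-labelled pings.
2. **Fishing grounds** — rasterize fishing pings on a 30 × 30 grid fitted to
   the fleet's extent, build each vessel's portfolio of fished cells and its
   chronological visitation series **L**ᵢ (one element per visit bout).
3. **EETO metrics** — choice entropy
   `S_im = −Σⱼ fᵢ(j) log₂ fᵢ(j)` computed cumulatively over every prefix of
   **L**ᵢ (score = mean after a 50% burn-in), patch residence time (mean
   bout duration), displacement (proportion of pre-closure fished cells
   inside the closure polygon), and lagged activity.
4. **Counterfactual performance** — undisturbed revenue model
   `Ru_it = P_i + β₁D_it + β₂F₋it + ε` (vessel fixed effects, trip duration,
   and a leave-one-out fleet index over the 14 days after each trip), then
   per-trip business-as-usual deviance during the closure:
   `Md_it = Rd_it − β̂₁D_it − β̂₂F₋it`, `ΔP_it = Md_it / Ed_it − 1`.
5. **Inference** — standardized-covariate regressions of performance and
   deviance on entropy, PRT (linear + quadratic), activity, length and
   displacement; stepwise AIC/BIC selection; vessel-level random-intercept
   mixed models; fleet-shift ANOVAs; and a growing-window analysis tracing
   how strategy effects dissipate after the closure.

The real fisheries data behind this design are confidential, so the package
ships a first-class, seeded **synthetic fleet generator**
(`fleet_config()`, `generate_fleet()`, `simulate_tracks()`,
`simulate_disturbance()`) that emulates their structure — heterogeneous
strategies, hourly pings, seasonal fleet-wide revenue, entropy-dependent
exit at the closure, and decaying deviance effects — making every stage
testable end to end.

## Worked example

```r
library(eetofleet)

world  <- sim_world()
config <- fleet_config(n_vessels = 40, undisturbed_days = 365,
                       disturbed_days = 50, seed = 42)
fleet  <- generate_fleet(config, world)

und  <- simulate_trips(fleet, world, config)      # logbook + true bouts
dist <- simulate_disturbance(fleet, world, config, und)

model <- fit_undisturbed(fleet_performance(und$trips))
round(c(beta_duration = model$beta_duration, beta_fleet = model$beta_fleet), 3)
#> beta_duration    beta_fleet
#>       245.815         0.936

dev <- compute_deviance(model, fleet_performance(dist$trips))

S   <- vapply(split(und$visits, und$visits$vessel_id),
              function(v) entropy_score(entropy_trajectory(v$cell[order(v$start_hour)])),
              numeric(1))
prof <- tibble::tibble(
  vessel_id = names(S), S = S,
  prt = tapply(und$visits$bout_hours, und$visits$vessel_id, mean)[names(S)],
  activity = tapply(und$trips$duration_days, und$trips$vessel_id, sum)[names(S)],
  length = fleet$length_m[match(names(S), fleet$vessel_id)],
  displacement = dist$exit_flags$displacement_true[match(names(S), fleet$vessel_id)])

mm <- fit_deviance_model(dev, scale_covariates(prof))
subset(as.data.frame(mm$coefs), term %in% c("S", "displacement"))
#>           term   estimate         se         z            p        lo95        hi95
#> 2            S  0.2491546 0.08656578  2.878211 3.999378e-03  0.07948564  0.41882350
#> 8 displacement -0.1581750 0.03511046 -4.505066 6.635229e-06 -0.22699146 -0.08935845
```

The true duration effect in this configuration is 250 revenue units per day
and the fleet-signal multiplier is 1, so the undisturbed model recovers both
within sampling error. In the mixed model, each standard deviation of choice
entropy is worth about +25% better-than-expected revenue averaged over the
whole closure (the injected effect starts at +80% per SD and halves every 14
days), while each SD of displacement costs about 16% — the buffering value
of a broad exploration history, and the cost of losing grounds, on this
simulated fleet of 40 vessels (99 disturbed trips). The
`growing_window()` trajectory of the same model shows both effects decaying
over the first 50 days.

The orchestrated version of the same analysis (classifying simulated pings
with the random forest rather than using generator truth) is one call:

```r
run_pipeline("all", run_config(fleet = config), "my_run")
```

which writes `classified_pings.csv`, `profiles.csv`, `deviance.csv`,
`growing_window.csv`, model summaries as JSON, and a run log, every artifact
stamped with the seed and configuration hash.

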