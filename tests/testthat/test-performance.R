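toy_trips <- function() {
  tibble::tibble(
    vessel_id = c("A", "B", "C", "D"),
    trip_id = paste0("T", 1:4),
    landing_date = as.Date("2008-01-01") + c(0, 5, 10, 20),
    duration_days = c(5, 5, 5, 5),
    revenue = c(10, 20, 40, 80))
}

test_that("the fleet index is the leave-one-out mean over the forward window", {
  t <- fleet_performance(toy_trips(), window_days = 14)
  # for A's trip at day 0: B (20, day 5) and C (40, day 10) qualify; D at day 20 does not
  expect_equal(t$fleet_index[t$vessel_id == "A"], 30)
  # only one qualifying trip: index equals that revenue
  expect_equal(t$fleet_index[t$vessel_id == "C"], 80)
  # nothing lands after D's trip
  expect_true(is.na(t$fleet_index[t$vessel_id == "D"]))

  # leave-one-out invariance: perturbing vessel A's own revenue
  t2 <- toy_trips(); t2$revenue[t2$vessel_id == "A"] <- 9999
  out2 <- fleet_performance(t2, window_days = 14)
  expect_equal(out2$fleet_index[out2$vessel_id == "A"],
               t$fleet_index[t$vessel_id == "A"])
})

test_that("skewed and symmetric index windows agree on seasonal fleets", {
  cfg <- fleet_config(n_vessels = 60, undisturbed_days = 365, disturbed_days = 10,
                      seed = 22)
  world <- sim_world()
  fleet <- generate_fleet(cfg, world)
  sim <- simulate_trips(fleet, world, cfg)
  res <- window_bias_check(sim$trips)
  expect_gt(res$r, 0.8)
  expect_lt(res$p, 0.001)
  # degenerate constant revenue: correlation undefined, reported as such
  const <- toy_trips()
  const$revenue <- 10
  const <- dplyr::bind_rows(const, const, const)
  const$vessel_id <- rep(c("A", "B", "C", "D"), 3)
  const$landing_date <- as.Date("2008-01-01") + seq_len(12)
  res2 <- window_bias_check(const)
  expect_true(is.na(res2$r))
})

test_that("boundary trips are pruned exactly two weeks before the closure", {
  closure <- as.Date("2009-05-19")
  trips <- tibble::tibble(
    vessel_id = "A", trip_id = paste0("T", 1:3),
    landing_date = closure - c(13, 15, 40),
    duration_days = 5, revenue = 10)
  out <- prune_boundary_trips(trips, closure)
  expect_false(any(out$landing_date == closure - 13))
  expect_true(all((closure - c(15, 40)) %in% out$landing_date))
  expect_equal(attr(out, "n_pruned"),
               sum(trips$landing_date >= closure - 14 & trips$landing_date < closure))
})

test_that("revenue outliers are removed iteratively from the top", {
  mk <- function(r) tibble::tibble(vessel_id = "A", trip_id = seq_along(r),
                                   landing_date = as.Date("2008-01-01"),
                                   duration_days = 1, revenue = r)
  expect_equal(remove_revenue_outliers(mk(c(1, 1, 1, 10)))$revenue, c(1, 1, 1))
  expect_equal(remove_revenue_outliers(mk(c(1, 1, 1, 4)))$revenue, c(1, 1, 1, 4))
  # ~8 times the second-largest value: removed
  out <- remove_revenue_outliers(mk(c(100, 12, 10, 9)))
  expect_false(100 %in% out$revenue)
  expect_equal(attr(out, "n_outliers"), 1L)
})

test_that("the revenue model identifies generator coefficients exactly without noise", {
  cfg <- small_config(noise_sd = 0)
  world <- sim_world()
  fleet <- generate_fleet(cfg, world)
  sim <- simulate_trips(fleet, world, cfg)
  trips <- sim$trips
  # regression on duration and the true fleet signal (the generating covariate)
  day_idx <- pmin(pmax(ceiling(trips$landing_day), 1L), length(sim$signal))
  trips$fleet_index <- sim$signal[day_idx]
  m <- fit_undisturbed(trips)
  expect_equal(m$beta_duration, cfg$beta_duration, tolerance = 1e-8)
  expect_equal(m$beta_fleet, cfg$beta_fleet, tolerance = 1e-8)
  skill <- fleet$skill[match(m$P$vessel_id, fleet$vessel_id)]
  # absolute P_i is skill up to the centred-index offset, common to all vessels
  expect_lt(stats::sd((m$P$P - skill)), 1e-6)

  # permuting trip order leaves the estimates unchanged
  perm <- trips[sample(nrow(trips)), ]
  m2 <- fit_undisturbed(perm)
  expect_equal(m2$beta_duration, m$beta_duration, tolerance = 1e-10)
  expect_equal(m2$P$P[order(m2$P$vessel_id)], m$P$P[order(m$P$vessel_id)],
               tolerance = 1e-10)
})

test_that("per-vessel performance is covered by its confidence interval at nominal rate", {
  world <- sim_world()
  hits <- 0; total <- 0
  for (s in 1:12) {
    cfg <- fleet_config(n_vessels = 12, undisturbed_days = 200, disturbed_days = 10,
                        seed = 400 + s)
    fleet <- generate_fleet(cfg, world)
    sim <- simulate_trips(fleet, world, cfg)
    trips <- sim$trips
    day_idx <- pmin(pmax(ceiling(trips$landing_day), 1L), length(sim$signal))
    trips$fleet_index <- sim$signal[day_idx]
    m <- fit_undisturbed(trips)
    # with the centred index, absolute P_i estimates skill + b2 * mean(F)
    truth <- fleet$skill[match(m$P$vessel_id, fleet$vessel_id)] +
      cfg$beta_fleet * m$fleet_center
    X <- stats::model.matrix(m$fit)
    V <- stats::vcov(m$fit)
    for (i in seq_len(nrow(m$P))) {
      cvec <- rep(0, ncol(X)); names(cvec) <- colnames(X)
      cvec["(Intercept)"] <- 1
      nm <- paste0("vessel_id", m$P$vessel_id[i])
      if (nm %in% names(cvec)) cvec[nm] <- 1
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      hits <- hits + (abs(m$P$P[i] - truth[i]) <= 1.96 * se)
      total <- total + 1
    }
  }
  expect_gt(hits / total, 0.85)
})

test_that("deviances are null-centred, monotone in revenue, and scale-free", {
  # the leave-one-out index error is shared across trips in a window, so the
  # unit of replication for the null-centring check is the simulated fleet:
  # grand mean of per-seed fleet means against the across-seed SE. The
  # undisturbed period is an integer year so the seasonal signal has equal
  # footing in the index centre and the counterfactual window.
  world <- sim_world()
  seed_means <- vapply(1:8, function(s) {
    cfgn <- fleet_config(n_vessels = 30, undisturbed_days = 365, disturbed_days = 50,
                         deviance_entropy_coef = 0, deviance_displacement_coef = 0,
                         seed = s)
    fleetn <- generate_fleet(cfgn, world)
    undn <- simulate_trips(fleetn, world, cfgn)
    distn <- simulate_disturbance(fleetn, world, cfgn, undn)
    mn <- fit_undisturbed(suppressMessages(fleet_performance(undn$trips)))
    devn <- suppressMessages(compute_deviance(mn, fleet_performance(distn$trips)))
    mean(devn$deltaP)
  }, numeric(1))
  expect_lt(abs(mean(seed_means)),
            2 * stats::sd(seed_means) / sqrt(length(seed_means)))

  cfg <- fleet_config(n_vessels = 30, undisturbed_days = 365, disturbed_days = 50,
                      deviance_entropy_coef = 0, deviance_displacement_coef = 0,
                      seed = 7)
  fleet <- generate_fleet(cfg, world)
  und <- simulate_trips(fleet, world, cfg)
  dist <- simulate_disturbance(fleet, world, cfg, und)
  m <- fit_undisturbed(fleet_performance(und$trips))
  dt <- fleet_performance(dist$trips)
  dev <- compute_deviance(m, dt)
  # dP = 0 iff Md = Ed
  expect_equal(dev$deltaP == 0, dev$Md == dev$Ed)

  # doubling disturbed revenue shifts deviance positive
  dt2 <- dt; dt2$revenue <- dt2$revenue * 2
  dev2 <- compute_deviance(m, dt2)
  expect_true(all(dev2$deltaP > dev$deltaP))

  # rescaling all revenues by a common factor leaves deviance unchanged
  und3 <- und; und3$trips$revenue <- und3$trips$revenue * 3
  dt3 <- dt; dt3$revenue <- dt3$revenue * 3; dt3$fleet_index <- dt3$fleet_index * 3
  m3 <- fit_undisturbed(fleet_performance(und3$trips))
  dev3 <- compute_deviance(m3, dt3)
  expect_equal(dev3$deltaP, dev$deltaP, tolerance = 1e-8)
})

test_that("null deviances are approximately Gaussian", {
  cfg <- fleet_config(n_vessels = 50, undisturbed_days = 150, disturbed_days = 60,
                      deviance_entropy_coef = 0, deviance_displacement_coef = 0,
                      seed = 12)
  world <- sim_world()
  fleet <- generate_fleet(cfg, world)
  und <- simulate_trips(fleet, world, cfg)
  dist <- simulate_disturbance(fleet, world, cfg, und)
  m <- fit_undisturbed(fleet_performance(und$trips))
  dev <- compute_deviance(m, fleet_performance(dist$trips))
  expect_gte(nrow(dev), 50)
  set.seed(1)
  samp <- dev$deltaP[sample(nrow(dev), 50)]
  expect_gt(stats::shapiro.test(samp)$p.value, 0.01)
})

test_that("the log-link mode runs the counterfactual chain on the log scale", {
  sim <- small_sim()
  und <- fleet_performance(sim$und$trips)
  m <- fit_undisturbed(und, link_mode = "log")
  expect_equal(m$link_mode, "log")
  dev <- compute_deviance(m, fleet_performance(sim$dist$trips))
  expect_true(all(is.finite(dev$deltaP)))
})
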