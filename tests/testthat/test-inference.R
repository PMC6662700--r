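fake_profiles <- function(n = 40, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    vessel_id = sprintf("V%03d", seq_len(n)),
    S = rnorm(n, 4, 1), prt = rlnorm(n, 2, 0.4),
    activity = rpois(n, 120), length = runif(n, 15, 30),
    displacement = runif(n))
}

test_that("covariate scaling produces unit z-scores with interpretable quadratics", {
  p <- tibble::tibble(vessel_id = c("a", "b", "c"), S = c(1, 2, 3),
                      prt = c(2, 4, 9), activity = c(1, 5, 9),
                      length = c(10, 20, 30), displacement = c(0, 0.5, 1))
  sc <- scale_covariates(p)
  expect_equal(sc$S, c(-1, 0, 1))
  expect_equal(sc$S2, c(1, 0, 1))
  for (cn in c("S", "prt", "activity", "length", "displacement")) {
    expect_equal(mean(sc[[cn]]), 0, tolerance = 1e-9)
    expect_equal(stats::sd(sc[[cn]]), 1, tolerance = 1e-9)
  }
  # affine invariance and idempotence
  p2 <- p; p2$S <- 100 + 7 * p$S
  expect_equal(scale_covariates(p2)$S, sc$S)
  expect_equal(as.numeric(scale(sc$S)), sc$S)
  p3 <- p; p3$length <- 5
  expect_error(scale_covariates(p3), "length")
})

test_that("the pre-disturbance regression recovers injected covariate effects", {
  prof <- fake_profiles(100, seed = 3)
  cov <- scale_covariates(prof)
  # linear length effect
  P1 <- tibble::tibble(vessel_id = prof$vessel_id,
                       P = 10000 + 800 * cov$length + rnorm(100, 0, 200))
  r1 <- fit_performance_model(P1, cov)
  len <- r1$coefs[r1$coefs$term == "length", ]
  expect_lt(abs(len$estimate - 800), 1.96 * len$se)
  # humped entropy effect: significantly negative quadratic
  P2 <- tibble::tibble(vessel_id = prof$vessel_id,
                       P = 10000 - 500 * cov$S2 + rnorm(100, 0, 200))
  r2 <- fit_performance_model(P2, cov)
  s2 <- r2$coefs[r2$coefs$term == "S2", ]
  expect_lt(s2$estimate, 0)
  expect_lt(s2$p, 0.01)
  expect_error(fit_performance_model(P2[1:5, ], cov[1:5, ]), "too few")
})

test_that("stepwise selection respects hierarchy and finds fixed points", {
  prof <- fake_profiles(100, seed = 5)
  cov <- scale_covariates(prof)
  cov$P <- 1000 + 400 * cov$S + rnorm(100, 0, 100)
  sel <- stepwise_select("P", c("S", "S2", "prt", "prt2", "activity", "length"), cov)
  expect_true("S" %in% sel$terms)
  # hierarchy: S2 must have been dropped before S could be considered;
  # no trace row drops a linear term while its quadratic survives
  if (nrow(sel$trace) > 0) {
    remaining <- c("S", "S2", "prt", "prt2", "activity", "length")
    for (i in seq_len(nrow(sel$trace))) {
      t <- sel$trace$dropped[i]
      expect_false(paste0(t, "2") %in% remaining)
      remaining <- setdiff(remaining, t)
    }
  }
  # an already-minimal model is returned unchanged
  sel2 <- stepwise_select("P", sel$terms, cov)
  expect_setequal(sel2$terms, sel$terms)

  # pure noise: everything droppable goes in most runs
  kept <- vapply(1:50, function(s) {
    set.seed(s)
    cov$Pn <- rnorm(100)
    length(stepwise_select("Pn", c("S", "prt", "activity", "length"), cov)$terms)
  }, numeric(1))
  # with the both-criteria drop rule each spurious term survives ~16% of
  # the time, so intercept-only is the modal but not dominant outcome
  expect_gt(mean(kept == 0), 0.35)
  expect_gt(mean(kept <= 1), 0.85)

  # a strong single effect survives selection in every run
  always <- vapply(1:50, function(s) {
    set.seed(100 + s)
    cov$Ps <- 1000 + 500 * cov$length + rnorm(100, 0, 100)
    "length" %in% stepwise_select("Ps", c("S", "prt", "activity", "length"), cov)$terms
  }, logical(1))
  expect_true(all(always))
})

test_that("the deviance mixed model collapses to OLS in degenerate designs", {
  prof <- fake_profiles(30, seed = 8)
  cov <- scale_covariates(prof)
  # one trip per vessel: no information to separate the random intercept
  set.seed(2)
  dev <- tibble::tibble(vessel_id = prof$vessel_id, trip_id = paste0("T", 1:30),
                        days_since_closure = runif(30, 0, 50),
                        Md = 0, Ed = 1,
                        deltaP = 0.3 * cov$S - 0.3 * cov$displacement + rnorm(30, 0, 0.1))
  mm <- fit_deviance_model(dev, cov)
  ols <- stats::lm(deltaP ~ S + S2 + prt + prt2 + activity + length + displacement,
                   data = dplyr::inner_join(dev, cov, by = "vessel_id"))
  expect_equal(mm$coefs$estimate, unname(stats::coef(ols)), tolerance = 1e-6)

  # balanced design with within-vessel replication: duplicating every trip
  # leaves the fixed-effect point estimates unchanged
  dev3 <- dplyr::bind_rows(lapply(1:3, function(k) {
    d <- dev; d$trip_id <- paste0(d$trip_id, "_", k)
    d$deltaP <- d$deltaP + rnorm(30, 0, 0.05)
    d
  }))
  mm3 <- fit_deviance_model(dev3, cov)
  dev6 <- dplyr::bind_rows(dev3, dev3)
  dev6$trip_id <- paste0(dev6$trip_id, rep(c("a", "b"), each = nrow(dev3)))
  mm6 <- fit_deviance_model(dev6, cov)
  expect_equal(mm6$coefs$estimate, mm3$coefs$estimate, tolerance = 1e-6)
})

test_that("the fleet-shift ANOVA matches hand-computed sums of squares", {
  same <- fleet_shift_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  ft <- fleet_shift_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ft$F, 1.5)
  expect_equal(c(ft$df1, ft$df2), c(1, 4))
  expect_error(fleet_shift_test(1, c(1, 2)), ">= 2")
})

test_that("the fleet-shift test holds its size under permutation", {
  set.seed(33)
  x <- rnorm(60, 4, 1)
  rejections <- vapply(1:1000, function(i) {
    g <- sample(rep(c(TRUE, FALSE), c(35, 25)))
    fleet_shift_test(x[g], x[!g])$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("growing windows are nested and agree with a direct fit on the last window", {
  sim <- small_sim()
  m <- fit_undisturbed(fleet_performance(sim$und$trips))
  dev <- compute_deviance(m, fleet_performance(sim$dist$trips))
  prof <- true_profiles(sim$fleet, sim$und, sim$dist)
  prof <- prof[stats::complete.cases(prof), ]
  cov <- scale_covariates(prof)
  gw <- growing_window(dev, cov, step = 10, horizon = 50)
  expect_true(all(gw$window_end %in% seq(10, 50, 10)))
  direct <- fit_deviance_model(dev[dev$days_since_closure <= 50, ], cov)
  last <- gw[gw$window_end == 50, ]
  expect_equal(last$estimate[match(direct$coefs$term, last$term)],
               direct$coefs$estimate, tolerance = 1e-8)
})

test_that("a time-constant effect yields a flat coefficient trajectory", {
  prof <- fake_profiles(60, seed = 21)
  cov <- scale_covariates(prof)
  set.seed(4)
  reps <- 4L
  dev <- tibble::tibble(
    vessel_id = rep(prof$vessel_id, reps),
    trip_id = paste0("T", seq_len(60 * reps)),
    days_since_closure = runif(60 * reps, 0, 50),
    Md = 0, Ed = 1,
    deltaP = rep(0.4 * cov$S, reps) + rnorm(60 * reps, 0, 0.05))
  gw <- growing_window(dev, cov)
  s <- gw[gw$term == "S", ]
  trend <- stats::lm(estimate ~ window_end, data = s)
  ci <- stats::confint(trend)["window_end", ]
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})
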