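test_that("rhumb distance matches closed forms and an independent implementation", {
  expect_equal(rhumb_distance(0, 0, 0, 0), 0)
  # one degree of longitude at the equator: R * pi/180
  expect_equal(rhumb_distance(0, 0, 1, 0), 111195, tolerance = 1 / 111195)
  # cross-implementation oracle on an oblique pair
  ours <- rhumb_distance(5, 10, 7, 12)
  ref <- geosphere::distRhumb(c(5, 10), c(7, 12), r = 6371000)
  expect_lt(abs(ours - ref) / ref, 0.001)
  # symmetry under swap for pure east-west and north-south pairs
  expect_equal(rhumb_distance(3, 20, 8, 20), rhumb_distance(8, 20, 3, 20))
  expect_equal(rhumb_distance(3, 10, 3, 18), rhumb_distance(3, 18, 3, 10))
  expect_error(rhumb_distance(0, 90, 1, 0), "pole")
  expect_error(rhumb_distance(NA, 0, 1, 0), "finite")
})

make_pings <- function(lon, lat, vessel = "V001", t0 = as.POSIXct("2007-06-01", tz = "UTC")) {
  tibble::tibble(vessel_id = vessel, timestamp = t0 + 3600 * (seq_along(lon) - 1),
                 lon = lon, lat = lat)
}

test_that("speed filtering deletes implausible jumps and recomputes successors", {
  # 1 degree of longitude in one hour at the equator is ~30.9 m/s
  p <- make_pings(c(0, 1, 1.001, 1.002), c(0, 0, 0, 0))
  out <- clean_pings(p, world = NULL, speed_threshold = 20)
  expect_equal(nrow(out), 3)
  expect_false(1 %in% out$lon)  # the jumping ping is gone
  expect_true(all(stats::na.omit(out$speed) <= 20))
  expect_equal(attr(out, "log")$n_speed, 1L)

  # stationary vessel: all speeds zero, everything retained
  q <- make_pings(rep(5, 6), rep(25, 6))
  outq <- clean_pings(q, world = NULL)
  expect_equal(nrow(outq), 6)
  expect_true(all(stats::na.omit(outq$speed) == 0))
})

test_that("cleaning drops out-of-extent pings, resolves duplicates, and is idempotent", {
  world <- sim_world()
  t0 <- as.POSIXct("2007-06-01", tz = "UTC")
  p <- tibble::tibble(
    vessel_id = "V001",
    timestamp = t0 + 3600 * c(0, 1, 1, 2, 3),
    lon = c(-84, -84.01, -84.01, -50, -84.02),  # -50 is far outside
    lat = c(27, 27.01, 27.01, 27, 27.02))
  out <- clean_pings(p, world)
  log <- attr(out, "log")
  expect_equal(log$n_extent, 1L)
  expect_equal(log$n_dupes, 1L)
  expect_equal(nrow(out), 3)
  expect_true("depth" %in% names(out))

  # idempotence on a realistic noisy track
  tk <- small_tracks()
  sub <- tk$sim$pings[tk$sim$pings$vessel_id == tk$sim$pings$vessel_id[1], ]
  once <- clean_pings(sub, tk$world)
  twice <- clean_pings(once, tk$world)
  attr(once, "log") <- NULL; attr(twice, "log") <- NULL
  expect_equal(twice, once)
})

test_that("turning angles follow track geometry", {
  world <- sim_world()
  # collinear, equally spaced: zero turn
  p <- make_pings(c(-84, -84.01, -84.02), c(27, 27, 27))
  f <- derive_features(clean_pings(p, world), world)
  expect_equal(f$turn_angle, 0, tolerance = 1e-6)
  # out and back: 180 degrees
  p <- make_pings(c(-84, -84.01, -84), c(27, 27, 27))
  f <- derive_features(clean_pings(p, world), world)
  expect_equal(f$turn_angle, 180, tolerance = 1e-6)
  # small-scale right-angle dogleg: ~90 degrees
  p <- make_pings(c(-84, -84.01, -84.01), c(27, 27, 27.01))
  f <- derive_features(clean_pings(p, world), world)
  expect_equal(f$turn_angle, 90, tolerance = 0.05)
  # hour of day and port displacement populated
  expect_true(all(f$hour >= 0 & f$hour < 24))
  expect_true(all(f$port_km > 0))
  # vessels with < 3 pings yield no rows, with a warning
  expect_warning(
    empty <- derive_features(clean_pings(make_pings(-84, 27), world), world),
    "< 3 pings")
  expect_equal(nrow(empty), 0)
})

test_that("a speed-separable labelling is learned perfectly", {
  set.seed(42)
  n <- 300
  feats <- tibble::tibble(
    vessel_id = "V001",
    timestamp = as.POSIXct("2007-06-01", tz = "UTC") + 3600 * seq_len(3 * n),
    speed = c(runif(n, 0, 1.5), runif(n, 4, 6), runif(n, 0, 0.05)),
    turn_angle = runif(3 * n, 0, 180),
    depth = runif(3 * n, 10, 300),
    hour = runif(3 * n, 0, 24),
    port_km = c(runif(2 * n, 10, 200), runif(n, 0, 1.5)),
    speed_ma3 = 0)
  feats$speed_ma3 <- feats$speed
  labels <- tibble::tibble(vessel_id = feats$vessel_id, timestamp = feats$timestamp,
                           activity = rep(c("fishing", "transit", "port"), each = n))
  clf <- train_activity_classifier(feats, labels, seed = 1)
  expect_equal(clf$balanced_accuracy, 1.0)
  # classifying the training rows reproduces the labels
  pred <- classify_activity(clf, feats)
  expect_gt(mean(pred == labels$activity), 0.99)
  # determinism: identical rows, identical labels
  expect_identical(pred, classify_activity(clf, feats))
  # schema mismatch names the missing features
  expect_error(classify_activity(clf, feats[, -which(names(feats) == "depth")]),
               "depth")
})

test_that("uninformative labels score at binary chance level", {
  set.seed(9)
  n <- 900
  feats <- tibble::tibble(
    vessel_id = "V001",
    timestamp = as.POSIXct("2007-06-01", tz = "UTC") + 3600 * seq_len(n),
    speed = runif(n, 0, 6), turn_angle = runif(n, 0, 180),
    depth = runif(n, 10, 300), hour = runif(n, 0, 24),
    port_km = runif(n, 0, 200), speed_ma3 = runif(n, 0, 6))
  labels <- tibble::tibble(vessel_id = feats$vessel_id, timestamp = feats$timestamp,
                           activity = sample(c("fishing", "transit", "port"),
                                             n, replace = TRUE))
  clf <- train_activity_classifier(feats, labels, seed = 1)
  # with (TPR + TNR)/2 scoring, chance level is 0.5 regardless of class count
  expect_lt(abs(clf$balanced_accuracy - 0.5), 0.1)
})

test_that("balanced accuracy follows its definition and ignores class imbalance", {
  truth <- c(rep("fishing", 10), rep("transit", 10))
  perfect <- truth
  expect_equal(balanced_accuracy(truth, perfect), 1.0)
  expect_equal(balanced_accuracy(truth, rep("fishing", 20)), 0.5)
  # TPR 0.8, TNR 0.6 -> 0.7
  pred <- c(rep("fishing", 8), rep("transit", 2), rep("fishing", 4), rep("transit", 6))
  expect_equal(balanced_accuracy(truth, pred), 0.7)
  # duplicating negative examples leaves the score unchanged
  truth2 <- c(truth, rep("transit", 10)); pred2 <- c(pred, rep("fishing", 4), rep("transit", 6))
  expect_equal(balanced_accuracy(truth2, pred2), balanced_accuracy(truth, pred))
  expect_error(balanced_accuracy(rep("fishing", 5), rep("fishing", 5)), "undefined")
})

test_that("the synthetic fleet's predicted fishing fraction matches ground truth", {
  tk <- small_tracks()
  truth <- tk$sim$pings$activity_true[
    match(paste(tk$classified$vessel_id, tk$classified$timestamp),
          paste(tk$sim$pings$vessel_id, tk$sim$pings$timestamp))]
  frac_pred <- mean(tk$classified$activity == "fishing")
  frac_true <- mean(truth == "fishing")
  expect_lt(abs(frac_pred - frac_true) / frac_true, 0.10)
})
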