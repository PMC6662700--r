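# Shared fixtures: a small simulated fleet reused across test files, built
# once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

small_config <- function(seed = 7, ...) {
  args <- list(n_vessels = 15, undisturbed_days = 150, disturbed_days = 50,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(fleet_config, args)
}

# trips-only simulation bundle: fleet, logbook, disturbance
small_sim <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- small_config()
    world <- sim_world()
    fleet <- generate_fleet(cfg, world)
    und <- simulate_trips(fleet, world, cfg)
    dist <- simulate_disturbance(fleet, world, cfg, und)
    .fixtures$sim <- list(cfg = cfg, world = world, fleet = fleet,
                          und = und, dist = dist)
  }
  .fixtures$sim
}

# track-level bundle: pings through classification
small_tracks <- function() {
  if (is.null(.fixtures$tracks)) {
    cfg <- small_config()
    world <- sim_world()
    fleet <- generate_fleet(cfg, world)
    tr <- simulate_tracks(fleet, world, cfg)
    clean <- clean_pings(tr$pings, world)
    feats <- derive_features(clean, world)
    clf <- train_activity_classifier(feats, tr$labels, seed = 1)
    act <- classify_activity(clf, feats)
    classified <- dplyr::inner_join(
      clean, cbind(feats[, c("vessel_id", "timestamp")], activity = act),
      by = c("vessel_id", "timestamp"))
    .fixtures$tracks <- list(cfg = cfg, world = world, fleet = fleet, sim = tr,
                             clean = clean, feats = feats, clf = clf,
                             classified = classified)
  }
  .fixtures$tracks
}

# per-vessel entropy scores from a true (generator-level) visitation table
scores_from_visits <- function(visits, burn_in = 0.5) {
  vapply(split(visits, visits$vessel_id), function(v) {
    v <- v[order(v$start_hour), ]
    if (nrow(v) < 2) return(NA_real_)
    entropy_score(entropy_trajectory(v$cell), burn_in = burn_in)
  }, numeric(1))
}

# strategy profile built from generator ground truth (no track processing)
true_profiles <- function(fleet, und, dist) {
  s <- scores_from_visits(und$visits)
  prt <- tapply(und$visits$bout_hours, und$visits$vessel_id, mean)
  act <- tapply(und$trips$duration_days, und$trips$vessel_id, sum)
  ids <- names(s)
  tibble::tibble(
    vessel_id = ids,
    S = as.numeric(s),
    prt = as.numeric(prt[ids]),
    activity = as.numeric(act[ids]),
    length = fleet$length_m[match(ids, fleet$vessel_id)],
    displacement = dist$exit_flags$displacement_true[
      match(ids, dist$exit_flags$vessel_id)]
  )
}

# independent brute-force Shannon trajectory oracle (frequency counting on
# every prefix, no incremental bookkeeping)
brute_entropy_trajectory <- function(cells) {
  vapply(seq_along(cells), function(m) {
    f <- table(cells[seq_len(m)]) / m
    -sum(f * log2(f))
  }, numeric(1))
}
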