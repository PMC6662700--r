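# Synthetic fleet simulator: trip skeletons (logbook level), hourly track
# expansion (VMS level), and the closure disturbance.

# planar km distance, adequate at sub-basin scales for generator geometry
km_dist <- function(lon1, lat1, lon2, lat2) {
  kx <- 111.195 * cos(mean(c(lat1, lat2)) * pi / 180)
  sqrt(((lon2 - lon1) * kx)^2 + ((lat2 - lat1) * 111.195)^2)
}

TRANSIT_KMH <- 18   # ~5 m/s steaming speed
FISHING_FRACTION <- 0.65  # share of trip hours budgeted to fishing bouts

# Fleet-wide daily revenue signal: annual sinusoid plus AR(1) weather shocks.
# The closure opens on the late seasonal rise, about two weeks before the
# annual revenue peak (as in a late-spring closure ahead of the summer high
# season). At this phase the two small imperfections of the skewed-window
# fleet index -- its ~half-window lead on the signal slope and its residual
# attenuation of the signal level -- pull the business-as-usual
# counterfactual in opposite directions and offset, so fleet-mean deviance
# is centred under the null, as the design requires.
fleet_signal <- function(config) {
  n <- config$undisturbed_days + config$disturbed_days
  peak <- config$undisturbed_days + config$disturbed_days / 2 + 14
  phase <- peak - 365 / 4
  with_seed(vessel_seed(config$seed, 0L, stream = 9L), {
    shock <- stats::filter(stats::rnorm(n, 0, 300), 0.9, method = "recursive")
    2000 * sin(2 * pi * (seq_len(n) - phase) / 365) + as.numeric(shock)
  })
}

# Logbook-level trip skeleton for one period. Bout cells are drawn from the
# vessel's weights with no immediate within-trip repeat; bout durations are
# lognormal with mean prt_mean. Randomness comes from per-vessel sub-streams
# so the skeleton is identical whether or not tracks are expanded later.
build_trip_skeleton <- function(fleet, world, config,
                                period = c("undisturbed", "disturbed"),
                                portfolios = NULL) {
  period <- match.arg(period)
  n_days <- if (period == "undisturbed") config$undisturbed_days else config$disturbed_days
  day0 <- if (period == "undisturbed") 0L else config$undisturbed_days
  stream <- if (period == "undisturbed") 1L else 3L
  prefix <- if (period == "undisturbed") "U" else "D"
  dur_range <- config$trip_duration_range
  gap_mean <- if (period == "undisturbed") config$trip_gap_mean_days else
    (config$disturbed_trip_gap_mean_days %||% config$trip_gap_mean_days)
  sdlog <- 0.6

  trip_rows <- list(); visit_rows <- list()
  for (r in seq_len(nrow(fleet))) {
    v <- fleet[r, ]
    k <- as.integer(sub("^V", "", v$vessel_id))
    cells <- if (is.null(portfolios)) v$portfolio[[1]] else portfolios[[v$vessel_id]]$cells
    wts <- if (is.null(portfolios)) v$weights[[1]] else portfolios[[v$vessel_id]]$weights
    if (is.null(cells) || length(cells) == 0) next
    meanlog <- log(v$prt_mean) - sdlog^2 / 2
    with_seed(vessel_seed(config$seed, k, stream = stream), {
      # trip calendar: alternate exponential port gaps and 2-15 day trips
      n_max <- ceiling(n_days / (dur_range[1] / 2 + 0.5)) + 4L
      gaps <- 12 + stats::rexp(n_max, 1 / (gap_mean * 24))
      durs <- if (dur_range[1] == dur_range[2]) {
        rep(dur_range[1], n_max)
      } else {
        sample(seq.int(dur_range[1], dur_range[2]), n_max, replace = TRUE)
      }
      start_h <- ceiling(cumsum(gaps) + c(0, cumsum(durs * 24))[seq_len(n_max)])
      end_h <- start_h + durs * 24
      nt <- findInterval(n_days * 24, end_h)
      if (nt >= 1) {
        keep <- seq_len(nt)
        start_h <- start_h[keep]; end_h <- end_h[keep]; durs <- durs[keep]
        observer <- stats::runif(nt) < config$observer_fraction
        eps <- stats::rnorm(nt, 0, config$noise_sd)
        budgets <- durs * 24 * FISHING_FRACTION
        # batch bout draws per trip: lognormal durations cut at the budget,
        # cells sampled by weight with no immediate within-trip repeat
        bc_all <- integer(0); bh_all <- numeric(0); bt_all <- integer(0)
        for (j in seq_len(nt)) {
          need <- ceiling(budgets[j] / v$prt_mean) + 8L
          h <- stats::rlnorm(need, meanlog, sdlog)
          while (sum(h) < budgets[j]) h <- c(h, stats::rlnorm(need, meanlog, sdlog))
          nb <- which(cumsum(h) >= budgets[j])[1]
          h <- h[seq_len(nb)]
          h[nb] <- max(0.5, budgets[j] - sum(h[-nb]))
          if (length(cells) == 1) {
            cl <- rep(cells, nb)
          } else {
            cl <- cells[sample.int(length(cells), nb, replace = TRUE, prob = wts)]
            rep_i <- which(cl[-1] == cl[-nb]) + 1L
            while (length(rep_i)) {
              for (i in rep_i) {
                w <- wts * (cells != cl[i - 1L])
                cl[i] <- cells[sample.int(length(cells), 1, prob = w / sum(w))]
              }
              rep_i <- which(cl[-1] == cl[-nb]) + 1L
            }
          }
          bc_all <- c(bc_all, cl); bh_all <- c(bh_all, h)
          bt_all <- c(bt_all, rep(j, nb))
        }
        trip_ids <- sprintf("%s_%s%03d", v$vessel_id, prefix, seq_len(nt))
        trip_rows[[r]] <- tibble::tibble(
          vessel_id = v$vessel_id, trip_id = trip_ids,
          start_day = day0 + start_h / 24,
          landing_day = day0 + end_h / 24,
          duration_days = durs, observer = observer, eps = eps,
          period = period
        )
        seq_in_trip <- sequence(tabulate(bt_all))
        off <- unlist(lapply(base::split(bh_all, bt_all),
                             function(x) c(0, cumsum(x))[seq_along(x)]),
                      use.names = FALSE)
        visit_rows[[r]] <- tibble::tibble(
          vessel_id = v$vessel_id, trip_id = trip_ids[bt_all],
          seq = seq_in_trip, cell = as.integer(bc_all), bout_hours = bh_all,
          start_hour = day0 * 24 + start_h[bt_all] + off
        )
      }
    })
  }
  empty_trips <- tibble::tibble(vessel_id = character(), trip_id = character(),
                                start_day = numeric(), landing_day = numeric(),
                                duration_days = integer(), observer = logical(),
                                eps = numeric(), period = character())
  empty_visits <- tibble::tibble(vessel_id = character(), trip_id = character(),
                                 seq = integer(), cell = integer(),
                                 bout_hours = numeric(), start_hour = numeric())
  list(trips = if (length(trip_rows)) dplyr::bind_rows(trip_rows) else empty_trips,
       visits = if (length(visit_rows)) dplyr::bind_rows(visit_rows) else empty_visits)
}

# Revenue model: Ru_it = P_i + beta1 * D_it + beta2 * F_t + eps
attach_revenue <- function(trips, fleet, config, signal) {
  if (nrow(trips) == 0) {
    trips$revenue <- numeric(0); trips$landing_date <- as.Date(character(0))
    trips$length_m <- numeric(0)
    return(trips)
  }
  day_idx <- pmin(pmax(ceiling(trips$landing_day), 1L), length(signal))
  skill <- fleet$skill[match(trips$vessel_id, fleet$vessel_id)]
  trips$revenue <- pmax(0, skill + config$beta_duration * trips$duration_days +
                          config$beta_fleet * signal[day_idx] + trips$eps)
  trips$landing_date <- config$origin + floor(trips$landing_day)
  trips$length_m <- fleet$length_m[match(trips$vessel_id, fleet$vessel_id)]
  trips
}

#' Simulate a logbook (trips only, no position records)
#'
#' Fast path that generates the trip-level data the track simulator would
#' produce -- identical trip skeleton, revenues and true bout sequence -- but
#' skips hourly ping expansion. Used for parameter-recovery and power
#' simulations where only the logbook and the true visitation series matter.
#'
#' @param fleet a [generate_fleet()] result.
#' @param world a [sim_world()].
#' @param config the [fleet_config()] used to build the fleet.
#' @return list with `trips` (logbook tibble: revenue, duration, landing
#'   date, vessel length, observer flag), `visits` (true bout-level
#'   visitation series) and `signal` (daily fleet-wide revenue signal).
#' @export
simulate_trips <- function(fleet, world, config) {
  sk <- build_trip_skeleton(fleet, world, config, "undisturbed")
  sk$trips <- attach_revenue(sk$trips, fleet, config, fleet_signal(config))
  sk$signal <- fleet_signal(config)
  sk
}

# Expand one trip into hourly pings: transit legs at constant steaming speed,
# slow random-walk fishing bouts confined to the bout's cell, early return
# padded with port pings. Returns lon/lat/activity vectors of length dur_h.
expand_trip <- function(port, lattice, bouts, dur_h) {
  lon <- rep(port[1], dur_h); lat <- rep(port[2], dur_h)
  act <- rep("port", dur_h)
  cur <- port; used <- 0L
  for (b in seq_len(nrow(bouts))) {
    cell <- lattice[bouts$cell[b], ]
    target <- c(cell$lon + stats::runif(1, -0.5, 0.5) * cell$half_lon,
                cell$lat + stats::runif(1, -0.5, 0.5) * cell$half_lat)
    d <- km_dist(cur[1], cur[2], target[1], target[2])
    th <- max(1L, ceiling(d / TRANSIT_KMH))
    fh <- max(1L, round(bouts$bout_hours[b]))
    ret <- ceiling(km_dist(target[1], target[2], port[1], port[2]) / TRANSIT_KMH)
    if (used + th + fh + ret > dur_h) {
      if (b > 1) break
      fh <- max(1L, dur_h - used - th - ret)
      if (fh < 1 || used + th + fh + ret > dur_h) break
    }
    idx <- used + seq_len(th)
    frac <- seq_len(th) / th
    lon[idx] <- cur[1] + frac * (target[1] - cur[1])
    lat[idx] <- cur[2] + frac * (target[2] - cur[2])
    act[idx] <- "transit"
    used <- used + th
    # a fishing bout sits near its set location: slow jitter (< 2 m/s
    # derived speeds) around the anchor, kept inside the cell's bounds
    r_lon <- 0.5 / (111.195 * cos(cell$lat * pi / 180))
    r_lat <- 0.5 / 111.195
    flon <- target[1] + stats::runif(fh, -r_lon, r_lon)
    flat <- target[2] + stats::runif(fh, -r_lat, r_lat)
    flon <- reflect_into(flon, cell$lon - cell$half_lon, cell$lon + cell$half_lon)
    flat <- reflect_into(flat, cell$lat - cell$half_lat, cell$lat + cell$half_lat)
    idx <- used + seq_len(fh)
    lon[idx] <- flon; lat[idx] <- flat; act[idx] <- "fishing"
    used <- used + fh
    cur <- c(flon[fh], flat[fh])
  }
  d <- km_dist(cur[1], cur[2], port[1], port[2])
  if (d > 0) {
    th <- min(max(1L, ceiling(d / TRANSIT_KMH)), dur_h - used)
    if (th > 0) {
      idx <- used + seq_len(th)
      frac <- seq_len(th) / th
      lon[idx] <- cur[1] + frac * (port[1] - cur[1])
      lat[idx] <- cur[2] + frac * (port[2] - cur[2])
      act[idx] <- "transit"
      used <- used + th
    }
  }
  list(lon = lon, lat = lat, activity = act)
}

reflect_into <- function(x, lo, hi) {
  rng <- hi - lo
  y <- (x - lo) %% (2 * rng)
  lo + ifelse(y > rng, 2 * rng - y, y)
}

expand_tracks <- function(fleet, world, config, skeleton, period = "undisturbed") {
  n_days <- if (period == "undisturbed") config$undisturbed_days else config$disturbed_days
  day0 <- if (period == "undisturbed") 0L else config$undisturbed_days
  stream <- if (period == "undisturbed") 2L else 4L
  lattice <- world$lattice
  port <- unname(world$port)
  visits_by_trip <- base::split(skeleton$visits, skeleton$visits$trip_id)
  out <- list()
  for (r in seq_len(nrow(fleet))) {
    v <- fleet[r, ]
    k <- as.integer(sub("^V", "", v$vessel_id))
    vtrips <- skeleton$trips[skeleton$trips$vessel_id == v$vessel_id, ]
    n_h <- n_days * 24L
    with_seed(vessel_seed(config$seed, k, stream = stream), {
      lon <- port[1] + stats::runif(n_h, -5e-4, 5e-4)
      lat <- port[2] + stats::runif(n_h, -5e-4, 5e-4)
      act <- rep("port", n_h)
      tid <- rep(NA_character_, n_h)
      if (nrow(vtrips) > 0) {
        for (j in seq_len(nrow(vtrips))) {
          tr <- vtrips[j, ]
          bouts <- visits_by_trip[[tr$trip_id]]
          h0 <- round((tr$start_day - day0) * 24)
          dur_h <- tr$duration_days * 24L
          tk <- expand_trip(port, lattice, bouts, dur_h)
          idx <- h0 + seq_len(dur_h)
          keep <- idx >= 1 & idx <= n_h
          lon[idx[keep]] <- tk$lon[keep]; lat[idx[keep]] <- tk$lat[keep]
          act[idx[keep]] <- tk$activity[keep]
          tid[idx[keep]] <- tr$trip_id
        }
      }
      out[[r]] <- tibble::tibble(
        vessel_id = v$vessel_id,
        timestamp = as.POSIXct(config$origin, tz = "UTC") +
          (day0 * 24 + seq_len(n_h) - 1) * 3600 * config$ping_interval,
        lon = lon, lat = lat, activity_true = act, trip_id = tid
      )
    })
  }
  dplyr::bind_rows(out)
}

observer_labels <- function(pings, trips) {
  obs <- trips$trip_id[trips$observer]
  on_trip <- pings[!is.na(pings$trip_id) & pings$trip_id %in% obs, ]
  # dockside hours after each observer trip anchor the port class
  port_rows <- list()
  pt <- pings[is.na(pings$trip_id), ]
  for (tid in obs) {
    tr <- trips[trips$trip_id == tid, ]
    t_end <- as.POSIXct(tr$landing_date, tz = "UTC") + 86400
    sel <- pt$vessel_id == tr$vessel_id &
      pt$timestamp >= t_end - 86400 & pt$timestamp < t_end
    port_rows[[tid]] <- pt[sel, ]
  }
  lab <- dplyr::bind_rows(on_trip, dplyr::bind_rows(port_rows))
  tibble::tibble(vessel_id = lab$vessel_id, timestamp = lab$timestamp,
                 activity = lab$activity_true)
}

#' Simulate hourly vessel tracks for the undisturbed period
#'
#' Expands the logbook skeleton of [simulate_trips()] into hourly position
#' records: port pings at the dock, straight transit legs at steaming speed
#' (~5 m/s), and slow (< 2 m/s) random-walk fishing bouts confined to the
#' chosen candidate cell, mirroring the structure of vessel-monitoring data.
#' A configurable fraction of trips carries ground-truth activity labels,
#' standing in for on-board observer coverage.
#'
#' @inheritParams simulate_trips
#' @return list with `pings` (vessel_id, timestamp UTC, lon, lat, plus
#'   ground-truth `activity_true` and `trip_id`), `trips`, `labels`
#'   (observer-labelled subset), `visits` and `signal`.
#' @export
simulate_tracks <- function(fleet, world, config) {
  sk <- simulate_trips(fleet, world, config)
  pings <- expand_tracks(fleet, world, config, sk, "undisturbed")
  labels <- observer_labels(pings, sk$trips)
  list(pings = pings, trips = sk$trips, labels = labels,
       visits = sk$visits, signal = sk$signal)
}

# Closure polygon: bounding rectangle of the most-used candidate cells,
# ranked by fleet-wide fishing hours until `closure_fraction` of total effort
# is covered. Returned as a closed lon/lat ring.
derive_closure <- function(undisturbed_visits, world, config) {
  use <- stats::aggregate(bout_hours ~ cell, data = undisturbed_visits, sum)
  use <- use[order(-use$bout_hours), ]
  cum <- cumsum(use$bout_hours) / sum(use$bout_hours)
  n_top <- which(cum >= config$closure_fraction)[1]
  if (is.na(n_top) || n_top < 1) stop("closure covers zero cells", call. = FALSE)
  top <- world$lattice[world$lattice$cell %in% use$cell[seq_len(n_top)], ]
  lo_lon <- min(top$lon - top$half_lon); hi_lon <- max(top$lon + top$half_lon)
  lo_lat <- min(top$lat - top$half_lat); hi_lat <- max(top$lat + top$half_lat)
  ring <- cbind(lon = c(lo_lon, hi_lon, hi_lon, lo_lon, lo_lon),
                lat = c(lo_lat, lo_lat, hi_lat, hi_lat, lo_lat))
  list(ring = ring, cells = top$cell)
}

point_in_ring <- function(lon, lat, ring) {
  if (length(lon) == 0) return(logical(0))
  mgcv::in.out(ring, cbind(lon, lat))
}

#' Simulate the spatial-closure disturbance
#'
#' Closes the fleet's most-used fishing cells, lets each vessel exit the
#' fishery with probability `plogis(exit_baseline - exit_entropy_coef * S)`
#' (S the standardized true choice entropy, so broad explorers are more
#' likely to keep fishing), restricts survivors to grounds outside the
#' closure, and perturbs business-as-usual revenues by a deviance
#' `delta = (a * S - b * displacement) * 2^(-days_since_closure / halflife)`
#' plus noise, so entropy buffers and displacement depresses performance and
#' both effects decay.
#'
#' @inheritParams simulate_trips
#' @param undisturbed the result of [simulate_trips()] or [simulate_tracks()]
#'   for the same fleet/config (supplies the pre-closure visitation record).
#' @param tracks if `TRUE`, also expand hourly pings and observer labels for
#'   the disturbed period.
#' @return list with `trips` (including `days_since_closure` and the applied
#'   `delta`), `visits`, `exit_flags` (per vessel: exited, exit probability,
#'   true entropy and true displacement), `closure` (ring + closed cells),
#'   and optionally `pings`/`labels`.
#' @export
simulate_disturbance <- function(fleet, world, config, undisturbed,
                                 tracks = FALSE) {
  closure <- derive_closure(undisturbed$visits, world, config)
  lat_c <- world$lattice
  inside <- lat_c$cell[point_in_ring(lat_c$lon, lat_c$lat, closure$ring)]

  fished <- split(undisturbed$visits$cell, undisturbed$visits$vessel_id)
  disp_true <- vapply(fleet$vessel_id, function(v) {
    cells <- unique(fished[[v]])
    if (is.null(cells) || length(cells) == 0) return(0)
    mean(cells %in% inside)
  }, numeric(1))

  s_std <- as.numeric(scale(fleet$entropy_true))
  if (anyNA(s_std)) s_std <- rep(0, nrow(fleet))
  d_std <- as.numeric(scale(disp_true))
  if (anyNA(d_std)) d_std <- rep(0, nrow(fleet))
  p_exit <- stats::plogis(config$exit_baseline - config$exit_entropy_coef * s_std)
  exited <- vapply(seq_len(nrow(fleet)), function(r) {
    k <- as.integer(sub("^V", "", fleet$vessel_id[r]))
    with_seed(vessel_seed(config$seed, k, stream = 5L), stats::runif(1) < p_exit[r])
  }, logical(1))

  exit_flags <- tibble::tibble(vessel_id = fleet$vessel_id, exited = exited,
                               p_exit = p_exit, entropy_true = fleet$entropy_true,
                               displacement_true = disp_true)

  # Survivors relinquish closed cells and redistribute: each closed portfolio
  # cell is replaced by the nearest open cell not already held, inheriting its
  # choice weight, so portfolio breadth carries over while grounds shift.
  survivors <- fleet[!exited, ]
  open <- lat_c[!(lat_c$cell %in% inside), ]
  if (nrow(open) == 0) stop("closure covers the entire candidate lattice", call. = FALSE)
  portfolios <- list()
  for (r in seq_len(nrow(survivors))) {
    v <- survivors[r, ]
    cells <- v$portfolio[[1]]
    wts <- v$weights[[1]]
    closed <- cells %in% inside
    for (j in which(closed)) {
      old <- lat_c[cells[j], ]
      avail <- open[!(open$cell %in% cells), ]
      if (nrow(avail) == 0) next
      d <- km_dist(avail$lon, avail$lat, old$lon, old$lat)
      cells[j] <- avail$cell[which.min(d)]
    }
    still_closed <- cells %in% inside
    if (any(still_closed)) {
      wts <- wts[!still_closed] / sum(wts[!still_closed])
      cells <- cells[!still_closed]
    }
    portfolios[[v$vessel_id]] <- list(cells = cells, weights = wts)
  }

  sk <- build_trip_skeleton(survivors, world, config, "disturbed", portfolios)
  signal <- fleet_signal(config)
  sk$trips <- attach_revenue(sk$trips, fleet, config, signal)
  if (nrow(sk$trips) > 0) {
    sk$trips$days_since_closure <- sk$trips$landing_day - config$undisturbed_days
    decay <- 2^(-sk$trips$days_since_closure / config$deviance_decay_halflife)
    i <- match(sk$trips$vessel_id, fleet$vessel_id)
    delta_det <- (config$deviance_entropy_coef * s_std[i] -
                    config$deviance_displacement_coef * d_std[i]) * decay
    noise <- numeric(nrow(sk$trips))
    for (rows in split(seq_len(nrow(sk$trips)), sk$trips$vessel_id)) {
      k <- as.integer(sub("^V", "", sk$trips$vessel_id[rows[1]]))
      noise[rows] <- with_seed(vessel_seed(config$seed, k, stream = 6L),
                               stats::rnorm(length(rows), 0, config$deviance_noise_sd))
    }
    sk$trips$delta <- delta_det + noise
    # delta scales the vessel-performance component of revenue, so the
    # business-as-usual deviance of a trip equals delta by construction
    # (duration and fleet terms are controlled away by the counterfactual)
    skill_i <- fleet$skill[match(sk$trips$vessel_id, fleet$vessel_id)]
    sk$trips$revenue <- pmax(0, sk$trips$revenue + skill_i * sk$trips$delta)
  } else {
    sk$trips$days_since_closure <- numeric(0)
    sk$trips$delta <- numeric(0)
  }

  out <- list(trips = sk$trips, visits = sk$visits, exit_flags = exit_flags,
              closure = closure)
  if (tracks) {
    out$pings <- expand_tracks(survivors, world, config, sk, "disturbed")
    out$labels <- observer_labels(out$pings, sk$trips)
  }
  out
}
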