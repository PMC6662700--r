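#' Fleet simulation configuration
#'
#' Bundles every tunable of the synthetic-fleet generator into a validated
#' list. The defaults describe a bottom-longline-style fleet of 100 vessels
#' pinging hourly over one undisturbed year followed by a 60-day spatial
#' closure, with heterogeneous explore-exploit strategies: portfolio sizes
#' and Dirichlet choice concentrations span narrow, skewed choosers to broad,
#' even samplers.
#'
#' @param n_vessels number of vessels in the fleet (>= 2).
#' @param undisturbed_days length of the pre-closure period, days.
#' @param disturbed_days length of the closure period, days.
#' @param ping_interval position-report interval, hours.
#' @param portfolio_size_range integer pair: number of fishing cells per
#'   vessel, sampled uniformly.
#' @param choice_concentration_range positive pair: symmetric-Dirichlet
#'   concentration of cell-choice weights, sampled log-uniformly. Low values
#'   give skewed, low-entropy choosers.
#' @param prt_mean_range pair, hours: per-vessel mean fishing-bout duration.
#' @param vessel_length_range pair, metres.
#' @param base_revenue fleet-mean trip revenue at zero duration/fleet effect,
#'   revenue units.
#' @param skill_sd between-vessel SD of true mean performance P_i.
#' @param beta_duration revenue units per day of trip duration.
#' @param beta_fleet dimensionless multiplier on the fleet-wide seasonal
#'   revenue signal.
#' @param noise_sd trip-level revenue noise SD.
#' @param exit_baseline baseline logit of leaving the fishery at closure.
#' @param exit_entropy_coef logit units per SD of true choice entropy;
#'   positive values make broad explorers more likely to keep fishing.
#' @param deviance_entropy_coef,deviance_displacement_coef effect of
#'   standardized entropy (+) and displacement (-) on proportional revenue
#'   deviance at closure onset.
#' @param deviance_decay_halflife days for the deviance effects to halve.
#' @param deviance_noise_sd SD of trip-level proportional deviance noise.
#' @param observer_fraction fraction of trips carrying observer activity
#'   labels.
#' @param closure_fraction fraction of fleet-wide fishing effort whose
#'   top-ranked cells seed the closure polygon.
#' @param trip_gap_mean_days mean of the exponential port stay between trips.
#' @param trip_duration_range integer pair, days, of trip lengths.
#' @param disturbed_trip_gap_mean_days mean port stay between post-closure
#'   trips, days; shorter than the undisturbed gap, reflecting the urgency of
#'   re-establishing grounds while the closure bites.
#' @param origin calendar date of day 0 of the simulation.
#' @param seed integer master seed; all randomness flows from it through
#'   per-vessel sub-streams.
#'
#' @return an object of class `fleet_config` (a named list).
#' @export
fleet_config <- function(n_vessels = 100,
                         undisturbed_days = 365,
                         disturbed_days = 60,
                         ping_interval = 1,
                         portfolio_size_range = c(3L, 25L),
                         choice_concentration_range = c(0.25, 4),
                         prt_mean_range = c(4, 16),
                         vessel_length_range = c(15, 30),
                         base_revenue = 10000,
                         skill_sd = 1500,
                         beta_duration = 250,
                         beta_fleet = 1,
                         noise_sd = 200,
                         exit_baseline = 0,
                         exit_entropy_coef = 1.5,
                         deviance_entropy_coef = 0.8,
                         deviance_displacement_coef = 0.5,
                         deviance_decay_halflife = 14,
                         deviance_noise_sd = 0.03,
                         observer_fraction = 0.2,
                         closure_fraction = 0.35,
                         trip_gap_mean_days = 4,
                         trip_duration_range = c(2L, 15L),
                         disturbed_trip_gap_mean_days = 1.5,
                         origin = as.Date("2007-05-19"),
                         seed = 1L) {
  cfg <- list(
    n_vessels = as.integer(n_vessels),
    undisturbed_days = as.integer(undisturbed_days),
    disturbed_days = as.integer(disturbed_days),
    ping_interval = ping_interval,
    portfolio_size_range = as.integer(portfolio_size_range),
    choice_concentration_range = as.numeric(choice_concentration_range),
    prt_mean_range = as.numeric(prt_mean_range),
    vessel_length_range = as.numeric(vessel_length_range),
    base_revenue = base_revenue,
    skill_sd = skill_sd,
    beta_duration = beta_duration,
    beta_fleet = beta_fleet,
    noise_sd = noise_sd,
    exit_baseline = exit_baseline,
    exit_entropy_coef = exit_entropy_coef,
    deviance_entropy_coef = deviance_entropy_coef,
    deviance_displacement_coef = deviance_displacement_coef,
    deviance_decay_halflife = deviance_decay_halflife,
    deviance_noise_sd = deviance_noise_sd,
    observer_fraction = observer_fraction,
    closure_fraction = closure_fraction,
    trip_gap_mean_days = trip_gap_mean_days,
    trip_duration_range = as.integer(trip_duration_range),
    disturbed_trip_gap_mean_days = disturbed_trip_gap_mean_days,
    origin = as.Date(origin),
    seed = as.integer(seed)
  )
  validate_fleet_config(cfg)
  structure(cfg, class = "fleet_config")
}

validate_fleet_config <- function(cfg) {
  ranges <- c("portfolio_size_range", "choice_concentration_range",
              "prt_mean_range", "vessel_length_range", "trip_duration_range")
  for (r in ranges) {
    v <- cfg[[r]]
    if (length(v) != 2 || anyNA(v) || v[1] > v[2]) {
      stop("invalid configuration: ", r, " must be an ordered pair", call. = FALSE)
    }
  }
  if (cfg$n_vessels < 2) stop("invalid configuration: n_vessels must be >= 2", call. = FALSE)
  if (cfg$ping_interval <= 0) stop("invalid configuration: ping_interval must be > 0", call. = FALSE)
  if (any(cfg$choice_concentration_range <= 0)) {
    stop("invalid configuration: choice_concentration_range must be positive", call. = FALSE)
  }
  if (cfg$portfolio_size_range[1] < 1) {
    stop("invalid configuration: portfolio sizes must be >= 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Synthetic study region
#'
#' Builds the simulation world: a lon/lat extent on the continental shelf, a
#' single port, a deterministic bathymetry surface that deepens offshore with
#' smooth ridges, and the lattice of candidate fishing cells vessels choose
#' among. The bathymetry is a synthetic stand-in for a real depth raster; it
#' exists so the depth covariate and the depth-confound diagnostic can be
#' exercised without external data.
#'
#' @param lon_range,lat_range extent, decimal degrees (WGS84).
#' @param port lon/lat of the single home port.
#' @param lattice_dim number of candidate-cell columns and rows.
#' @return an object of class `sim_world`: extent, port, `depth(lon, lat)`
#'   function (metres below sea level, >= 0 on the extent) and the candidate
#'   cell lattice (`$lattice`, a tibble of cell centres and half-widths).
#' @export
sim_world <- function(lon_range = c(-86.6, -82.5),
                      lat_range = c(25.1, 28.9),
                      port = c(-82.75, 27.9),
                      lattice_dim = c(18L, 16L)) {
  stopifnot(length(lon_range) == 2, length(lat_range) == 2,
            diff(lon_range) > 0, diff(lat_range) > 0, length(port) == 2)
  # depth increases towards the south-west (offshore), with gentle ridges
  depth <- function(lon, lat) {
    x <- (lon_range[2] - lon) / diff(lon_range)
    y <- (lat_range[2] - lat) / diff(lat_range)
    d <- 12 + 260 * x + 90 * y + 35 * sin(3 * pi * x) * cos(2 * pi * y)
    pmax(d, 0)
  }
  # candidate fishing cells sit offshore of the port, inset from the extent
  fx <- lon_range + c(0.15, -0.55) * diff(lon_range) / 4
  fy <- lat_range + c(0.35, -0.35) * diff(lat_range) / 4
  nc <- as.integer(lattice_dim[1]); nr <- as.integer(lattice_dim[2])
  dlon <- diff(fx) / nc; dlat <- diff(fy) / nr
  centres <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  lattice <- tibble::tibble(
    cell = seq_len(nrow(centres)),
    lon = fx[1] + (centres$col - 0.5) * dlon,
    lat = fy[1] + (centres$row - 0.5) * dlat,
    half_lon = dlon / 2,
    half_lat = dlat / 2
  )
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 port = c(lon = port[1], lat = port[2]),
                 depth = depth, lattice = lattice),
            class = "sim_world")
}

# deterministic per-vessel sub-stream seed; `stream` separates skeleton,
# ping and disturbance randomness so logbook-only runs match track runs
vessel_seed <- function(seed, k, stream = 0L) {
  as.integer((abs(as.numeric(seed)) %% 1e6) * 1009 + k * 7919 + stream * 104729) %% 2147483629L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
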