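# Position-record cleaning and movement-feature derivation.

#' Clean raw position records
#'
#' Applies the standard vessel-monitoring cleaning sequence: drop pings
#' outside the study extent, resolve duplicate (vessel, timestamp) records by
#' keeping the first, sort non-monotone timestamps, derive per-vessel speeds
#' from successive rhumb-line distances over elapsed time, and iteratively
#' delete pings whose arrival speed exceeds `speed_threshold` (recomputing
#' successor speeds after each deletion, until none remain). Optionally
#' attaches depth from a deterministic bathymetry surface.
#'
#' @param pings tibble with vessel_id, timestamp (POSIXct UTC), lon, lat.
#' @param world a [sim_world()] supplying the extent and depth surface, or
#'   `NULL` to skip the extent filter and depth.
#' @param speed_threshold maximum credible speed, m/s; faster arrivals are
#'   treated as positioning errors.
#' @return cleaned tibble with `speed` (m/s; NA for each vessel's first ping)
#'   and, when a world is given, `depth` (m). Filter counts are attached as
#'   the `"log"` attribute.
#' @export
clean_pings <- function(pings, world = NULL, speed_threshold = 20) {
  req <- c("vessel_id", "timestamp", "lon", "lat")
  miss <- setdiff(req, names(pings))
  if (length(miss)) stop("pings missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  log <- list(n_in = nrow(pings), n_extent = 0L, n_dupes = 0L,
              n_speed = 0L, resorted = FALSE)

  if (!is.null(world)) {
    keep <- pings$lon >= world$lon_range[1] & pings$lon <= world$lon_range[2] &
      pings$lat >= world$lat_range[1] & pings$lat <= world$lat_range[2]
    log$n_extent <- sum(!keep)
    pings <- pings[keep, ]
  }
  ord <- order(pings$vessel_id, pings$timestamp)
  if (is.unsorted(ord)) log$resorted <- TRUE
  pings <- pings[ord, ]
  dup <- duplicated(pings[, c("vessel_id", "timestamp")])
  log$n_dupes <- sum(dup)
  pings <- pings[!dup, ]

  out <- lapply(split(pings, pings$vessel_id), function(p) {
    repeat {
      n <- nrow(p)
      if (n < 2) { p$speed <- rep(NA_real_, n); break }
      dt <- as.numeric(difftime(p$timestamp[-1], p$timestamp[-n], units = "secs"))
      d <- rhumb_distance(p$lon[-n], p$lat[-n], p$lon[-1], p$lat[-1])
      sp <- c(NA_real_, d / dt)
      bad <- which(!is.na(sp) & sp > speed_threshold)
      if (length(bad) == 0) { p$speed <- sp; break }
      log$n_speed <<- log$n_speed + length(bad)
      p <- p[-bad, ]
    }
    p
  })
  out <- dplyr::bind_rows(out)
  if (!is.null(world) && nrow(out) > 0) out$depth <- world$depth(out$lon, out$lat)
  attr(out, "log") <- log
  out
}

#' Derive movement features for activity classification
#'
#' One row per interior ping (a ping with both a predecessor and a successor
#' from the same vessel): arrival speed, turning angle (absolute change in
#' rhumb bearing, degrees in \[0, 180\]), depth, hour of day (UTC),
#' displacement from port (km) and a centred 3-ping moving average of speed.
#'
#' @param pings cleaned pings from [clean_pings()] (must carry `speed`; and
#'   `depth` unless `world` is supplied).
#' @param world a [sim_world()]; supplies the port (and depth if missing).
#' @return tibble keyed by (vessel_id, timestamp) with columns `speed`,
#'   `turn_angle`, `depth`, `hour`, `port_km`, `speed_ma3`. Vessels with
#'   fewer than 3 pings yield no rows, with a warning.
#' @export
derive_features <- function(pings, world) {
  if (!"speed" %in% names(pings)) stop("run clean_pings() first (no speed column)", call. = FALSE)
  if (!"depth" %in% names(pings)) pings$depth <- world$depth(pings$lon, pings$lat)
  short <- FALSE
  out <- lapply(split(pings, pings$vessel_id), function(p) {
    n <- nrow(p)
    if (n < 3) { short <<- TRUE; return(NULL) }
    b <- rhumb_bearing(p$lon[-n], p$lat[-n], p$lon[-1], p$lat[-1])  # n-1 bearings
    dturn <- abs(((b[-1] - b[-(n - 1)] + 180) %% 360) - 180)
    dturn[is.na(dturn)] <- 0  # stationary segment: no defined turn
    i <- 2:(n - 1)
    sp <- p$speed
    sp[is.na(sp)] <- 0
    ma3 <- (sp[i - 1] + sp[i] + sp[i + 1]) / 3
    tibble::tibble(
      vessel_id = p$vessel_id[i], timestamp = p$timestamp[i],
      speed = p$speed[i],
      turn_angle = dturn,
      depth = p$depth[i],
      hour = as.numeric(format(p$timestamp[i], "%H", tz = "UTC")) +
        as.numeric(format(p$timestamp[i], "%M", tz = "UTC")) / 60,
      port_km = rhumb_distance(p$lon[i], p$lat[i],
                               world$port[1], world$port[2]) / 1000,
      speed_ma3 = ma3
    )
  })
  if (short) warning("vessels with < 3 pings contribute no feature rows")
  dplyr::bind_rows(out)
}
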