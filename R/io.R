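# Plain-text dataset interchange: pings/trips/labels as CSV, the closure
# polygon as GeoJSON, the configuration as YAML.

iso8601 <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write a simulated dataset to disk
#'
#' Serializes simulator outputs in the formats a real analysis would ingest:
#' `pings.csv` (vessel_id, ISO-8601 UTC timestamp, lon, lat), `trips.csv`,
#' `labels.csv`, `closure.geojson` (single WGS84 polygon) and `config.yaml`.
#' Files round-trip losslessly through [read_dataset()].
#'
#' @param sim list with any of `pings`, `trips`, `labels`, `closure`;
#'   typically [simulate_tracks()] output merged with
#'   [simulate_disturbance()] output.
#' @param dir output directory, created if needed.
#' @param config optional [fleet_config()] echoed to `config.yaml`.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir, config = NULL) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  paths <- character(0)
  if (!is.null(sim$pings)) {
    p <- sim$pings
    out <- tibble::tibble(vessel_id = p$vessel_id, timestamp = iso8601(p$timestamp),
                          lon = p$lon, lat = p$lat)
    readr::write_csv(out, file.path(dir, "pings.csv"))
    paths <- c(paths, file.path(dir, "pings.csv"))
  }
  if (!is.null(sim$trips)) {
    t <- sim$trips
    out <- tibble::tibble(vessel_id = t$vessel_id, trip_id = t$trip_id,
                          landing_date = t$landing_date,
                          duration_days = t$duration_days,
                          revenue = t$revenue, length_m = t$length_m)
    readr::write_csv(out, file.path(dir, "trips.csv"))
    paths <- c(paths, file.path(dir, "trips.csv"))
  }
  if (!is.null(sim$labels)) {
    l <- sim$labels
    out <- tibble::tibble(vessel_id = l$vessel_id, timestamp = iso8601(l$timestamp),
                          activity = l$activity)
    readr::write_csv(out, file.path(dir, "labels.csv"))
    paths <- c(paths, file.path(dir, "labels.csv"))
  }
  if (!is.null(sim$closure)) {
    ring <- sim$closure$ring
    gj <- list(type = "Feature", properties = stats::setNames(list(), character(0)),
               geometry = list(type = "Polygon",
                               coordinates = list(lapply(seq_len(nrow(ring)),
                                                         function(i) unname(ring[i, ])))))
    jsonlite::write_json(gj, file.path(dir, "closure.geojson"),
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, file.path(dir, "closure.geojson"))
  }
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$origin <- as.character(cfg$origin)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
    paths <- c(paths, file.path(dir, "config.yaml"))
  }
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the files.
#' @return list with whichever of `pings`, `trips`, `labels`, `closure`,
#'   `config` are present.
#' @export
read_dataset <- function(dir) {
  out <- list()
  f <- file.path(dir, "pings.csv")
  if (file.exists(f)) {
    p <- readr::read_csv(f, show_col_types = FALSE,
                         col_types = readr::cols(vessel_id = "c", timestamp = "c",
                                                 lon = "d", lat = "d"))
    p$timestamp <- as.POSIXct(p$timestamp, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
    out$pings <- p
  }
  f <- file.path(dir, "trips.csv")
  if (file.exists(f)) {
    out$trips <- readr::read_csv(f, show_col_types = FALSE,
                                 col_types = readr::cols(vessel_id = "c", trip_id = "c",
                                                         landing_date = readr::col_date(),
                                                         duration_days = "i",
                                                         revenue = "d", length_m = "d"))
  }
  f <- file.path(dir, "labels.csv")
  if (file.exists(f)) {
    l <- readr::read_csv(f, show_col_types = FALSE,
                         col_types = readr::cols(vessel_id = "c", timestamp = "c",
                                                 activity = "c"))
    l$timestamp <- as.POSIXct(l$timestamp, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
    out$labels <- l
  }
  f <- file.path(dir, "closure.geojson")
  if (file.exists(f)) {
    gj <- jsonlite::read_json(f)
    coords <- gj$geometry$coordinates[[1]]
    ring <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    colnames(ring) <- c("lon", "lat")
    out$closure <- list(ring = ring)
  }
  f <- file.path(dir, "config.yaml")
  if (file.exists(f)) out$config <- yaml::read_yaml(f)
  out
}
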