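# Discretization of fishing activity into grid cells, vessel portfolios and
# chronological visitation series.

#' Build the analysis grid over fleet fishing activity
#'
#' The grid extent is the bounding box of all fleet fishing pings; `n` by `n`
#' cells tile it exactly. Cells are half-open `[low, high)` in both axes,
#' with the maximal row and column closed above so boundary points remain
#' assignable. Cell indices are 0-based `(col, row)` pairs.
#'
#' @param fishing_pings tibble of fishing-classified pings (lon, lat).
#' @param n cells per side (default 30, i.e. 900 cells).
#' @return a `grid_spec`: extent, cell counts and cell sizes.
#' @export
build_grid <- function(fishing_pings, n = 30) {
  stopifnot(nrow(fishing_pings) > 0)
  lon_range <- range(fishing_pings$lon)
  lat_range <- range(fishing_pings$lat)
  if (diff(lon_range) <= 0 || diff(lat_range) <= 0) {
    stop("degenerate extent: fishing pings span zero width", call. = FALSE)
  }
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 n_cols = as.integer(n), n_rows = as.integer(n),
                 dlon = diff(lon_range) / n, dlat = diff(lat_range) / n),
            class = "grid_spec")
}

#' Assign pings to grid cells
#'
#' @param grid a [build_grid()] result.
#' @param lon,lat coordinates inside the grid extent (cleaning should have
#'   removed anything else; out-of-extent points are an error).
#' @return tibble with 0-based `cell_col`, `cell_row` and a `cell` id string.
#' @export
assign_cells <- function(grid, lon, lat) {
  if (any(lon < grid$lon_range[1] | lon > grid$lon_range[2] |
            lat < grid$lat_range[1] | lat > grid$lat_range[2])) {
    stop("ping outside grid extent", call. = FALSE)
  }
  col <- pmin(floor((lon - grid$lon_range[1]) / grid$dlon), grid$n_cols - 1L)
  row <- pmin(floor((lat - grid$lat_range[1]) / grid$dlat), grid$n_rows - 1L)
  tibble::tibble(cell_col = as.integer(col), cell_row = as.integer(row),
                 cell = paste(col, row, sep = ":"))
}

#' Centre coordinates of grid cells
#'
#' @param grid a `grid_spec`.
#' @param cell_col,cell_row 0-based cell indices.
#' @return two-column matrix of lon/lat centres.
#' @export
cell_centers <- function(grid, cell_col, cell_row) {
  cbind(lon = grid$lon_range[1] + (cell_col + 0.5) * grid$dlon,
        lat = grid$lat_range[1] + (cell_row + 0.5) * grid$dlat)
}

#' Build chronological visitation series
#'
#' Converts classified pings into one element per visit bout: consecutive
#' fishing pings in the same cell collapse into a single bout, and a new
#' element starts when the fished cell changes or after any port visit (so a
#' port return followed by the same cell appends a repeated element). Bout
#' duration is (last - first ping timestamp) plus one ping interval, so
#' single-ping bouts have nonzero duration.
#'
#' @param classified_pings tibble with vessel_id, timestamp, lon, lat and an
#'   `activity` column (fishing/transit/port).
#' @param grid a [build_grid()] result.
#' @param ping_interval nominal ping spacing, hours.
#' @param per_ping if `TRUE`, emit one element per fishing ping instead of
#'   one per bout (sensitivity mode).
#' @return tibble: vessel_id, seq, cell, cell_col, cell_row, bout_start,
#'   bout_end, n_pings, bout_hours. Vessels with no fishing pings yield no
#'   rows, with a warning.
#' @export
build_visitation_series <- function(classified_pings, grid, ping_interval = 1,
                                    per_ping = FALSE) {
  stopifnot("activity" %in% names(classified_pings))
  p <- classified_pings[order(classified_pings$vessel_id, classified_pings$timestamp), ]
  none <- FALSE
  out <- lapply(split(p, p$vessel_id), function(v) {
    ev <- v[v$activity %in% c("fishing", "port"), ]
    fish <- ev$activity == "fishing"
    if (!any(fish)) { none <<- TRUE; return(NULL) }
    epoch <- cumsum(ev$activity == "port")
    f <- ev[fish, ]
    cells <- assign_cells(grid, f$lon, f$lat)
    key_cell <- cells$cell
    key_epoch <- epoch[fish]
    if (per_ping) {
      grp <- seq_along(key_cell)
    } else {
      new_bout <- c(TRUE, key_cell[-1] != key_cell[-length(key_cell)] |
                      key_epoch[-1] != key_epoch[-length(key_epoch)])
      grp <- cumsum(new_bout)
    }
    idx <- base::split(seq_len(nrow(f)), grp)
    tibble::tibble(
      vessel_id = f$vessel_id[1],
      seq = seq_along(idx),
      cell = vapply(idx, function(i) key_cell[i[1]], character(1), USE.NAMES = FALSE),
      cell_col = vapply(idx, function(i) cells$cell_col[i[1]], integer(1), USE.NAMES = FALSE),
      cell_row = vapply(idx, function(i) cells$cell_row[i[1]], integer(1), USE.NAMES = FALSE),
      bout_start = f$timestamp[vapply(idx, min, integer(1), USE.NAMES = FALSE)],
      bout_end = f$timestamp[vapply(idx, max, integer(1), USE.NAMES = FALSE)],
      n_pings = unname(lengths(idx))
    )
  })
  if (none) warning("vessels with zero fishing pings yield empty series")
  out <- dplyr::bind_rows(out)
  if (nrow(out) > 0) {
    out$bout_hours <- as.numeric(difftime(out$bout_end, out$bout_start,
                                          units = "hours")) + ping_interval
  } else {
    out$bout_hours <- numeric(0)
  }
  out
}

#' Per-vessel portfolio of fished cells
#'
#' @param visitation a [build_visitation_series()] result.
#' @return tibble: vessel_id, cell, cell_col, cell_row, n_pings (total
#'   fishing pings in that cell).
#' @export
build_portfolio <- function(visitation) {
  dplyr::summarise(
    dplyr::group_by(visitation, .data$vessel_id, .data$cell,
                    .data$cell_col, .data$cell_row),
    n_pings = sum(.data$n_pings), .groups = "drop"
  )
}
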