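# Strategy metrics: patch residence time, displacement, activity, and the
# assembled per-vessel strategy profile.

#' Patch residence time
#'
#' Arithmetic mean of a vessel's fishing-bout durations: the average time it
#' remains within one fishing cell before moving to another cell or
#' returning to port. Lower values indicate faster exploration.
#'
#' @param visitation bout rows for one vessel ([build_visitation_series()]).
#' @return hours; `NA` with a warning when the series is empty (vessel
#'   excluded).
#' @export
patch_residence_time <- function(visitation) {
  if (nrow(visitation) == 0) {
    warning("empty visitation series; patch residence time undefined")
    return(NA_real_)
  }
  mean(visitation$bout_hours)
}

#' Displacement: proportion of fished locations lost to a closure
#'
#' The fraction of a vessel's pre-disturbance fished cell centres that fall
#' inside the closure polygon. A vessel scoring 0.8 lost 80% of its
#' pre-disturbance fishing locations.
#'
#' @param centers two-column matrix or data frame of lon/lat cell centres
#'   (the vessel's pre-disturbance portfolio).
#' @param ring closure polygon as a two-column lon/lat vertex matrix
#'   (closed or open ring).
#' @return proportion in \[0, 1\].
#' @export
displacement_score <- function(centers, ring) {
  centers <- as.matrix(centers)
  if (nrow(centers) == 0) stop("empty portfolio: displacement undefined", call. = FALSE)
  mean(mgcv::in.out(as.matrix(ring), centers))
}

#' Baseline activity: fishing days within a lagged window
#'
#' Sums trip durations (days) for trips landing inside the lag window, per
#' vessel. The lag guards against endogeneity with contemporaneous
#' performance.
#'
#' @param trips logbook tibble (vessel_id, landing_date, duration_days).
#' @param window Date pair `[start, end]` (inclusive).
#' @param vessels vessels to report; those with no trips in the window get 0
#'   with a warning.
#' @return tibble (vessel_id, activity).
#' @export
activity_days <- function(trips, window, vessels = unique(trips$vessel_id)) {
  inw <- trips$landing_date >= window[1] & trips$landing_date <= window[2]
  agg <- dplyr::summarise(dplyr::group_by(trips[inw, ], .data$vessel_id),
                          activity = sum(.data$duration_days), .groups = "drop")
  out <- tibble::tibble(vessel_id = vessels)
  out <- dplyr::left_join(out, agg, by = "vessel_id")
  if (anyNA(out$activity)) {
    warning(sum(is.na(out$activity)), " vessel(s) absent from activity window; set to 0")
    out$activity[is.na(out$activity)] <- 0
  }
  out
}

#' Assemble per-vessel strategy profiles
#'
#' Computes the choice-entropy score, patch residence time and displacement
#' for every vessel with a sufficiently long visitation series, and joins
#' activity and vessel length. Vessels with fewer than `min_series`
#' visitation elements are excluded as sparse.
#'
#' @param visitation fleet visitation series ([build_visitation_series()]).
#' @param grid the analysis grid.
#' @param trips logbook used for activity and vessel length.
#' @param activity_window Date pair for [activity_days()].
#' @param closure_ring closure polygon, or `NULL` to skip displacement.
#' @param burn_in burn-in fraction for [entropy_score()].
#' @param min_series minimum visitation elements for inclusion.
#' @return tibble: vessel_id, S (bits), prt (h), activity (days), length
#'   (m), displacement, n_series.
#' @export
strategy_profiles <- function(visitation, grid, trips, activity_window,
                              closure_ring = NULL, burn_in = 0.5,
                              min_series = 20) {
  per <- lapply(base::split(visitation, visitation$vessel_id), function(v) {
    v <- v[order(v$seq), ]
    if (nrow(v) < min_series) return(NULL)
    disp <- if (is.null(closure_ring)) NA_real_ else {
      cells <- unique(v[, c("cell_col", "cell_row")])
      displacement_score(cell_centers(grid, cells$cell_col, cells$cell_row),
                         closure_ring)
    }
    tibble::tibble(
      vessel_id = v$vessel_id[1],
      S = entropy_score(entropy_trajectory(v$cell), burn_in = burn_in),
      prt = patch_residence_time(v),
      displacement = disp,
      n_series = nrow(v)
    )
  })
  prof <- dplyr::bind_rows(per)
  if (nrow(prof) == 0) return(prof)
  act <- activity_days(trips, activity_window, vessels = prof$vessel_id)
  prof <- dplyr::left_join(prof, act, by = "vessel_id")
  len <- dplyr::distinct(trips[, c("vessel_id", "length_m")])
  prof <- dplyr::left_join(prof, len, by = "vessel_id")
  names(prof)[names(prof) == "length_m"] <- "length"
  prof[, c("vessel_id", "S", "prt", "activity", "length", "displacement", "n_series")]
}
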