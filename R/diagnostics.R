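# Robustness diagnostics: grid-size sensitivity of the entropy score, the
# depth confound check, and the travel-cost regression.

#' Sensitivity of entropy scores to grid resolution
#'
#' Recomputes per-vessel entropy scores on grids of several resolutions and
#' reports the Spearman rank correlation between the reference-resolution
#' scores and each alternative. High correlations indicate the strategy
#' ranking is not an artefact of the chosen cell size.
#'
#' @param classified_pings classified pings (activity column present).
#' @param sizes grid sides to test.
#' @param reference side of the reference grid.
#' @param burn_in,min_series passed to the scoring step.
#' @param ping_interval hours between pings.
#' @return tibble: size, rho, p, n_vessels. `rho` is `NA` when a score
#'   vector is constant (correlation undefined).
#' @export
grid_sensitivity <- function(classified_pings, sizes = c(20, 30, 45, 60, 75, 95),
                             reference = 30, burn_in = 0.5, min_series = 20,
                             ping_interval = 1) {
  fishing <- classified_pings[classified_pings$activity == "fishing", ]
  score_at <- function(n) {
    g <- build_grid(fishing, n = n)
    vis <- build_visitation_series(classified_pings, g, ping_interval = ping_interval)
    per <- lapply(base::split(vis, vis$vessel_id), function(v) {
      if (nrow(v) < min_series) return(NULL)
      tibble::tibble(vessel_id = v$vessel_id[1],
                     S = entropy_score(entropy_trajectory(v$cell[order(v$seq)]),
                                       burn_in = burn_in))
    })
    dplyr::bind_rows(per)
  }
  ref <- score_at(reference)
  if (nrow(ref) < 3) stop("need >= 3 vessels with scores", call. = FALSE)
  rows <- lapply(setdiff(sizes, reference), function(n) {
    alt <- score_at(n)
    m <- dplyr::inner_join(ref, alt, by = "vessel_id", suffix = c("_ref", "_alt"))
    if (nrow(m) < 3 || stats::sd(m$S_ref) == 0 || stats::sd(m$S_alt) == 0) {
      return(tibble::tibble(size = n, rho = NA_real_, p = NA_real_, n_vessels = nrow(m)))
    }
    ct <- suppressWarnings(stats::cor.test(m$S_ref, m$S_alt, method = "spearman"))
    tibble::tibble(size = n, rho = unname(ct$estimate), p = ct$p.value,
                   n_vessels = nrow(m))
  })
  dplyr::bind_rows(rows)
}

#' Depth confound check for the entropy score
#'
#' Regresses the entropy score on mean fishing depth per vessel and reports
#' (not asserts) the slope, t and p. In a well-behaved design there is no
#' systematic relationship.
#'
#' @param profiles tibble with vessel_id and S.
#' @param depths tibble with vessel_id and mean fishing `depth` (m).
#' @return list: slope, se, t, p, r, n.
#' @export
depth_entropy_check <- function(profiles, depths) {
  m <- dplyr::inner_join(profiles, depths, by = "vessel_id")
  if (nrow(m) < 3) stop("need >= 3 vessels", call. = FALSE)
  fit <- stats::lm(S ~ depth, data = m)
  sm <- summary(fit)$coefficients
  list(slope = sm["depth", "Estimate"], se = sm["depth", "Std. Error"],
       t = sm["depth", "t value"], p = sm["depth", "Pr(>|t|)"],
       r = stats::cor(m$S, m$depth), n = nrow(m))
}

#' Travel-cost regression: entropy vs revenue per kilometre
#'
#' Computes each trip's track length as the sum of inter-ping rhumb
#' distances, aggregates revenue per km travelled to vessel level, and
#' regresses the entropy score on it. A negative relation indicates
#' broad explorers travel farther per unit of revenue.
#'
#' @param trips logbook with revenue.
#' @param pings trip-resolved pings (carrying `trip_id`).
#' @param profiles tibble with vessel_id and S.
#' @return list: slope, F, p, n, data (vessel-level revenue_per_km).
#' @export
revenue_per_km <- function(trips, pings, profiles) {
  tp <- pings[!is.na(pings$trip_id), ]
  tp <- tp[order(tp$trip_id, tp$timestamp), ]
  dist_km <- lapply(base::split(tp, tp$trip_id), function(p) {
    n <- nrow(p)
    if (n < 2) return(0)
    sum(rhumb_distance(p$lon[-n], p$lat[-n], p$lon[-1], p$lat[-1])) / 1000
  })
  dk <- tibble::tibble(trip_id = names(dist_km), km = unlist(dist_km))
  m <- dplyr::inner_join(trips, dk, by = "trip_id")
  zero <- m$km <= 0
  if (any(zero)) message(sum(zero), " zero-distance trip(s) excluded")
  m <- m[!zero, ]
  vess <- dplyr::summarise(dplyr::group_by(m, .data$vessel_id),
                           revenue_per_km = sum(.data$revenue) / sum(.data$km),
                           .groups = "drop")
  d <- dplyr::inner_join(profiles, vess, by = "vessel_id")
  fit <- stats::lm(S ~ revenue_per_km, data = d)
  a <- stats::anova(fit)
  list(slope = unname(stats::coef(fit)["revenue_per_km"]),
       F = a$`F value`[1], p = a$`Pr(>F)`[1], n = nrow(d), data = d)
}
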