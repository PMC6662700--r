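# Trip-revenue modelling: the leave-one-out fleet-performance index, logbook
# filters, the undisturbed fixed-effects revenue model, and counterfactual
# business-as-usual deviances.

#' Leave-one-out fleet performance index
#'
#' For each trip t by vessel i, the mean raw revenue of all trips by *other*
#' vessels landing in the half-open window `(t, t + window_days]`. Controls
#' for shared temporal shocks (seasonality, storms, prices) without using
#' vessel i's own revenues.
#'
#' @param trips logbook tibble (vessel_id, trip_id, landing_date, revenue).
#' @param window_days window length after each trip, days.
#' @return `trips` with a `fleet_index` column; `NA` (and a message) where
#'   no qualifying trips exist.
#' @export
fleet_performance <- function(trips, window_days = 14) {
  trips$fleet_index <- fleet_index_window(trips, 0, window_days)
  if (anyNA(trips$fleet_index)) {
    message(sum(is.na(trips$fleet_index)),
            " trip(s) with no contemporaneous fleet trips; fleet_index = NA")
  }
  trips
}

# mean revenue of other vessels' trips landing in (d + lo, d + hi]
fleet_index_window <- function(trips, lo, hi) {
  d <- as.numeric(trips$landing_date)
  ord <- order(d)
  ds <- d[ord]; rev_s <- trips$revenue[ord]; ves_s <- trips$vessel_id[ord]
  csum <- cumsum(rev_s)
  cnt_le <- function(x) findInterval(x, ds)
  sum_all <- csum[pmax(cnt_le(d + hi), 1)] * (cnt_le(d + hi) > 0) -
    csum[pmax(cnt_le(d + lo), 1)] * (cnt_le(d + lo) > 0)
  n_all <- cnt_le(d + hi) - cnt_le(d + lo)
  # subtract own-vessel trips inside the window
  sum_own <- numeric(nrow(trips)); n_own <- numeric(nrow(trips))
  for (ix in base::split(seq_len(nrow(trips)), trips$vessel_id)) {
    dv <- sort(d[ix]); rv <- trips$revenue[ix][order(d[ix])]
    cv <- cumsum(rv)
    hi_i <- findInterval(d[ix] + hi, dv); lo_i <- findInterval(d[ix] + lo, dv)
    sum_own[ix] <- ifelse(hi_i > 0, cv[pmax(hi_i, 1)], 0) -
      ifelse(lo_i > 0, cv[pmax(lo_i, 1)], 0)
    n_own[ix] <- hi_i - lo_i
  }
  n_other <- n_all - n_own
  ifelse(n_other > 0, (sum_all - sum_own) / n_other, NA_real_)
}

#' Compare skewed vs symmetric fleet-index windows
#'
#' Computes the fleet index from the forward window `(t, t + w]` and from a
#' symmetric window `(t - w/2, t + w/2]` and reports their Pearson
#' correlation, quantifying the bias introduced by using a skewed window.
#'
#' @param trips logbook tibble.
#' @param window_days forward-window length, days.
#' @return list: r, t, df, p, n. `r` is `NA` when either index is constant.
#' @export
window_bias_check <- function(trips, window_days = 14) {
  skew <- fleet_index_window(trips, 0, window_days)
  symm <- fleet_index_window(trips, -window_days / 2, window_days / 2)
  ok <- !is.na(skew) & !is.na(symm)
  if (sum(ok) < 3) stop("need >= 3 paired index values", call. = FALSE)
  if (stats::sd(skew[ok]) == 0 || stats::sd(symm[ok]) == 0) {
    return(list(r = NA_real_, t = NA_real_, df = sum(ok) - 2, p = NA_real_,
                n = sum(ok), note = "constant index; correlation undefined"))
  }
  ct <- stats::cor.test(skew[ok], symm[ok])
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value, n = sum(ok))
}

#' Remove trips landing just before the closure
#'
#' Drops trips landing in `[closure_start - window_days, closure_start)`,
#' whose forward fleet-index windows would straddle the disturbance onset.
#'
#' @param trips logbook tibble.
#' @param closure_start Date of closure onset.
#' @param window_days width of the pruned window.
#' @return filtered trips; the removal count is attached as attribute
#'   `"n_pruned"`.
#' @export
prune_boundary_trips <- function(trips, closure_start, window_days = 14) {
  drop <- trips$landing_date >= closure_start - window_days &
    trips$landing_date < closure_start
  out <- trips[!drop, ]
  attr(out, "n_pruned") <- sum(drop)
  out
}

#' Remove extreme revenue outliers
#'
#' Iteratively removes the largest revenue while it exceeds `factor` times
#' the largest remaining other revenue, generalizing a manual dot-plot check
#' into an unattended rule.
#'
#' @param trips logbook tibble (>= 2 rows).
#' @param factor multiple of the second-largest value that flags an outlier.
#' @return filtered trips with attribute `"n_outliers"`.
#' @export
remove_revenue_outliers <- function(trips, factor = 5) {
  stopifnot(nrow(trips) >= 2)
  removed <- 0L
  repeat {
    r <- sort(trips$revenue, decreasing = TRUE)
    if (length(r) < 2 || r[1] <= factor * r[2]) break
    trips <- trips[trips$revenue != r[1], ]
    removed <- removed + 1L
  }
  attr(trips, "n_outliers") <- removed
  trips
}

#' Fit the undisturbed revenue model
#'
#' Linear model of trip revenue on vessel-identity fixed effects, trip
#' duration and the leave-one-out fleet index:
#' `Ru_it = P_i + beta1 * D_it + beta2 * F_-it + eps_it`.
#' Absolute per-vessel performance P_i is the reference-coded vessel
#' estimate plus the model intercept. Vessels with a single trip are
#' excluded from estimation. An optional log mode fits the same structure
#' on log revenue.
#'
#' @param trips undisturbed logbook with a `fleet_index` column
#'   ([fleet_performance()]); rows with `NA` index are dropped.
#' @param link_mode `"identity"` (default) or `"log"` (the whole
#'   counterfactual chain is then computed on the log scale).
#' @return an `undisturbed_model`: the lm fit, tibble `P` of absolute
#'   per-vessel performance, `beta_duration`, `beta_fleet`, residual sigma
#'   and the link mode.
#' @export
fit_undisturbed <- function(trips, link_mode = c("identity", "log")) {
  link_mode <- match.arg(link_mode)
  if (!"fleet_index" %in% names(trips)) {
    stop("trips need a fleet_index column; run fleet_performance() first", call. = FALSE)
  }
  d <- trips[!is.na(trips$fleet_index), ]
  n_per <- table(d$vessel_id)
  single <- names(n_per)[n_per < 2]
  if (length(single)) {
    message(length(single), " vessel(s) with < 2 usable trips excluded from the revenue model")
    d <- d[!(d$vessel_id %in% single), ]
  }
  d$vessel_id <- factor(d$vessel_id)
  if (link_mode == "log") {
    d <- d[d$revenue > 0, ]
    d$.y <- log(d$revenue)
  } else {
    d$.y <- d$revenue
  }
  # the fleet index is centred so the intercept (and hence absolute P_i) is
  # performance at average fleet conditions rather than an extrapolation to
  # zero fleet revenue
  f_center <- mean(d$fleet_index)
  d$fleet_index_c <- d$fleet_index - f_center
  fit <- stats::lm(.y ~ vessel_id + duration_days + fleet_index_c, data = d)
  cf <- stats::coef(fit)
  vl <- levels(d$vessel_id)
  p_abs <- cf["(Intercept)"] + c(0, cf[paste0("vessel_id", vl[-1])])
  structure(list(
    fit = fit,
    P = tibble::tibble(vessel_id = vl, P = unname(p_abs)),
    beta_duration = unname(cf["duration_days"]),
    beta_fleet = unname(cf["fleet_index_c"]),
    fleet_center = f_center,
    sigma = summary(fit)$sigma,
    link_mode = link_mode,
    n_trips = nrow(d)
  ), class = "undisturbed_model")
}

#' Business-as-usual performance deviance for disturbed trips
#'
#' Measured performance removes the duration and fleet effects from
#' disturbed revenue, `Md_it = Rd_it - b1 * D_it - b2 * F_-it`; expected
#' performance is the business-as-usual prediction of that quantity, the
#' vessel's absolute undisturbed performance `Ed_it = P_i`; and the
#' standardized deviance is `dP_it = Md_it / Ed_it - 1`, zero when the trip
#' performed exactly as expected. In log mode the same chain applies to log
#' revenue.
#'
#' @param model an [fit_undisturbed()] result.
#' @param disturbed_trips disturbed logbook with `fleet_index` (computed on
#'   the disturbed-period trips) and `days_since_closure`.
#' @return tibble: vessel_id, trip_id, days_since_closure, Md, Ed, deltaP.
#'   Trips by vessels absent from the undisturbed model, or with Ed <= 0,
#'   are excluded with a message.
#' @export
compute_deviance <- function(model, disturbed_trips) {
  stopifnot(inherits(model, "undisturbed_model"))
  d <- disturbed_trips[!is.na(disturbed_trips$fleet_index), ]
  known <- d$vessel_id %in% model$P$vessel_id
  if (any(!known)) {
    message(sum(!known), " disturbed trip(s) by vessels absent from the undisturbed model excluded")
    d <- d[known, ]
  }
  y <- if (model$link_mode == "log") log(pmax(d$revenue, .Machine$double.eps)) else d$revenue
  md <- y - model$beta_duration * d$duration_days -
    model$beta_fleet * (d$fleet_index - model$fleet_center)
  ed <- model$P$P[match(d$vessel_id, model$P$vessel_id)]
  bad <- ed <= 0
  if (any(bad)) {
    message(sum(bad), " trip(s) with non-positive expected performance excluded")
  }
  tibble::tibble(vessel_id = d$vessel_id, trip_id = d$trip_id,
                 days_since_closure = d$days_since_closure,
                 Md = md, Ed = ed, deltaP = md / ed - 1)[!bad, ]
}
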