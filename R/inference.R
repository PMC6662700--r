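# Strategy-performance inference: covariate scaling, the pre-disturbance
# cross-sectional model, the disturbed-period mixed model, stepwise AIC/BIC
# selection, the fleet-shift test and the growing-window analysis.

#' Standardize strategy covariates
#'
#' Rescales each continuous covariate to standard deviations around its own
#' mean (z-scores, sample SD). Quadratic terms are squares of the
#' standardized linear terms, so hump tests are centred on the fleet mean.
#' Original values are retained with a `_raw` suffix.
#'
#' @param profiles per-vessel tibble with columns among S, prt, activity,
#'   length, displacement.
#' @param cols covariates to scale.
#' @return tibble with standardized columns (same names), `S2`/`prt2`
#'   quadratics, and `*_raw` originals.
#' @export
scale_covariates <- function(profiles,
                             cols = intersect(c("S", "prt", "activity", "length",
                                                "displacement"), names(profiles))) {
  if (nrow(profiles) < 3) stop("need >= 3 vessels to standardize", call. = FALSE)
  out <- profiles
  for (cn in cols) {
    x <- profiles[[cn]]
    if (stats::sd(x, na.rm = TRUE) == 0) {
      stop("zero-variance covariate: ", cn, call. = FALSE)
    }
    out[[paste0(cn, "_raw")]] <- x
    out[[cn]] <- as.numeric(scale(x))
  }
  if ("S" %in% cols) out$S2 <- out$S^2
  if ("prt" %in% cols) out$prt2 <- out$prt^2
  out
}

#' Pre-disturbance performance regression
#'
#' Ordinary least squares of undisturbed per-vessel performance on linear
#' and quadratic entropy and patch-residence terms plus activity and length:
#' `P_i = a + b1 S + b2 S^2 + b3 prt + b4 prt^2 + b5 activity + b6 length`.
#' The quadratic terms test for humped performance around intermediate
#' strategies.
#'
#' @param P tibble (vessel_id, P) from [fit_undisturbed()].
#' @param covariates standardized covariates ([scale_covariates()]).
#' @return list: lm `fit`, `coefs` tibble (term, estimate, se, t, p), AIC,
#'   BIC, n.
#' @export
fit_performance_model <- function(P, covariates) {
  d <- dplyr::inner_join(P, covariates, by = "vessel_id")
  terms <- c("S", "S2", "prt", "prt2", "activity", "length")
  if (nrow(d) <= length(terms) + 1) stop("too few vessels for the model", call. = FALSE)
  fit <- stats::lm(stats::reformulate(terms, response = "P"), data = d)
  sm <- summary(fit)$coefficients
  list(fit = fit,
       coefs = tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                              se = unname(sm[, 2]), t = unname(sm[, 3]),
                              p = unname(sm[, 4])),
       AIC = stats::AIC(fit), BIC = stats::BIC(fit), n = nrow(d), data = d)
}

#' Stepwise AIC/BIC model reduction
#'
#' Sequentially drops the fixed-effect term whose removal lowers (or leaves
#' unchanged) both AIC and BIC, stopping when no drop qualifies. Hierarchy
#' is respected: a linear term is never dropped while its quadratic
#' (`<term>2`) remains. Ties favour the simpler model. Mixed models are
#' compared under maximum likelihood.
#'
#' @param response response variable name.
#' @param terms character vector of candidate fixed-effect terms.
#' @param data model frame.
#' @param random optional lme4 random-effects clause, e.g.
#'   `"(1 | vessel_id)"`; when supplied an lmer model is used.
#' @param keep terms never considered for dropping (forced into the model).
#' @return list: `terms` retained, final `fit` (REML for mixed models),
#'   `trace` tibble of drops.
#' @export
stepwise_select <- function(response, terms, data, random = NULL,
                            keep = character(0)) {
  fit_fun <- function(tm, reml = FALSE) {
    rhs <- if (length(tm)) tm else "1"
    if (is.null(random)) {
      stats::lm(stats::reformulate(rhs, response = response), data = data)
    } else {
      lme4::lmer(stats::as.formula(paste(response, "~", paste(c(rhs, random), collapse = " + "))),
                 data = data, REML = reml,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                            check.nobs.vs.nlev = "ignore",
                                            check.nobs.vs.nRE = "ignore"))
    }
  }
  current <- terms
  trace <- list()
  fit <- fit_fun(current)
  repeat {
    a0 <- stats::AIC(fit); b0 <- stats::BIC(fit)
    droppable <- current[!vapply(current, function(t) paste0(t, "2") %in% current,
                                 logical(1)) & !(current %in% keep)]
    if (length(droppable) == 0) break
    best <- NULL
    for (t in droppable) {
      cand <- suppressWarnings(suppressMessages(fit_fun(setdiff(current, t))))
      a1 <- stats::AIC(cand); b1 <- stats::BIC(cand)
      if (a1 <= a0 && b1 <= b0 && (is.null(best) || a1 < best$a1)) {
        best <- list(term = t, fit = cand, a1 = a1, b1 = b1)
      }
    }
    if (is.null(best)) break
    trace[[length(trace) + 1L]] <- tibble::tibble(
      dropped = best$term, AIC_before = a0, AIC_after = best$a1,
      BIC_before = b0, BIC_after = best$b1)
    current <- setdiff(current, best$term)
    fit <- best$fit
  }
  if (!is.null(random)) fit <- suppressWarnings(suppressMessages(fit_fun(current, reml = TRUE)))
  list(terms = current, fit = fit,
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         tibble::tibble(dropped = character(), AIC_before = numeric(),
                        AIC_after = numeric(), BIC_before = numeric(),
                        BIC_after = numeric()))
}

#' Disturbed-period deviance mixed model
#'
#' Linear mixed-effects model of per-trip performance deviance on the
#' standardized strategy covariates with a per-vessel random intercept:
#' `dP = (b0 + b0_i) + b1 S + b2 S^2 + b3 prt + b4 prt^2 + b5 activity +
#' b6 length + b7 displacement + eps`, `b0_i ~ N(0, sigma_i^2)`, fitted by
#' restricted maximum likelihood. p-values use the normal approximation to
#' the Wald statistic; 95% CIs are Wald intervals.
#'
#' @param deviance deviance records ([compute_deviance()]).
#' @param covariates standardized covariates including displacement.
#' @param terms fixed-effect terms to include.
#' @return a `deviance_model` list: lmer `fit`, `coefs` tibble (term,
#'   estimate, se, z, p, lo95, hi95), random-intercept SD, `singular` flag,
#'   AIC, BIC, n_trips, n_vessels.
#' @export
fit_deviance_model <- function(deviance, covariates,
                               terms = c("S", "S2", "prt", "prt2",
                                         "activity", "length", "displacement")) {
  d <- dplyr::inner_join(deviance, covariates, by = "vessel_id")
  if (length(unique(d$vessel_id)) < 2) stop("need >= 2 vessels with disturbed trips", call. = FALSE)
  terms <- intersect(terms, names(d))
  form <- stats::as.formula(paste("deltaP ~", paste(terms, collapse = " + "),
                                  "+ (1 | vessel_id)"))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                            check.nobs.vs.nlev = "ignore",
                                            check.nobs.vs.nRE = "ignore"))))
  singular <- lme4::isSingular(fit)
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  z <- est / se
  coefs <- tibble::tibble(term = rownames(sm), estimate = unname(est),
                          se = unname(se), z = unname(z),
                          p = 2 * stats::pnorm(-abs(unname(z))),
                          lo95 = unname(est - 1.96 * se),
                          hi95 = unname(est + 1.96 * se))
  structure(list(fit = fit, coefs = coefs,
                 ranef_sd = sqrt(unname(lme4::VarCorr(fit)$vessel_id[1])),
                 singular = singular,
                 AIC = stats::AIC(fit), BIC = stats::BIC(fit),
                 n_trips = nrow(d), n_vessels = length(unique(d$vessel_id)),
                 data = d),
            class = "deviance_model")
}

#' Fleet-shift test for a strategy metric
#'
#' One-way ANOVA comparing a metric's fleet distribution before vs during
#' the disturbance (e.g. entropy scores of all pre-closure vessels vs those
#' that kept fishing).
#'
#' @param before,during numeric score vectors (each length >= 2).
#' @return list: F, df1, df2, p, mean_before, mean_during.
#' @export
fleet_shift_test <- function(before, during) {
  if (length(before) < 2 || length(during) < 2) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  g <- factor(rep(c("before", "during"), c(length(before), length(during))))
  x <- c(before, during)
  ft <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = ft$p.value,
       mean_before = mean(before), mean_during = mean(during))
}

#' Growing-window analysis of deviance predictors
#'
#' Refits the fully specified deviance mixed model on nested post-closure
#' subsets (`[0, step]`, `[0, 2*step]`, ... up to `horizon` days) and
#' returns the coefficient trajectory with 95% CIs, tracing how strategy
#' effects dissipate after the disturbance onset.
#'
#' @param deviance deviance records with `days_since_closure`.
#' @param covariates standardized covariates.
#' @param step window increment, days.
#' @param horizon last window end, days.
#' @param terms fixed-effect terms of the full model.
#' @param select if `TRUE`, stepwise-reduce the model within each window
#'   (AIC/BIC rule) before reporting, mirroring per-window model selection;
#'   `keep` terms are never dropped.
#' @param keep terms protected from per-window selection.
#' @return tibble: window_end, term, estimate, se, lo95, hi95, n_trips,
#'   n_vessels. Windows that cannot be fitted are skipped with a message.
#' @export
growing_window <- function(deviance, covariates, step = 10, horizon = 50,
                           terms = c("S", "S2", "prt", "prt2",
                                     "activity", "length", "displacement"),
                           select = FALSE, keep = c("S", "displacement")) {
  ends <- seq(step, horizon, by = step)
  rows <- lapply(ends, function(e) {
    sub <- deviance[deviance$days_since_closure <= e, ]
    res <- tryCatch({
      w_terms <- terms
      if (select) {
        d <- dplyr::inner_join(sub, covariates, by = "vessel_id")
        sel <- stepwise_select("deltaP", terms, d, random = "(1 | vessel_id)",
                               keep = intersect(keep, terms))
        w_terms <- sel$terms
      }
      fit_deviance_model(sub, covariates, terms = w_terms)
    }, error = function(err) NULL)
    if (is.null(res) || res$n_trips <= length(res$coefs$term) + 1) {
      message("window [0, ", e, "] skipped: too few trips to fit")
      return(NULL)
    }
    cf <- res$coefs
    cf$window_end <- e
    cf$n_trips <- res$n_trips
    cf$n_vessels <- res$n_vessels
    cf[, c("window_end", "term", "estimate", "se", "lo95", "hi95",
           "n_trips", "n_vessels")]
  })
  dplyr::bind_rows(rows)
}
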