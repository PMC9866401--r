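#' Development-rate observations
#'
#' Helper constructing/validating a data frame of mean development times
#' observed at constant temperatures, the unit of data that TPC fitting
#' consumes. One row is one study x temperature x stage combination; the
#' development rate is the inverse of the mean development time.
#'
#' @param species species key (snake-case binomial).
#' @param stage life stage, one of \code{"egg"}, \code{"larva"}, \code{"pupa"}.
#' @param study_id study identifier (source of the observation).
#' @param temperature_C rearing temperature, degrees Celsius, in [0, 50].
#' @param mean_dev_time_days mean development time, days, > 0.
#' @return data frame with the five columns above plus \code{rate}
#'   (day^-1).
#' @export
rate_observations <- function(species, stage, study_id, temperature_C,
                              mean_dev_time_days) {
  obs <- data.frame(species = species, stage = stage, study_id = study_id,
                    temperature_C = temperature_C,
                    mean_dev_time_days = mean_dev_time_days,
                    stringsAsFactors = FALSE)
  validate_observations(obs)
}

validate_observations <- function(obs) {
  need <- c("species", "stage", "study_id", "temperature_C",
            "mean_dev_time_days")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("observations lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(obs$stage %in% c("egg", "larva", "pupa")))
    stop("stage must be one of egg, larva, pupa", call. = FALSE)
  if (any(obs$temperature_C < 0 | obs$temperature_C > 50))
    stop("temperatures must lie in [0, 50] degrees C", call. = FALSE)
  if (any(obs$mean_dev_time_days <= 0))
    stop("mean development times must be positive", call. = FALSE)
  obs$rate <- 1 / obs$mean_dev_time_days
  obs
}

## Starting values: thresholds bracket the observed temperatures, shape
## parameters at mild defaults, and the single multiplicative scale
## parameter solved so the curve passes through the largest observed rate.
.start_values <- function(model, temps, rates) {
  ct0 <- min(temps) - 2
  ct1 <- max(temps) + 2
  tpk <- temps[which.max(rates)]
  rpk <- max(rates)
  shape <- switch(model,
    analytis_77     = c(b = 2, c = 1),
    ratkowsky_83    = c(k = 0.2),
    hilbertLogan_83 = c(a = (tpk - ct0) / 2, deltaT = 4),
    beta_95         = c(a = 2, b = 1),
    beta_16         = c(Topt = tpk),
    briere2_99      = c(b = 2.5),
    shi_11          = c(k1 = 0.2, k2 = 0.4),
    perf2_11        = c(k = 0.4),
    regniere_12     = c(b = 0.15, deltab = 4),
    c())
  scale_name <- switch(model,
    analytis_77 = "a", ratkowsky_83 = "c", hilbertLogan_83 = "phi",
    beta_95 = "mu", beta_16 = "rm", briere1_99 = "a", briere2_99 = "a",
    kontodimas_04 = "a", shi_11 = "c", perf2_11 = "c", regniere_12 = "phi")
  p <- c(shape, CTmin = ct0, CTmax = ct1)
  ## value of the raw curve at the observed peak with unit scale
  unit <- p
  unit[[scale_name]] <- if (model == "beta_95") 0 else 1
  base <- .tpc_raw[[model]](as.list(unit), tpk)
  if (!is.finite(base) || base <= 0) base <- 1
  sc <- switch(model,
    ratkowsky_83 = sqrt(rpk / base),
    beta_95      = log(rpk / base),
    rpk / base)
  out <- c(p, sc)
  names(out)[length(out)] <- scale_name
  out[.tpc_param_names[[model]]]
}

#' Fit one TPC model to pooled observations for a life stage
#'
#' Nonlinear least squares on development rates via the
#' Levenberg-Marquardt algorithm, with multiple jittered restarts from
#' data-driven starting values (critical thresholds bracketing the
#' observed temperatures, the scale parameter matched to the largest
#' observed rate). The best converged restart by residual sum of squares
#' is kept. Standard errors come from the Gauss-Newton curvature
#' \eqn{(J'J)^{-1} RSS/(n-k)} at the optimum. Observations are pooled
#' across studies and fitted unweighted.
#'
#' @param observations data frame as from \code{\link{rate_observations}}
#'   (a single species and stage).
#' @param model model name from \code{\link{tpc_model_specs}}.
#' @param seed integer seed for the restart jitter.
#' @param n_starts number of jittered restarts (default 20).
#' @return an object of class \code{stage_fit}: list with \code{params}
#'   (\code{tpc_params} or NULL on failure), \code{stderrs}, \code{rss},
#'   \code{n_obs}, \code{aic}, \code{traits}, \code{converged},
#'   \code{status} (filled in by \code{\link{select_model}}), and the data.
#'   Non-convergence of every restart yields a fit-failure record
#'   (\code{converged = FALSE}), not an error.
#' @seealso \code{\link{fit_all_models}}, \code{\link{select_model}}
#' @export
fit_stage <- function(observations, model, seed = 1L, n_starts = 20L) {
  obs <- validate_observations(observations)
  pn <- .tpc_param_names[[model]]
  if (is.null(pn))
    stop("unknown TPC model '", model, "'", call. = FALSE)
  k <- length(pn)
  n <- nrow(obs)
  if (n <= k)
    stop("insufficient data: ", n, " observations for the ", k,
         "-parameter model '", model, "'", call. = FALSE)
  temps <- obs$temperature_C
  rates <- obs$rate

  raw <- .tpc_raw[[model]]
  ## residuals on the raw formula restricted to the open thermal domain;
  ## outside it the modelled rate is 0 by contract
  resid_fun <- function(par) {
    p <- as.list(par)
    if (p$CTmin >= p$CTmax) return(rep(1e6, n))
    if (model == "beta_16" && (p$Topt <= p$CTmin || p$Topt >= p$CTmax))
      return(rep(1e6, n))
    inside <- temps > p$CTmin & temps < p$CTmax
    pred <- numeric(n)
    if (any(inside)) pred[inside] <- pmax(0, raw(p, temps[inside]))
    pred[!is.finite(pred)] <- 1e6
    pred - rates
  }

  start0 <- .start_values(model, temps, rates)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- start0
    if (s > 1L) st <- st * (1 + stats::rnorm(length(st), 0, 0.15))
    ans <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(ans)) next
    rss <- sum(ans$fvec^2)
    if (!is.finite(rss)) next
    if (ans$par[["CTmin"]] >= ans$par[["CTmax"]]) next
    if (is.null(best) || rss < best_rss) {
      best <- ans
      best_rss <- rss
    }
  }

  species <- obs$species[1]
  stage <- obs$stage[1]
  if (is.null(best)) {
    return(structure(list(species = species, stage = stage, model = model,
                          params = NULL, stderrs = NULL, rss = Inf,
                          n_obs = n, aic = Inf, delta_aic = NA_real_,
                          traits = NULL, converged = FALSE,
                          status = "failed", observations = obs),
                     class = "stage_fit"))
  }

  est <- best$par
  rss <- best_rss
  params <- tryCatch(tpc_params(model, est), error = function(e) NULL)
  ## curvature-based standard errors
  se <- rep(NA_real_, k)
  names(se) <- pn
  if (n > k && rss > 0) {
    jtj <- best$hessian  # J'J at the optimum, as stored by nls.lm
    cv <- tryCatch(solve(jtj) * rss / (n - k), error = function(e) NULL)
    if (!is.null(cv)) {
      d <- diag(cv)
      se[d >= 0] <- sqrt(d[d >= 0])
    }
  }
  traits <- if (!is.null(params))
    tryCatch(tpc_traits(params), error = function(e) NULL) else NULL

  structure(list(species = species, stage = stage, model = model,
                 params = params, stderrs = se, rss = rss, n_obs = n,
                 aic = tpc_aic(rss, n, k), delta_aic = NA_real_,
                 traits = traits, converged = !is.null(params),
                 status = "unranked", observations = obs),
            class = "stage_fit")
}

#' @export
print.stage_fit <- function(x, ...) {
  cat(sprintf("stage_fit: %s %s, model %s [%s]\n", x$species, x$stage,
              x$model, x$status))
  if (x$converged) {
    est <- x$params$values
    cat(sprintf("  RSS %.4g on %d obs, AIC %.2f\n", x$rss, x$n_obs, x$aic))
    print(round(rbind(estimate = est, stderr = x$stderrs[names(est)]), 6))
    if (!is.null(x$traits))
      cat(sprintf("  Topt %.2f C (CTmin %.2f, CTmax %.2f)\n",
                  x$traits$Topt, x$traits$CTmin, x$traits$CTmax))
  } else cat("  did not converge\n")
  invisible(x)
}

#' AIC for a least-squares TPC fit
#'
#' Gaussian-likelihood AIC up to an additive constant:
#' \eqn{n \log(RSS/n) + 2 (k + 1)}, counting the error variance as the
#' extra parameter. Only AIC differences between fits to the same data are
#' meaningful, and those are invariant to the constant.
#'
#' @param rss residual sum of squares (> 0; an exactly-zero RSS is flagged
#'   as a perfect fit and returns \code{-Inf}).
#' @param n number of observations.
#' @param k number of model parameters.
#' @return numeric AIC value.
#' @examples
#' tpc_aic(0.001, 10, 3)  # 10*log(1e-4) + 8
#' @export
tpc_aic <- function(rss, n, k) {
  if (rss < 0) stop("RSS cannot be negative", call. = FALSE)
  if (rss == 0) {
    warning("perfect fit (RSS = 0); AIC is -Inf", call. = FALSE)
    return(-Inf)
  }
  n * log(rss / n) + 2 * (k + 1)
}

#' Fit every catalogue model to one stage's observations
#'
#' @inheritParams fit_stage
#' @param models character vector of model names (default: all eleven).
#' @return list of \code{stage_fit} objects, one per model.
#' @export
fit_all_models <- function(observations, seed = 1L,
                           models = names(tpc_model_specs()),
                           n_starts = 20L) {
  obs <- validate_observations(observations)
  fits <- list()
  for (m in models) {
    k <- length(.tpc_param_names[[m]])
    if (nrow(obs) <= k) next  # cannot fit; skip rather than abort the sweep
    fits[[m]] <- fit_stage(obs, m, seed = seed, n_starts = n_starts)
  }
  if (!length(fits))
    stop("no model has fewer parameters than there are observations",
         call. = FALSE)
  fits
}

#' Model-selection rules
#'
#' The selection ledger applied to a set of candidate fits: fits with
#' \eqn{\Delta AIC \ge 10} are discarded as clearly worse; fits with
#' \eqn{\Delta AIC \le 2} are treated as statistically equivalent; fits
#' whose estimated CTmin falls below 0 degrees C or CTmax above 50 degrees
#' C are discarded as biologically implausible (development is inhibited
#' by thermal stress at those temperatures).
#'
#' @param delta_aic_discard discard threshold on delta-AIC (default 10).
#' @param delta_aic_equivalent equivalence threshold (default 2).
#' @param ctmin_floor lower bound on plausible CTmin (default 0 C).
#' @param ctmax_ceiling upper bound on plausible CTmax (default 50 C).
#' @return list of class \code{selection_rules}.
#' @export
selection_rules <- function(delta_aic_discard = 10, delta_aic_equivalent = 2,
                            ctmin_floor = 0, ctmax_ceiling = 50) {
  if (delta_aic_discard <= delta_aic_equivalent)
    stop("discard threshold must exceed the equivalence threshold",
         call. = FALSE)
  structure(list(delta_aic_discard = delta_aic_discard,
                 delta_aic_equivalent = delta_aic_equivalent,
                 ctmin_floor = ctmin_floor,
                 ctmax_ceiling = ctmax_ceiling),
            class = "selection_rules")
}

#' Select the best fit under the AIC + biology ledger
#'
#' Pipeline, in order: (1) delta-AIC against the lowest AIC among converged
#' fits; fits at or above the discard threshold get status
#' \code{discarded_aic}; (2) fits within the equivalence threshold are
#' marked \code{equivalent}; (3) fits whose CTmin/CTmax violate the
#' biological bounds get \code{discarded_biology} (applied to every fit,
#' including AIC survivors); (4) the surviving fit with the lowest AIC is
#' \code{selected}.
#'
#' @param fits list of \code{stage_fit} objects for the same data.
#' @param rules a \code{\link{selection_rules}} object.
#' @return list with \code{selected} (the winning \code{stage_fit}) and
#'   \code{fits} (all fits, statuses annotated). If no fit survives,
#'   an error lists each discarded fit and the reason.
#' @export
select_model <- function(fits, rules = selection_rules()) {
  if (inherits(fits, "stage_fit")) fits <- list(fits)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv))
    stop("no converged fit to select from", call. = FALSE)
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  best_aic <- min(aics[conv])
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (!conv[i]) { fits[[i]]$status <- "failed"; next }
    f$delta_aic <- f$aic - best_aic
    if (is.nan(f$delta_aic)) f$delta_aic <- 0  # perfect fits (-Inf AIC) tie at the top
    v <- f$params$values
    if (v[["CTmin"]] < rules$ctmin_floor ||
        v[["CTmax"]] > rules$ctmax_ceiling) {
      f$status <- "discarded_biology"
    } else if (f$delta_aic >= rules$delta_aic_discard) {
      f$status <- "discarded_aic"
    } else if (f$delta_aic <= rules$delta_aic_equivalent) {
      f$status <- "equivalent"
    } else {
      f$status <- "retained"
    }
    fits[[i]] <- f
  }
  ok <- vapply(fits, function(f)
    f$status %in% c("equivalent", "retained"), logical(1))
  if (!any(ok)) {
    why <- vapply(fits, function(f)
      paste0(f$model, ": ", f$status), character(1))
    stop("no fit survives the selection filters --\n  ",
         paste(why, collapse = "\n  "), call. = FALSE)
  }
  win <- which(ok)[which.min(aics[ok])]
  fits[[win]]$status <- "selected"
  list(selected = fits[[win]], fits = fits)
}

#' Residual diagnostics for a converged fit
#'
#' Exports the material for the usual graphical NLS checks: residuals and
#' fitted values, a Shapiro-Wilk normality statistic, and the slope of the
#' scale-location regression (sqrt(|standardised residual|) on fitted
#' value) as a homoscedasticity indicator. Diagnostic only -- nothing is
#' rejected automatically.
#'
#' @param fit a converged \code{stage_fit}.
#' @return list with \code{table} (data frame: temperature_C, observed,
#'   fitted, residual), \code{shapiro_W}, \code{shapiro_p},
#'   \code{scale_location_slope}.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "stage_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  obs <- fit$observations
  fitted <- tpc_rate(fit$params, obs$temperature_C)
  res <- obs$rate - fitted
  tab <- data.frame(temperature_C = obs$temperature_C, observed = obs$rate,
                    fitted = fitted, residual = res)
  sw <- if (length(res) >= 3 && stats::sd(res) > 0)
    stats::shapiro.test(res) else list(statistic = NA_real_, p.value = NA_real_)
  sl <- NA_real_
  if (stats::sd(res) > 0 && stats::sd(fitted) > 0) {
    z <- sqrt(abs(res / stats::sd(res)))
    sl <- unname(stats::coef(stats::lm(z ~ fitted))[2])
  }
  list(table = tab, shapiro_W = unname(sw$statistic),
       shapiro_p = sw$p.value, scale_location_slope = sl)
}

#' Check for a study effect in pooled observations
#'
#' One-way analysis of variance of the fit residuals grouped by study.
#' Pooling data across rearing studies assumes no systematic between-study
#' differences in development rate; a small p-value flags a study effect.
#' The response is the residual from the fitted curve (so the shared
#' temperature dependence is removed first); this operationalisation is
#' recorded in the returned \code{method} field.
#'
#' @param fit a converged \code{stage_fit} whose observations carry at
#'   least two distinct \code{study_id} values.
#' @return list with \code{F}, \code{p}, \code{df}, \code{n_studies},
#'   \code{method}; if only one study is present, \code{p} and \code{F} are
#'   \code{NA} and \code{applicable} is \code{FALSE}.
#' @export
study_effect_check <- function(fit) {
  stopifnot(inherits(fit, "stage_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  obs <- fit$observations
  studies <- unique(obs$study_id)
  method <- "one-way ANOVA of NLS residuals grouped by study_id"
  if (length(studies) < 2)
    return(list(applicable = FALSE, F = NA_real_, p = NA_real_,
                df = c(NA_integer_, NA_integer_), n_studies = 1L,
                method = method))
  res <- obs$rate - tpc_rate(fit$params, obs$temperature_C)
  fitaov <- stats::aov(res ~ factor(obs$study_id))
  s <- summary(fitaov)[[1]]
  list(applicable = TRUE, F = s$`F value`[1], p = s$`Pr(>F)`[1],
       df = s$Df, n_studies = length(studies), method = method)
}

#' Tabulate a list of fits as a Table-3-style report
#'
#' @param fits list of \code{stage_fit} objects (e.g. from
#'   \code{\link{select_model}}'s \code{fits} element).
#' @return data frame with one row per parameter per fit: species, stage,
#'   model, parameter, estimate, stderr, rss, n, aic, delta_aic, status.
#' @export
fit_report <- function(fits) {
  if (inherits(fits, "stage_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    if (!f$converged)
      return(data.frame(species = f$species, stage = f$stage,
                        model = f$model, parameter = NA_character_,
                        estimate = NA_real_, stderr = NA_real_,
                        rss = NA_real_, n = f$n_obs, aic = NA_real_,
                        delta_aic = NA_real_, status = f$status))
    est <- f$params$values
    data.frame(species = f$species, stage = f$stage, model = f$model,
               parameter = names(est), estimate = unname(est),
               stderr = unname(f$stderrs[names(est)]), rss = f$rss,
               n = f$n_obs, aic = f$aic,
               delta_aic = if (is.null(f$delta_aic)) NA_real_ else f$delta_aic,
               status = f$status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
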