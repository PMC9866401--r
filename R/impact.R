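#' Period specification for climate averaging
#'
#' @param label \code{"current"} or \code{"future"}.
#' @param year_start,year_end inclusive year range. Defaults follow the
#'   convention current = 1990-2014, future = 2081-2100.
#' @return list of class \code{period_spec}.
#' @export
period_spec <- function(label = c("current", "future"),
                        year_start = NULL, year_end = NULL) {
  label <- match.arg(label)
  if (is.null(year_start))
    year_start <- if (label == "current") 1990L else 2081L
  if (is.null(year_end))
    year_end <- if (label == "current") 2014L else 2100L
  stopifnot(year_start <= year_end)
  structure(list(label = label, year_start = as.integer(year_start),
                 year_end = as.integer(year_end)),
            class = "period_spec")
}

validate_ensemble <- function(records) {
  need <- c("region", "scenario", "gcm", "year", "month", "tas_C")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("ensemble records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(records$month %in% 1:12))
    stop("month must be in 1..12", call. = FALSE)
  if (any(records$tas_C < -90 | records$tas_C > 60))
    stop("tas_C outside plausible range [-90, 60]", call. = FALSE)
  records
}

#' Monthly climatology of one GCM over a period
#'
#' Arithmetic mean of each calendar month across the years of the period
#' (equal weight per year-month). The period must be complete: every month
#' of every year present, for the single GCM/scenario/region selected in
#' \code{records}.
#'
#' @param records data frame of monthly temperature records with columns
#'   region, scenario, gcm, year, month, tas_C (one GCM's series).
#' @param period a \code{\link{period_spec}}.
#' @return named numeric vector of 12 monthly means, degrees C.
#' @export
period_monthly_means <- function(records, period) {
  records <- validate_ensemble(records)
  stopifnot(inherits(period, "period_spec"))
  years <- period$year_start:period$year_end
  sub <- records[records$year %in% years, , drop = FALSE]
  have <- paste(sub$year, sub$month)
  want <- as.vector(outer(years, 1:12, paste))
  gap <- setdiff(want, have)
  if (length(gap))
    stop("missing year-month(s) in period ", period$year_start, "-",
         period$year_end, ": ", paste(utils::head(gap, 12), collapse = ", "),
         if (length(gap) > 12) " ..." else "", call. = FALSE)
  means <- tapply(sub$tas_C, factor(sub$month, levels = 1:12), mean)
  stats::setNames(as.numeric(means), month.abb)
}

#' Fraction of maximal development rate at a temperature
#'
#' \eqn{r(T)/r_{max}}: the total development rate at temperature T divided
#' by the species' maximum total rate. Lies in [0, 1]; equals 1 at the
#' optimum and 0 wherever any life stage has null development. Computed on
#' the deterministic total-rate curve.
#'
#' @param model a \code{\link{species_model}}.
#' @param temp numeric vector of temperatures, degrees C.
#' @param rmax optional precomputed \code{\link{total_rmax}} value (the
#'   \code{rmax} element); computed if missing.
#' @return numeric vector of fractions in [0, 1].
#' @export
r_over_rmax <- function(model, temp, rmax = NULL) {
  if (is.null(rmax)) rmax <- total_rmax(model)$rmax
  if (rmax <= 0) stop("rmax must be positive", call. = FALSE)
  pmin(1, total_rate_curve(model, temp) / rmax)
}

#' Monthly warming-impact differences
#'
#' Per calendar month, the difference between the fraction of maximal
#' development reached under future temperatures and under current
#' temperatures. Positive values mean faster development under warming;
#' each difference lies in [-1, 1].
#'
#' @param model a \code{\link{species_model}}.
#' @param current_means,future_means numeric vectors of 12 monthly mean
#'   temperatures, degrees C.
#' @return numeric vector of 12 differences.
#' @export
impact_difference <- function(model, current_means, future_means) {
  if (length(current_means) != 12 || length(future_means) != 12)
    stop("monthly means must have length 12", call. = FALSE)
  rmax <- total_rmax(model)$rmax
  r_over_rmax(model, future_means, rmax) -
    r_over_rmax(model, current_means, rmax)
}

#' Warming impact across a GCM ensemble
#'
#' For every GCM present in both the historical records and the chosen
#' scenario, computes the monthly climatologies over the current and
#' future periods and the per-month r/rmax difference.
#'
#' @param model a \code{\link{species_model}}.
#' @param records ensemble data frame (columns region, scenario, gcm,
#'   year, month, tas_C) holding historical and scenario rows for one
#'   region.
#' @param scenario future scenario label, e.g. \code{"ssp126"} or
#'   \code{"ssp585"}.
#' @param current,future \code{\link{period_spec}} objects.
#' @return data frame of impact records: species, region, scenario, gcm,
#'   month, r_over_rmax_current, r_over_rmax_future, difference.
#' @export
impact_assessment <- function(model, records, scenario,
                              current = period_spec("current"),
                              future = period_spec("future")) {
  records <- validate_ensemble(records)
  region <- unique(records$region)
  if (length(region) != 1)
    stop("records must cover exactly one region, got: ",
         paste(region, collapse = ", "), call. = FALSE)
  hist <- records[records$scenario == "historical", , drop = FALSE]
  fut <- records[records$scenario == scenario, , drop = FALSE]
  if (!nrow(fut))
    stop("no records for scenario '", scenario, "'", call. = FALSE)
  gcms <- sort(intersect(unique(hist$gcm), unique(fut$gcm)))
  if (!length(gcms))
    stop("no GCM present in both historical and scenario records",
         call. = FALSE)
  rmax <- total_rmax(model)$rmax
  out <- lapply(gcms, function(g) {
    cm <- period_monthly_means(hist[hist$gcm == g, ], current)
    fm <- period_monthly_means(fut[fut$gcm == g, ], future)
    rc <- r_over_rmax(model, cm, rmax)
    rf <- r_over_rmax(model, fm, rmax)
    data.frame(species = model$species, region = region,
               scenario = scenario, gcm = g, month = 1:12,
               r_over_rmax_current = rc, r_over_rmax_future = rf,
               difference = rf - rc)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise impact records across the GCM ensemble
#'
#' Per month (and scenario), the mean, minimum, maximum, quartiles and
#' median of the r/rmax differences across GCMs. Quantiles use linear
#' interpolation between order statistics.
#'
#' @param impacts data frame from \code{\link{impact_assessment}}.
#' @return data frame with one row per scenario x month: n_gcm, mean, min,
#'   q25, median, q75, max.
#' @export
ensemble_summary <- function(impacts) {
  need <- c("scenario", "month", "difference")
  if (!all(need %in% names(impacts)))
    stop("impact records lack column(s): ",
         paste(setdiff(need, names(impacts)), collapse = ", "), call. = FALSE)
  grp <- interaction(impacts$scenario, impacts$month, drop = TRUE)
  rows <- lapply(split(impacts, grp), function(d) {
    q <- stats::quantile(d$difference, c(0.25, 0.5, 0.75), names = FALSE,
                         type = 7)
    data.frame(scenario = d$scenario[1], month = d$month[1],
               n_gcm = nrow(d), mean = mean(d$difference),
               min = min(d$difference), q25 = q[1], median = q[2],
               q75 = q[3], max = max(d$difference))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$scenario, out$month), ]
  rownames(out) <- NULL
  out
}
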