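#' Species development model
#'
#' Bundles the three selected stage-level thermal performance curves (egg,
#' larva, pupa) with the inter-individual coefficient of variation of
#' development rates. The default cv of 0.15 reflects reported
#' inter-individual variation in insect development rates and is shared by
#' all stages.
#'
#' @param species species key.
#' @param egg,larva,pupa \code{\link{tpc_params}} objects for the three
#'   immature stages.
#' @param cv coefficient of variation of individual development rates
#'   around the stage TPC mean (dimensionless, >= 0; default 0.15).
#' @return object of class \code{species_model}.
#' @export
species_model <- function(species, egg, larva, pupa, cv = 0.15) {
  for (s in list(egg, larva, pupa))
    stopifnot(inherits(s, "tpc_params"))
  if (!is.numeric(cv) || length(cv) != 1 || cv < 0)
    stop("cv must be a single non-negative number", call. = FALSE)
  structure(list(species = species,
                 stages = list(egg = egg, larva = larva, pupa = pupa),
                 cv = cv),
            class = "species_model")
}

#' @export
print.species_model <- function(x, ...) {
  cat("species_model:", x$species, " (cv =", x$cv, ")\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-5s %-14s CTmin %.1f  CTmax %.1f\n", nm,
                x$stages[[nm]]$model, x$stages[[nm]]$values[["CTmin"]],
                x$stages[[nm]]$values[["CTmax"]]))
  invisible(x)
}

#' Simulation settings
#'
#' @param n_individuals cohort size (default 5000).
#' @param deadline_days growing-season deadline for complete egg-to-imago
#'   development, days (default 182, i.e. six months between two dry
#'   seasons in the tropics or spring to autumn in temperate regions).
#' @param seed integer master seed; per-temperature streams are derived
#'   from it deterministically so refining a temperature grid does not
#'   reshuffle draws at existing temperatures.
#' @return list of class \code{sim_settings}.
#' @export
sim_settings <- function(n_individuals = 5000L, deadline_days = 182,
                         seed = 1L) {
  stopifnot(n_individuals >= 1, deadline_days > 0)
  structure(list(n_individuals = as.integer(n_individuals),
                 deadline_days = deadline_days, seed = as.integer(seed)),
            class = "sim_settings")
}

## deterministic per-temperature sub-stream seed (stays within 32-bit int)
.temp_seed <- function(seed, temp) {
  as.integer((as.double(seed) * 7919 + round(temp * 1000)) %% 2147483647)
}

## truncated-normal draws on [0, Inf) by inverse CDF; exact and vectorised
.rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Draw individual stage-level development rates
#'
#' For each individual and each stage j, the development rate at
#' temperature T is drawn from a normal distribution with mean equal to
#' the stage TPC rate tau_j(T) and standard deviation cv * tau_j(T),
#' truncated to [0, Inf) since development cannot run backwards. Stages
#' are independent within an individual. If tau_j(T) = 0 the stage rate is
#' exactly 0 (null development).
#'
#' @param model a \code{\link{species_model}}.
#' @param temp constant temperature, degrees C.
#' @param settings a \code{\link{sim_settings}} object; its seed (combined
#'   deterministically with \code{temp}) governs the draws.
#' @return numeric matrix, \code{n_individuals} x 3 (columns egg, larva,
#'   pupa), of rates in day^-1.
#' @export
draw_individual_rates <- function(model, temp, settings = sim_settings()) {
  stopifnot(inherits(model, "species_model"),
            inherits(settings, "sim_settings"))
  n <- settings$n_individuals
  set.seed(.temp_seed(settings$seed, temp))
  out <- matrix(0, n, 3, dimnames = list(NULL, c("egg", "larva", "pupa")))
  for (j in 1:3) {
    tau <- tpc_rate(model$stages[[j]], temp)
    if (tau > 0) out[, j] <- .rtruncnorm0(n, tau, model$cv * tau)
  }
  out
}

#' Simulate egg-to-imago development times at a constant temperature
#'
#' Each individual's total development time is the sum over the three
#' stages of the inverse of its drawn stage rate; an individual with any
#' zero stage rate has infinite total time. An individual fails when its
#' total time strictly exceeds the deadline (infinite times always fail).
#' All eggs are laid simultaneously at time zero.
#'
#' @inheritParams draw_individual_rates
#' @return list of class \code{dev_time_distribution}: \code{temperature_C},
#'   \code{times} (per-individual days, possibly \code{Inf}), \code{mean},
#'   \code{median}, \code{q2.5}, \code{q97.5} (empirical quantiles),
#'   \code{failure_fraction}.
#' @examples
#' \donttest{
#' bf <- stemborer_models()[["busseola_fusca"]]
#' simulate_dev_times(bf, 25, sim_settings(seed = 42))$mean
#' }
#' @export
simulate_dev_times <- function(model, temp, settings = sim_settings()) {
  r <- draw_individual_rates(model, temp, settings)
  d <- rowSums(1 / r)  # 1/0 = Inf propagates as intended
  q <- stats::quantile(d, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  structure(list(temperature_C = temp, times = d, mean = mean(d),
                 median = q[2], q2.5 = q[1], q97.5 = q[3],
                 failure_fraction = mean(d > settings$deadline_days)),
            class = "dev_time_distribution")
}

failure_fraction_at <- function(model, temp, settings) {
  r <- draw_individual_rates(model, temp, settings)
  mean(rowSums(1 / r) > settings$deadline_days)
}

#' Thermal window for complete development
#'
#' T50min and T50max are the lowest and highest constant temperatures at
#' which at least half of the simulated cohort completes egg-to-imago
#' development within the deadline. Located by a coarse 0.5-degree scan of
#' [0, 50] followed by bisection to 0.05 degrees; every temperature is
#' evaluated with its own deterministic sub-stream of the master seed.
#'
#' @inheritParams draw_individual_rates
#' @param scan_step coarse scan step, degrees C (default 0.5).
#' @param refine_tol bisection tolerance, degrees C (default 0.05).
#' @return list of class \code{thermal_window} with \code{T50min},
#'   \code{T50max}, \code{deadline_days}; both bounds are \code{NA} (empty
#'   window) if development fails at every scanned temperature.
#' @examples
#' \donttest{
#' cp <- stemborer_models()[["chilo_partellus"]]
#' thermal_window(cp, sim_settings(seed = 42))  # about (16.6, 37.1)
#' }
#' @export
thermal_window <- function(model, settings = sim_settings(),
                           scan_step = 0.5, refine_tol = 0.05) {
  stopifnot(inherits(model, "species_model"))
  grid <- seq(0, 50, by = scan_step)
  ok <- vapply(grid, function(T)
    failure_fraction_at(model, T, settings) <= 0.5, logical(1))
  if (!any(ok))
    return(structure(list(T50min = NA_real_, T50max = NA_real_,
                          deadline_days = settings$deadline_days,
                          empty = TRUE),
                     class = "thermal_window"))
  lo_i <- which(ok)[1]
  hi_i <- which(ok)[length(which(ok))]

  bisect <- function(fail_T, succ_T) {
    while (abs(succ_T - fail_T) > refine_tol) {
      mid <- (fail_T + succ_T) / 2
      if (failure_fraction_at(model, mid, settings) <= 0.5) succ_T <- mid
      else fail_T <- mid
    }
    succ_T
  }
  t50min <- if (lo_i == 1L) grid[1] else bisect(grid[lo_i - 1L], grid[lo_i])
  t50max <- if (hi_i == length(grid)) grid[length(grid)]
            else bisect(grid[hi_i + 1L], grid[hi_i])
  structure(list(T50min = t50min, T50max = t50max,
                 deadline_days = settings$deadline_days, empty = FALSE),
            class = "thermal_window")
}

#' @export
print.thermal_window <- function(x, ...) {
  if (isTRUE(x$empty))
    cat("thermal window: empty (development fails at every temperature)\n")
  else
    cat(sprintf("thermal window: T50min = %.2f C, T50max = %.2f C (deadline %g d)\n",
                x$T50min, x$T50max, x$deadline_days))
  invisible(x)
}

#' Deterministic total development rate across temperature
#'
#' The development rate for complete immature development is the inverse
#' of the summed mean stage times, \eqn{r(T) = 1 / \sum_j 1/\tau_j(T)},
#' and is 0 wherever any stage rate is null.
#'
#' @param model a \code{\link{species_model}}.
#' @param temp numeric vector of temperatures, degrees C.
#' @return numeric vector of total rates, day^-1.
#' @examples
#' \donttest{
#' cp <- stemborer_models()[["chilo_partellus"]]
#' total_rate_curve(cp, 25)  # 0.02206 / day (45.3 days)
#' }
#' @export
total_rate_curve <- function(model, temp) {
  stopifnot(inherits(model, "species_model"))
  taus <- vapply(model$stages, tpc_rate, numeric(length(temp)), temp = temp)
  if (length(temp) == 1L) taus <- matrix(taus, nrow = 1L)
  out <- 1 / rowSums(1 / taus)
  out[!is.finite(out)] <- 0
  out
}

#' Maximum total development rate
#'
#' Maximum of \code{\link{total_rate_curve}} over [0, 50] degrees C at
#' 0.01-degree resolution, and its argmax temperature.
#'
#' @param model a \code{\link{species_model}}.
#' @return list with \code{rmax} (day^-1) and \code{T_at_rmax} (degrees C).
#' @export
total_rmax <- function(model) {
  grid <- seq(0, 50, by = 0.01)
  r <- total_rate_curve(model, grid)
  if (all(r <= 0))
    stop("degenerate model: total development rate is zero everywhere",
         call. = FALSE)
  i <- which.max(r)
  list(rmax = r[i], T_at_rmax = grid[i])
}
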