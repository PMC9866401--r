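#' Generate synthetic development-rate observations
#'
#' Emulates the literature tables the TPC fitting consumes: for each study
#' x temperature x stage, \code{n_reps} individual stage development times
#' are simulated under the same variance model the development simulator
#' assumes (individual rates normal with mean tau_j(T) and sd
#' cv * tau_j(T), truncated at 0), and their mean time is recorded as one
#' observation. Optional per-study multiplicative biases on mean
#' development time inject a study effect. Temperature x stage
#' combinations where the true rate is null are omitted (real studies
#' report no development time there), with a message.
#'
#' @param truth a \code{\link{species_model}} giving the generating stage
#'   curves; its \code{cv} is used unless \code{cv} is supplied.
#' @param temperatures numeric vector of rearing temperatures, degrees C,
#'   within [0, 50].
#' @param n_reps individuals per temperature x stage (>= 1).
#' @param cv coefficient of variation of individual rates; \code{cv = 0}
#'   yields mean times exactly \code{1/tau_j(T)}.
#' @param study_offsets named numeric vector of multiplicative biases on
#'   mean development time, one per study (names are the study ids);
#'   default a single unbiased study \code{"S1"}.
#' @param seed integer seed.
#' @return observations data frame as accepted by \code{\link{fit_stage}}.
#' @export
generate_observations <- function(truth, temperatures, n_reps = 50L,
                                  cv = NULL, study_offsets = c(S1 = 1),
                                  seed = 1L) {
  stopifnot(inherits(truth, "species_model"), n_reps >= 1,
            all(temperatures >= 0 & temperatures <= 50))
  if (is.null(cv)) cv <- truth$cv
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  if (is.null(names(study_offsets)))
    stop("study_offsets must be a named vector (names = study ids)",
         call. = FALSE)
  set.seed(as.integer(seed))
  rows <- list()
  dropped <- 0L
  for (study in names(study_offsets)) {
    for (stage in names(truth$stages)) {
      for (temp in temperatures) {
        tau <- tpc_rate(truth$stages[[stage]], temp)
        if (tau <= 0) { dropped <- dropped + 1L; next }
        r <- .rtruncnorm0(n_reps, tau, cv * tau)
        times <- 1 / r
        times <- times[is.finite(times)]
        if (!length(times)) { dropped <- dropped + 1L; next }
        rows[[length(rows) + 1L]] <- data.frame(
          species = truth$species, stage = stage, study_id = study,
          temperature_C = temp,
          mean_dev_time_days = mean(times) * study_offsets[[study]])
      }
    }
  }
  if (dropped > 0L)
    message(dropped, " non-developing temperature x stage combination(s) omitted")
  if (!length(rows))
    stop("no developing temperature x stage combination in the request",
         call. = FALSE)
  validate_observations(do.call(rbind, rows))
}

#' Generate a GCM-like monthly temperature ensemble
#'
#' A deliberately simple test fixture for the climate-impact pipeline, not
#' a climate emulator: historical records are a 12-month baseline
#' climatology plus interannual noise; each future scenario adds a
#' scenario-wide warming offset and a GCM-specific shift drawn once per
#' GCM, plus interannual noise. Deterministic under \code{seed}.
#'
#' @param baseline_monthly numeric vector of 12 baseline monthly mean
#'   temperatures, degrees C.
#' @param warming_offsets named numeric vector of scenario warming offsets
#'   in degrees C, e.g. \code{c(ssp126 = 1.5, ssp585 = 4)}.
#' @param n_gcms number of GCMs per scenario.
#' @param inter_gcm_sd sd of the per-GCM shift, degrees C.
#' @param interannual_sd sd of the year-to-year noise, degrees C.
#' @param region region label stamped on every record.
#' @param current,future \code{\link{period_spec}} objects giving the
#'   historical and scenario year ranges.
#' @param seed integer seed.
#' @return ensemble data frame with columns region, scenario, gcm, year,
#'   month, tas_C.
#' @export
generate_ensemble <- function(baseline_monthly,
                              warming_offsets = c(ssp126 = 1.5, ssp585 = 4),
                              n_gcms = 5L, inter_gcm_sd = 0.5,
                              interannual_sd = 0.5, region = "SEAF",
                              current = period_spec("current"),
                              future = period_spec("future"),
                              seed = 1L) {
  stopifnot(length(baseline_monthly) == 12, n_gcms >= 1,
            inter_gcm_sd >= 0, interannual_sd >= 0)
  set.seed(as.integer(seed))
  gcms <- sprintf("gcm%02d", seq_len(n_gcms))
  block <- function(scenario, years, offset, shift) {
    grid <- expand.grid(month = 1:12, year = years)
    data.frame(region = region, scenario = scenario,
               year = grid$year, month = grid$month,
               tas_C = baseline_monthly[grid$month] + offset + shift +
                 stats::rnorm(nrow(grid), 0, interannual_sd))
  }
  out <- list()
  for (g in gcms) {
    hist <- block("historical", current$year_start:current$year_end, 0, 0)
    hist$gcm <- g
    out[[length(out) + 1L]] <- hist
    for (sc in names(warming_offsets)) {
      shift <- stats::rnorm(1, 0, inter_gcm_sd)
      fut <- block(sc, future$year_start:future$year_end,
                   warming_offsets[[sc]], shift)
      fut$gcm <- g
      out[[length(out) + 1L]] <- fut
    }
  }
  res <- do.call(rbind, out)
  validate_ensemble(res[, c("region", "scenario", "gcm", "year", "month",
                            "tas_C")])
}
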