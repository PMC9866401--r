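#' Fitted stage parameter sets for the four stemborer species
#'
#' Loads the packaged table of selected stage-level TPC fits (model name,
#' parameter estimates and standard errors for the egg, larval and pupal
#' stages of Chilo partellus, Busseola fusca, Ostrinia nubilalis and
#' Sesamia nonagrioides) and assembles one \code{\link{species_model}} per
#' species. Species keys are snake-case binomials. The tabulated Topt rows
#' are derived traits, not free parameters, and are dropped for every
#' model that does not fit Topt directly.
#'
#' @param cv inter-individual coefficient of variation attached to each
#'   model (default 0.15).
#' @param file path to an alternative parameter table with columns
#'   species, stage, model, parameter, estimate, stderr; default the
#'   packaged table.
#' @return named list of \code{\link{species_model}} objects.
#' @examples
#' names(stemborer_models())
#' stemborer_models()[["chilo_partellus"]]
#' @export
stemborer_models <- function(cv = 0.15, file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "stage_parameters.csv",
                        package = "tpcdev", mustWork = TRUE)
  if (!file.exists(file))
    stop("parameter table not found: ", file, call. = FALSE)
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  out <- list()
  for (sp in unique(tab$species)) {
    stages <- list()
    for (st in c("egg", "larva", "pupa")) {
      rows <- tab[tab$species == sp & tab$stage == st, ]
      if (!nrow(rows))
        stop("parameter table has no rows for ", sp, " ", st, call. = FALSE)
      model <- unique(rows$model)
      if (length(model) != 1)
        stop("ambiguous model for ", sp, " ", st, call. = FALSE)
      keep <- rows$parameter %in% .tpc_param_names[[model]]
      vals <- stats::setNames(rows$estimate[keep], rows$parameter[keep])
      stages[[st]] <- tpc_params(model, vals)
    }
    out[[sp]] <- species_model(sp, stages$egg, stages$larva, stages$pupa,
                               cv = cv)
  }
  out
}

#' Read / write development-rate observation tables
#'
#' Plain CSV with header
#' \code{species,stage,study_id,temperature_C,mean_dev_time_days}, one row
#' per study x temperature x stage. The reader validates ranges and adds
#' the derived \code{rate} column.
#'
#' @param file path.
#' @param obs observations data frame (the \code{rate} column, if present,
#'   is not written -- it is derived).
#' @return \code{read_observations}: validated data frame;
#'   \code{write_observations}: \code{file}, invisibly.
#' @export
read_observations <- function(file) {
  if (!file.exists(file))
    stop("observations file not found: ", file, call. = FALSE)
  validate_observations(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, file) {
  obs <- validate_observations(obs)
  cols <- c("species", "stage", "study_id", "temperature_C",
            "mean_dev_time_days")
  utils::write.csv(obs[, cols], file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

## Atlas exports spell scenarios in several ways; normalise to a fixed set
.normalise_scenario <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  map <- c(historical = "historical", ssp126 = "ssp126", ssp585 = "ssp585")
  out <- unname(map[key])
  if (anyNA(out))
    stop("unrecognised scenario label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Read / write monthly temperature ensemble tables
#'
#' Plain CSV with header \code{region,scenario,gcm,year,month,tas_C}, one
#' row per GCM x year x month. This is the adapter target for regional
#' monthly near-surface temperature aggregates such as the IPCC WGI
#' Interactive Atlas exports; scenario spellings like \code{"SSP1-2.6"}
#' are normalised to \code{historical}/\code{ssp126}/\code{ssp585} on
#' read.
#'
#' @param file path.
#' @param records ensemble data frame.
#' @return \code{read_ensemble}: validated data frame;
#'   \code{write_ensemble}: \code{file}, invisibly.
#' @export
read_ensemble <- function(file) {
  if (!file.exists(file))
    stop("ensemble file not found: ", file, call. = FALSE)
  rec <- utils::read.csv(file, stringsAsFactors = FALSE)
  rec <- validate_ensemble(rec)
  rec$scenario <- .normalise_scenario(rec$scenario)
  rec
}

#' @rdname read_ensemble
#' @export
write_ensemble <- function(records, file) {
  records <- validate_ensemble(records)
  cols <- c("region", "scenario", "gcm", "year", "month", "tas_C")
  utils::write.csv(records[, cols], file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' End-to-end runs writing result tables and a run manifest
#'
#' Thin orchestrators over the package functions for scripted use.
#' \code{run_thermal_window} simulates the thermal window for the chosen
#' species; \code{run_impact} computes the monthly r/rmax impact records
#' and their ensemble summary from an ensemble file or data frame. Both
#' write their result tables plus a \code{manifest.csv} recording the
#' resolved configuration and seed, so a rerun with the same inputs is
#' reproducible byte for byte.
#'
#' @param species species key, one of \code{names(stemborer_models())}.
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @param cv,n_individuals,deadline_days simulation overrides.
#' @param grid_step coarse scan step for the window search, degrees C.
#' @return \code{run_thermal_window}: the \code{thermal_window} record;
#'   \code{run_impact}: list with \code{impacts} and \code{summary}.
#' @export
run_thermal_window <- function(species, out_dir, seed = 1L, cv = 0.15,
                               n_individuals = 5000L, deadline_days = 182,
                               grid_step = 0.5) {
  models <- stemborer_models(cv = cv)
  if (!species %in% names(models))
    stop("unknown species '", species, "'; available: ",
         paste(names(models), collapse = ", "), call. = FALSE)
  settings <- sim_settings(n_individuals, deadline_days, seed)
  win <- thermal_window(models[[species]], settings, scan_step = grid_step)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(species = species, T50min = win$T50min,
                              T50max = win$T50max,
                              deadline_days = deadline_days),
                   file.path(out_dir, "thermal_window.csv"),
                   row.names = FALSE, quote = FALSE)
  .write_manifest(out_dir, list(command = "window", species = species,
                                seed = seed, cv = cv,
                                n_individuals = n_individuals,
                                deadline_days = deadline_days,
                                grid_step = grid_step))
  win
}

#' @rdname run_thermal_window
#' @param ensemble ensemble file path or data frame.
#' @param scenario future scenario label.
#' @param current,future \code{\link{period_spec}} objects.
#' @export
run_impact <- function(species, ensemble, scenario, out_dir, cv = 0.15,
                       current = period_spec("current"),
                       future = period_spec("future")) {
  models <- stemborer_models(cv = cv)
  if (!species %in% names(models))
    stop("unknown species '", species, "'; available: ",
         paste(names(models), collapse = ", "), call. = FALSE)
  rec <- if (is.character(ensemble)) read_ensemble(ensemble)
         else validate_ensemble(ensemble)
  imp <- impact_assessment(models[[species]], rec, scenario,
                           current = current, future = future)
  summ <- ensemble_summary(imp)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(imp, file.path(out_dir, "impact_records.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(summ, file.path(out_dir, "impact_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  .write_manifest(out_dir, list(command = "impact", species = species,
                                scenario = scenario,
                                current = paste(current$year_start,
                                                current$year_end, sep = ":"),
                                future = paste(future$year_start,
                                               future$year_end, sep = ":")))
  list(impacts = imp, summary = summ)
}

.write_manifest <- function(out_dir, config) {
  man <- data.frame(key = names(config),
                    value = vapply(config, as.character, character(1)))
  utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(man)
}
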