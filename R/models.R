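#' Thermal performance curve (TPC) model catalogue
#'
#' Eleven nonlinear models relating insect development rate (day^-1) to
#' constant temperature (degrees Celsius). All eleven parameterise the
#' critical thermal minimum (CTmin) and maximum (CTmax) explicitly, so the
#' optimal temperature Topt can always be computed as the local maximum of
#' the curve between the two thresholds. Purely linear (degree-day) models
#' are deliberately absent: they carry no thermal limits.
#'
#' The catalogue entries are, with their free parameters (beyond CTmin and
#' CTmax, which every model carries):
#' \describe{
#'   \item{analytis_77}{\eqn{r(T) = a (T-CTmin)^b (CTmax-T)^c}}
#'   \item{ratkowsky_83}{\eqn{r(T) = [c (T-CTmin) (1 - e^{k (T-CTmax)})]^2}
#'     (square-root regression form, squared)}
#'   \item{hilbertLogan_83}{\eqn{r(T) = \phi [ (T-CTmin)^2 / ((T-CTmin)^2 + a^2)
#'     - e^{-(CTmax - (T-CTmin)) / \Delta T} ]}}
#'   \item{beta_95}{\eqn{r(T) = e^{\mu} (T-CTmin)^a (CTmax-T)^b}}
#'   \item{beta_16}{\eqn{r(T) = r_m \frac{CTmax-T}{CTmax-Topt}
#'     \left(\frac{T-CTmin}{Topt-CTmin}\right)^{(Topt-CTmin)/(CTmax-Topt)}},
#'     with Topt itself a fitted parameter constrained to (CTmin, CTmax)}
#'   \item{briere1_99}{\eqn{r(T) = a T (T-CTmin) (CTmax-T)^{1/2}}}
#'   \item{briere2_99}{\eqn{r(T) = a T (T-CTmin) (CTmax-T)^{1/b}}}
#'   \item{kontodimas_04}{\eqn{r(T) = a (T-CTmin)^2 (CTmax-T)}}
#'   \item{shi_11}{\eqn{r(T) = c (1 - e^{-k_1 (T-CTmin)}) (1 - e^{k_2 (T-CTmax)})}}
#'   \item{perf2_11}{\eqn{r(T) = c (T-CTmin) (1 - e^{k (T-CTmax)})}}
#'   \item{regniere_12}{\eqn{r(T) = \phi [ e^{b (T-CTmin)}
#'     - \frac{CTmax-T}{CTmax-CTmin} e^{-b (T-CTmin)/\Delta b}
#'     - \frac{T-CTmin}{CTmax-CTmin} e^{b (CTmax-CTmin) - (CTmax-T)/\Delta b} ]},
#'     transcribed from the original source with a single boundary-layer
#'     width \eqn{\Delta b} at both thresholds and the upper threshold
#'     identified with CTmax}
#' }
#'
#' Evaluation contract: the raw formula value is clamped to be non-negative
#' and the domain is restricted to the open interval (CTmin, CTmax) --
#' development is null at and beyond the critical thresholds, and
#' expressions that would be undefined outside the domain (e.g. the square
#' root in the Briere forms) return exactly 0 there.
#'
#' @return \code{tpc_model_specs()} returns a named list of model
#'   specifications; each has elements \code{name},
#'   \code{parameter_names} (ordered; always includes CTmin and CTmax) and
#'   \code{has_closed_form_topt}.
#' @examples
#' names(tpc_model_specs())
#' tpc_model_specs()[["briere1_99"]]$parameter_names
#' @export
tpc_model_specs <- function() {
  .tpc_catalogue
}

## raw formula bodies, evaluated only strictly inside (CTmin, CTmax)
.tpc_raw <- list(
  analytis_77 = function(p, T)
    p[["a"]] * (T - p[["CTmin"]])^p[["b"]] * (p[["CTmax"]] - T)^p[["c"]],
  ratkowsky_83 = function(p, T)
    (p[["c"]] * (T - p[["CTmin"]]) * (1 - exp(p[["k"]] * (T - p[["CTmax"]]))))^2,
  hilbertLogan_83 = function(p, T) {
    x <- T - p[["CTmin"]]
    p[["phi"]] * (x^2 / (x^2 + p[["a"]]^2) -
                  exp(-(p[["CTmax"]] - x) / p[["deltaT"]]))
  },
  beta_95 = function(p, T)
    exp(p[["mu"]]) * (T - p[["CTmin"]])^p[["a"]] * (p[["CTmax"]] - T)^p[["b"]],
  beta_16 = function(p, T) {
    ex <- (p[["Topt"]] - p[["CTmin"]]) / (p[["CTmax"]] - p[["Topt"]])
    p[["rm"]] * (p[["CTmax"]] - T) / (p[["CTmax"]] - p[["Topt"]]) *
      ((T - p[["CTmin"]]) / (p[["Topt"]] - p[["CTmin"]]))^ex
  },
  briere1_99 = function(p, T)
    p[["a"]] * T * (T - p[["CTmin"]]) * sqrt(p[["CTmax"]] - T),
  briere2_99 = function(p, T)
    p[["a"]] * T * (T - p[["CTmin"]]) * (p[["CTmax"]] - T)^(1 / p[["b"]]),
  kontodimas_04 = function(p, T)
    p[["a"]] * (T - p[["CTmin"]])^2 * (p[["CTmax"]] - T),
  shi_11 = function(p, T)
    p[["c"]] * (1 - exp(-p[["k1"]] * (T - p[["CTmin"]]))) *
      (1 - exp(p[["k2"]] * (T - p[["CTmax"]]))),
  perf2_11 = function(p, T)
    p[["c"]] * (T - p[["CTmin"]]) * (1 - exp(p[["k"]] * (T - p[["CTmax"]]))),
  regniere_12 = function(p, T) {
    w <- p[["CTmax"]] - p[["CTmin"]]
    p[["phi"]] * (exp(p[["b"]] * (T - p[["CTmin"]])) -
      (p[["CTmax"]] - T) / w * exp(-p[["b"]] * (T - p[["CTmin"]]) / p[["deltab"]]) -
      (T - p[["CTmin"]]) / w *
        exp(p[["b"]] * w - (p[["CTmax"]] - T) / p[["deltab"]]))
  }
)

.tpc_param_names <- list(
  analytis_77     = c("a", "b", "c", "CTmin", "CTmax"),
  ratkowsky_83    = c("c", "k", "CTmin", "CTmax"),
  hilbertLogan_83 = c("phi", "a", "deltaT", "CTmin", "CTmax"),
  beta_95         = c("mu", "a", "b", "CTmin", "CTmax"),
  beta_16         = c("rm", "Topt", "CTmin", "CTmax"),
  briere1_99      = c("a", "CTmin", "CTmax"),
  briere2_99      = c("a", "b", "CTmin", "CTmax"),
  kontodimas_04   = c("a", "CTmin", "CTmax"),
  shi_11          = c("c", "k1", "k2", "CTmin", "CTmax"),
  perf2_11        = c("c", "k", "CTmin", "CTmax"),
  regniere_12     = c("phi", "b", "deltab", "CTmin", "CTmax")
)

.tpc_catalogue <- local({
  closed <- c("briere1_99", "kontodimas_04")
  specs <- lapply(names(.tpc_param_names), function(nm) {
    structure(list(name = nm,
                   parameter_names = .tpc_param_names[[nm]],
                   has_closed_form_topt = nm %in% closed),
              class = "tpc_model_spec")
  })
  names(specs) <- names(.tpc_param_names)
  specs
})

#' Construct a TPC parameter set
#'
#' Bundles a model name from the catalogue with named parameter values.
#' Temperatures are degrees Celsius, rates day^-1.
#'
#' @param model model name, one of \code{names(tpc_model_specs())}.
#' @param values named numeric vector or list of parameter values; the names
#'   must be exactly the model's \code{parameter_names}.
#' @return an object of class \code{tpc_params}.
#' @examples
#' p <- tpc_params("kontodimas_04", c(a = 4.7e-5, CTmin = 10.4, CTmax = 42.3))
#' tpc_rate(p, 25)
#' @export
tpc_params <- function(model, values) {
  if (!model %in% names(.tpc_catalogue))
    stop("unknown TPC model '", model, "'; see names(tpc_model_specs())",
         call. = FALSE)
  values <- unlist(values)
  wanted <- .tpc_param_names[[model]]
  if (!setequal(names(values), wanted))
    stop("model '", model, "' needs parameters {",
         paste(wanted, collapse = ", "), "}, got {",
         paste(names(values), collapse = ", "), "}", call. = FALSE)
  values <- values[wanted]
  if (any(!is.finite(values)))
    stop("non-finite parameter value in TPC parameter set", call. = FALSE)
  if (values[["CTmin"]] >= values[["CTmax"]])
    stop("CTmin must be strictly below CTmax", call. = FALSE)
  if (model == "beta_16" &&
      (values[["Topt"]] <= values[["CTmin"]] ||
       values[["Topt"]] >= values[["CTmax"]]))
    stop("beta_16 requires CTmin < Topt < CTmax", call. = FALSE)
  structure(list(model = model, values = values), class = "tpc_params")
}

#' @export
print.tpc_params <- function(x, ...) {
  cat("TPC parameter set:", x$model, "\n")
  print(x$values)
  invisible(x)
}

#' Evaluate a thermal performance curve
#'
#' Development rate at temperature \code{temp}. Rates are clamped to be
#' non-negative and are exactly 0 at and outside the (CTmin, CTmax)
#' interval, where development is null.
#'
#' @param params a \code{\link{tpc_params}} object.
#' @param temp numeric vector of temperatures (degrees Celsius).
#' @return numeric vector of development rates (day^-1), same length as
#'   \code{temp}.
#' @examples
#' larva <- tpc_params("briere1_99", c(a = 3.3e-5, CTmin = 13.5, CTmax = 37.1))
#' tpc_rate(larva, c(10, 25, 40))
#' @export
tpc_rate <- function(params, temp) {
  stopifnot(inherits(params, "tpc_params"))
  p <- params$values
  r <- numeric(length(temp))
  inside <- temp > p[["CTmin"]] & temp < p[["CTmax"]]
  if (any(inside))
    r[inside] <- pmax(0, .tpc_raw[[params$model]](p, temp[inside]))
  r[!is.finite(r)] <- 0
  r
}

#' Thermal traits of a parameter set
#'
#' CTmin and CTmax are read off the parameters; the optimal temperature
#' Topt is located as the local maximum of the curve on [CTmin, CTmax] by
#' golden-section search (tolerance 1e-4 degrees C), seeded from a 0.001
#' degree grid scan so that the global maximum is found even if the curve
#' is not perfectly unimodal.
#'
#' @param params a \code{\link{tpc_params}} object.
#' @return list with numeric elements \code{CTmin}, \code{Topt},
#'   \code{CTmax} (degrees C) and \code{rate_at_topt} (day^-1).
#' @examples
#' egg <- tpc_params("kontodimas_04", c(a = 4.7e-5, CTmin = 10.4, CTmax = 42.3))
#' tpc_traits(egg)$Topt  # equals (2*CTmax + CTmin) / 3
#' @export
tpc_traits <- function(params) {
  stopifnot(inherits(params, "tpc_params"))
  lo <- params$values[["CTmin"]]
  hi <- params$values[["CTmax"]]
  grid <- seq(lo, hi, by = 0.001)
  rg <- tpc_rate(params, grid)
  if (all(rg <= 0))
    stop("degenerate curve: rate is zero throughout [CTmin, CTmax]",
         call. = FALSE)
  i <- which.max(rg)  # which.max takes the first (lowest-T) maximiser on ties
  a <- grid[max(1L, i - 2L)]
  b <- grid[min(length(grid), i + 2L)]
  opt <- stats::optimize(function(T) tpc_rate(params, T),
                         interval = c(a, b), maximum = TRUE, tol = 1e-5)
  topt <- opt$maximum
  if (opt$objective < rg[i]) topt <- grid[i]  # grid wins on pathologies
  list(CTmin = lo, Topt = topt, CTmax = hi,
       rate_at_topt = max(opt$objective, rg[i]))
}
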