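# Atmospheric properties of habitat records: humid-air density from the
# Dalton partial-pressure decomposition, dynamic viscosity from Sutherland's
# law, and the construction of the CFD field-domain condition sets. The
# aerodynamic simulations themselves are outside this package.

#' Atmospheric constants
#'
#' Gas constants for dry air and water vapour, the Sutherland temperature,
#' and the viscosity reference point (standard air at 273.15 K).
#'
#' @param Rg_d dry-air gas constant, J/(kg K).
#' @param Rg_v water-vapour gas constant, J/(kg K).
#' @param S Sutherland temperature, K.
#' @param mu_ref reference viscosity, Pa s.
#' @param T_ref reference temperature for `mu_ref`, K.
#' @return named list of constants.
#' @export
atmospheric_constants <- function(Rg_d = 287.1, Rg_v = 461.5, S = 110.4,
                                  mu_ref = 1.716e-5, T_ref = 273.15) {
  stopifnot(Rg_d > 0, Rg_v > 0, S > 0, mu_ref > 0, T_ref > 0)
  list(Rg_d = Rg_d, Rg_v = Rg_v, S = S, mu_ref = mu_ref, T_ref = T_ref)
}

#' Humid-air density (Dalton's law of partial pressures)
#'
#' `rho = (P - Pv) / (Rg_d T) + Pv / (Rg_v T)`: the dry-air and water-vapour
#' partial densities added. At `Pv = 0` this reduces exactly to the dry-air
#' ideal gas law; at fixed P and T, density strictly decreases with
#' moisture content (Rg_v > Rg_d).
#'
#' @param P atmospheric pressure, Pa.
#' @param Pv water-vapour partial pressure, Pa (0 <= Pv < P).
#' @param T_k absolute temperature, K (> 0).
#' @param const constants from [atmospheric_constants()].
#' @return density in kg/m^3.
#' @export
air_density <- function(P, Pv, T_k, const = atmospheric_constants()) {
  if (any(T_k <= 0)) stop("temperature must be positive (K)")
  if (any(Pv < 0) || any(Pv >= P)) stop("need 0 <= Pv < P")
  (P - Pv) / (const$Rg_d * T_k) + Pv / (const$Rg_v * T_k)
}

#' Dynamic viscosity of air (Sutherland's law)
#'
#' `mu = mu_ref (T/T_ref)^{3/2} (T_ref + S) / (T + S)`; equals `mu_ref`
#' exactly at `T = T_ref` and increases monotonically with temperature.
#'
#' @param T_k absolute temperature, K (> 0).
#' @param const constants from [atmospheric_constants()].
#' @return viscosity in Pa s.
#' @export
air_viscosity <- function(T_k, const = atmospheric_constants()) {
  if (any(T_k <= 0)) stop("temperature must be positive (K)")
  const$mu_ref * (T_k / const$T_ref)^1.5 *
    (const$T_ref + const$S) / (T_k + const$S)
}

#' Unit helpers
#' @param x value(s) to convert.
#' @return converted value(s).
#' @name units
NULL

#' @rdname units
#' @export
hpa_to_pa <- function(x) x * 100
#' @rdname units
#' @export
pa_to_hpa <- function(x) x / 100
#' @rdname units
#' @export
celsius_to_kelvin <- function(x) x + 273.15
#' @rdname units
#' @export
kelvin_to_celsius <- function(x) x - 273.15

#' CFD field-domain condition sets from habitat records
#'
#' From a collection of per-record atmospheric variables (derived density
#' and viscosity included), builds the six transient sets - each takes one
#' of \{airflow velocity v, density rho, viscosity mu\} at its extreme
#' (max or min over the records) with the other two at their means - and the
#' one steady set (mean v, mean mu, minimum rho: a relatively adverse
#' circumstance). Optionally, per-wing-shape temperature variants use the
#' median habitat MAT of each shape group.
#'
#' @param records data.frame with columns `P`, `Pv`, `T` (K), `v` (m/s);
#'   `rho`/`mu` are derived if absent.
#' @param hmat_by_shape optional named list of per-shape habitat MAT value
#'   vectors (degrees C), e.g. `list(oval = ..., falcate = ...)`.
#' @param const constants from [atmospheric_constants()].
#' @return a `field_conditions` list: `transient` (6-row data.frame),
#'   `steady` (1-row), `summary` (min/mean/max per variable),
#'   `temperature_variants` (median H-MAT per shape, if given).
#' @export
field_condition_sets <- function(records, hmat_by_shape = NULL,
                                 const = atmospheric_constants()) {
  if (!nrow(records)) stop("no atmospheric records supplied")
  if (is.null(records$rho))
    records$rho <- air_density(records$P, records$Pv, records$T, const)
  if (is.null(records$mu)) records$mu <- air_viscosity(records$T, const)
  vars <- c("v", "rho", "mu")
  stats_tab <- sapply(vars, function(v)
    c(min = min(records[[v]]), mean = mean(records[[v]]),
      max = max(records[[v]])))
  sets <- list()
  for (v in vars) for (ex in c("max", "min")) {
    row <- stats_tab["mean", ]
    row[v] <- stats_tab[ex, v]
    sets[[paste0(v, "_", ex)]] <- row
  }
  transient <- as.data.frame(do.call(rbind, sets))
  transient$set <- names(sets)
  transient <- transient[, c("set", vars)]
  steady <- data.frame(set = "steady", v = stats_tab["mean", "v"],
                       rho = stats_tab["min", "rho"],
                       mu = stats_tab["mean", "mu"])
  tv <- NULL
  if (!is.null(hmat_by_shape))
    tv <- vapply(hmat_by_shape, stats::median, numeric(1))
  structure(list(transient = transient, steady = steady,
                 summary = stats_tab, temperature_variants = tv),
            class = "field_conditions")
}
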