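#' Treatment-level light-curve parameters shipped with the package
#'
#' Mean Jassby-Platt parameters (with standard errors, n = 5 replicate
#' tanks) per scenario (ambient / future), water flow (0.5 / 1.4 L min-1)
#' and response variable, from the flow-through kelp experiment the
#' predictive model is built on. `pmax` is in response delta-units
#' (umol L-1 for DO/DIC, pH units or dimensionless for pH/Omega), `alpha`
#' in the same units per umol photons m-2 s-1, `ek` in
#' umol photons m-2 s-1. For the pH and Omega rows the published slope is
#' rounded to zero at two decimals, so `alpha` is reconstructed as
#' `pmax/ek`.
#'
#' @return data.frame with columns `scenario`, `flow_L_min`, `variable`,
#'   `pmax`, `pmax_se`, `alpha`, `alpha_se`, `ek`, `ek_se`, `n`.
#' @examples
#' head(default_treatment_fits())
#' @export
default_treatment_fits <- function() {
  path <- system.file("extdata", "treatment_fits.csv", package = "phycarb",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Predictive model of macrophyte amelioration capacity
#'
#' Builds the per-biomass-density predictor of seawater-chemistry change:
#' the treatment-mean Jassby-Platt curves are evaluated at the two fitted
#' flow endpoints, each tank-level rate is divided by the tank biomass
#' density (biomass_fw / volume), and intermediate flows are obtained by
#' point-wise linear interpolation between the endpoint curves.
#'
#' @param fits treatment parameter table as returned by
#'   [default_treatment_fits()] or the `summary` element of
#'   [fit_tank_curves()] (columns `scenario`, `flow_L_min`, `variable`,
#'   `pmax`, `alpha`).
#' @param biomass_fw fresh-weight biomass per tank used in the fits, g.
#' @param volume_L tank volume, L.
#' @return Object of class `amelioration_model`.
#' @examples
#' m <- amelioration_model()
#' predict(m, irradiance = 250, flow = 0.5, scenario = "future",
#'         variable = "dic")
#' @seealso [per_density_rate()], [predict_bulk_change()],
#'   [apply_to_background()], [amelioration_threshold()], [surface_grid()]
#' @export
amelioration_model <- function(fits = default_treatment_fits(),
                               biomass_fw = 150, volume_L = 30) {
  req <- c("scenario", "flow_L_min", "variable", "pmax", "alpha")
  if (!all(req %in% names(fits)))
    stop("`fits` must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (biomass_fw <= 0 || volume_L <= 0)
    stop("`biomass_fw` and `volume_L` must be positive", call. = FALSE)
  for (sc in unique(fits$scenario)) for (v in unique(fits$variable)) {
    fl <- fits$flow_L_min[fits$scenario == sc & fits$variable == v]
    if (length(fl) && length(unique(fl)) < 2)
      stop("need both flow endpoints for ", sc, "/", v, call. = FALSE)
  }
  out <- list(fits = fits, biomass_fw = biomass_fw, volume_L = volume_L,
              flow_range = range(fits$flow_L_min))
  class(out) <- "amelioration_model"
  out
}

.model_row <- function(model, flow, scenario, variable) {
  i <- model$fits$scenario == scenario & model$fits$variable == variable &
    model$fits$flow_L_min == flow
  if (!any(i))
    stop("no fitted parameters for ", scenario, "/", variable, " at flow ",
         flow, call. = FALSE)
  model$fits[which(i)[1], ]
}

#' Per-biomass-density amelioration rate
#'
#' Predicted change of the response per gram fresh weight per litre of
#' water at irradiance `E` and water flow `flow`, by evaluating the
#' treatment-mean light curve at each fitted flow endpoint (divided by the
#' tank biomass density) and interpolating linearly in flow. At an
#' endpoint flow the prediction equals that endpoint's curve exactly.
#'
#' @param model an [amelioration_model()].
#' @param E irradiance, umol photons m-2 s-1, >= 0 (vectorized).
#' @param flow water flow, L min-1. Values outside the fitted range are
#'   clamped with a warning, or rejected when `strict = TRUE`.
#' @param scenario `"ambient"` or `"future"`.
#' @param variable `"do"` or `"dic"` (the directly modelled responses);
#'   `"ph"`/`"omega"` curves are available for descriptive use.
#' @param strict error instead of clamping out-of-range flows.
#' @return Rate in umol L-1 per (g FW L-1) (delta-units per g/L for
#'   pH/Omega).
#' @export
per_density_rate <- function(model, E, flow, scenario, variable = "dic",
                             strict = FALSE) {
  stopifnot(inherits(model, "amelioration_model"))
  if (any(E < 0)) stop("`E` must be non-negative", call. = FALSE)
  fr <- model$flow_range
  if (flow < fr[1] || flow > fr[2]) {
    if (strict)
      stop("flow ", flow, " outside fitted range [", fr[1], ", ", fr[2],
           "] L/min", call. = FALSE)
    warning("flow ", flow, " outside fitted range [", fr[1], ", ", fr[2],
            "]; clamped (extrapolation)", call. = FALSE)
    flow <- min(max(flow, fr[1]), fr[2])
  }
  density <- model$biomass_fw / model$volume_L   # g FW per L
  lo <- .model_row(model, fr[1], scenario, variable)
  hi <- .model_row(model, fr[2], scenario, variable)
  r_lo <- jassby_platt(E, lo$pmax, lo$alpha) / density
  r_hi <- jassby_platt(E, hi$pmax, hi$alpha) / density
  w <- (flow - fr[1]) / (fr[2] - fr[1])
  (1 - w) * r_lo + w * r_hi
}

#' Scale a per-density rate to a bulk water-body change
#'
#' Multiplies the per-biomass-density rate by the standing-stock biomass
#' density of the water body. `rate` in umol L-1 per (g FW L-1),
#' `biomass_fw` in grams fresh weight, `volume_L` in litres; e.g. 5,000 kg
#' FW in 1000 m3 is `biomass_fw = 5e6`, `volume_L = 1e6` (5 g FW/L).
#'
#' @param rate per-density rate (see [per_density_rate()]).
#' @param biomass_fw standing-stock fresh weight, g, >= 0.
#' @param volume_L water volume, L, > 0.
#' @return Bulk change, umol L-1.
#' @examples
#' predict_bulk_change(4.5, biomass_fw = 5e6, volume_L = 1e6)  # 22.5
#' @export
predict_bulk_change <- function(rate, biomass_fw, volume_L) {
  if (any(biomass_fw < 0)) stop("`biomass_fw` must be >= 0", call. = FALSE)
  if (any(volume_L <= 0)) stop("`volume_L` must be positive", call. = FALSE)
  rate * (biomass_fw / volume_L)
}

#' Translate a bulk DIC drawdown into pH and saturation-state change
#'
#' Converts a volumetric DIC removal (umol L-1) to gravimetric units with
#' the fixed 1.024 kg/L factor, subtracts it from the background DIC at
#' constant total alkalinity (photosynthetic DIC removal does not change
#' TA), and solves both states with [carb_from_dic_ta()].
#'
#' @param bulk_ddic DIC removed, umol L-1 (positive = removal).
#' @param DIC,TA background state, umol kg-1.
#' @param temperature,salinity background conditions.
#' @return list with `before` and `after` (`carbsys` rows), `pH_before`,
#'   `pH_after`, `d_ph` and `d_omega`.
#' @examples
#' apply_to_background(22.5, DIC = 2200, TA = 2100,
#'                     temperature = 11, salinity = 30)
#' @export
apply_to_background <- function(bulk_ddic, DIC, TA, temperature, salinity) {
  before <- carb_from_dic_ta(DIC, TA, temperature, salinity)
  after <- carb_from_dic_ta(DIC - umol_l_to_kg(bulk_ddic), TA,
                            temperature, salinity)
  list(before = before, after = after,
       pH_before = before$pH_total, pH_after = after$pH_total,
       d_ph = after$pH_total - before$pH_total,
       d_omega = after$omega_ar - before$omega_ar)
}

#' Fresh-weight / dry-weight biomass conversion
#'
#' Empirical linear conversion for kelp biomass,
#' `DW = 0.1187 * FW - 0.0086` (grams), floored at zero; `dw_to_fw()` is
#' the inverse above the floor.
#'
#' @param fw,dw biomass, g.
#' @return Converted biomass, g.
#' @examples
#' fw_to_dw(100)   # 11.8614 g DW
#' @export
fw_to_dw <- function(fw) {
  if (any(fw < 0)) stop("`fw` must be >= 0", call. = FALSE)
  pmax(0.1187 * fw - 0.0086, 0)
}

#' @rdname fw_to_dw
#' @export
dw_to_fw <- function(dw) {
  if (any(dw < 0)) stop("`dw` must be >= 0", call. = FALSE)
  (dw + 0.0086) / 0.1187
}

#' Irradiance threshold for net amelioration
#'
#' Smallest irradiance at which the net light response (gross Jassby-Platt
#' rate minus a dark respiration offset) becomes non-negative, located by
#' bisection to 1e-3 umol photons m-2 s-1. With no dark offset the model
#' passes through the origin and the threshold is zero.
#'
#' @param model an [amelioration_model()].
#' @param flow,scenario,variable treatment selectors (see
#'   [per_density_rate()]).
#' @param dark_offset dark respiration rate in tank delta-units (umol L-1),
#'   `0 <= dark_offset <` interpolated `pmax`.
#' @return Threshold irradiance E*, umol photons m-2 s-1.
#' @export
amelioration_threshold <- function(model, flow, scenario, variable = "dic",
                                   dark_offset = 0) {
  stopifnot(inherits(model, "amelioration_model"))
  if (dark_offset < 0) stop("`dark_offset` must be >= 0", call. = FALSE)
  if (dark_offset == 0) return(0)
  fr <- model$flow_range
  lo <- .model_row(model, fr[1], scenario, variable)
  hi <- .model_row(model, fr[2], scenario, variable)
  w <- (min(max(flow, fr[1]), fr[2]) - fr[1]) / (fr[2] - fr[1])
  tank_rate <- function(E)
    (1 - w) * jassby_platt(E, lo$pmax, lo$alpha) +
    w * jassby_platt(E, hi$pmax, hi$alpha)
  p_sup <- (1 - w) * lo$pmax + w * hi$pmax
  if (dark_offset >= p_sup)
    stop("dark offset >= interpolated Pmax: net rate never positive",
         call. = FALSE)
  eu <- max(lo$ek, hi$ek, lo$pmax / lo$alpha, hi$pmax / hi$alpha) * 50
  a <- 0; b <- eu
  while (b - a > 1e-3) {
    m <- (a + b) / 2
    if (tank_rate(m) - dark_offset >= 0) b <- m else a <- m
  }
  (a + b) / 2
}

#' Dense rate surface over irradiance and flow
#'
#' Evaluates [per_density_rate()] on a grid for export or plotting.
#'
#' @param model an [amelioration_model()].
#' @param scenario,variable treatment selectors.
#' @param E_grid,flow_grid numeric grids (flows within the fitted range).
#' @return data.frame with columns `irradiance`, `flow_L_min`, `rate`.
#' @export
surface_grid <- function(model, scenario, variable = "dic",
                         E_grid = seq(0, 260, by = 5),
                         flow_grid = seq(model$flow_range[1],
                                         model$flow_range[2],
                                         length.out = 20)) {
  g <- expand.grid(irradiance = E_grid, flow_L_min = flow_grid,
                   KEEP.OUT.ATTRS = FALSE)
  g$rate <- unlist(lapply(flow_grid, function(f)
    per_density_rate(model, E_grid, f, scenario, variable)))
  g
}

#' Residence time of a tank at a given flow
#'
#' Labelled conversion `volume / flow` in minutes (e.g. 60 min at
#' 0.5 L min-1 in 30 L). Provided for reporting; the model interpolates in
#' flow, not residence time.
#'
#' @param flow water flow, L min-1, > 0.
#' @param volume_L tank volume, L.
#' @return Residence time, minutes.
#' @export
residence_time <- function(flow, volume_L = 30) {
  if (any(flow <= 0)) stop("`flow` must be positive", call. = FALSE)
  volume_L / flow
}

#' @export
print.amelioration_model <- function(x, ...) {
  cat("Macrophyte amelioration model (flow-interpolated light curves)\n")
  cat(sprintf("  tank biomass %.4g g FW in %.4g L (density %.3g g/L)\n",
              x$biomass_fw, x$volume_L, x$biomass_fw / x$volume_L))
  cat(sprintf("  flow range [%.3g, %.3g] L/min; variables: %s\n",
              x$flow_range[1], x$flow_range[2],
              paste(unique(x$fits$variable), collapse = ", ")))
  invisible(x)
}

#' @export
predict.amelioration_model <- function(object, irradiance, flow,
                                       scenario = c("ambient", "future"),
                                       variable = "dic",
                                       biomass_fw = NULL, volume_L = NULL,
                                       background = NULL, ...) {
  scenario <- match.arg(scenario)
  rate <- per_density_rate(object, irradiance, flow, scenario, variable)
  out <- data.frame(scenario = scenario, flow_L_min = flow,
                    irradiance = irradiance, variable = variable,
                    per_density_rate = rate)
  if (!is.null(biomass_fw) && !is.null(volume_L)) {
    out$bulk_delta <- predict_bulk_change(rate, biomass_fw, volume_L)
    if (!is.null(background)) {
      stopifnot(variable == "dic")
      bg <- lapply(out$bulk_delta, function(dd)
        apply_to_background(dd, background$DIC, background$TA,
                            background$temperature, background$salinity))
      out$pH_before <- vapply(bg, `[[`, numeric(1), "pH_before")
      out$pH_after <- vapply(bg, `[[`, numeric(1), "pH_after")
      out$d_omega <- vapply(bg, `[[`, numeric(1), "d_omega")
    }
  }
  out
}

#' @export
plot.amelioration_model <- function(x, scenario = "future",
                                    variable = "dic", ...) {
  g <- surface_grid(x, scenario, variable)
  E <- sort(unique(g$irradiance)); fl <- sort(unique(g$flow_L_min))
  z <- matrix(g$rate[order(g$flow_L_min, g$irradiance)],
              nrow = length(E), ncol = length(fl))
  graphics::filled.contour(
    E, fl, z,
    xlab = "Irradiance (umol photons m-2 s-1)", ylab = "Flow (L min-1)",
    main = sprintf("%s, %s: delta per g FW per L", scenario, variable), ...)
  invisible(x)
}
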