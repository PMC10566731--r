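# Grams of seawater per litre used for volumetric <-> gravimetric conversion.
# A fixed factor (not a full equation of state) so that field predictions in
# umol/L map onto the gravimetric carbonate solver reproducibly.
.SW_KG_PER_L <- 1.024

# Core alkalinity bookkeeping at a given total-scale [H+].
# All concentrations mol/kg. Returns the non-carbonate alkalinity terms and
# the speciation denominators needed by both solver directions.
.alk_terms <- function(H, k) {
  Hfree <- H / (1 + k$ST / k$KS)
  KFfree <- k$KF / (1 + k$ST / k$KS)   # Perez & Fraga KF is total scale
  list(
    Hfree = Hfree,
    boh4 = k$BT * k$KB / (k$KB + H),
    oh = k$KW / H,
    hso4 = k$ST * Hfree / (Hfree + k$KS),
    hf = k$FT * Hfree / (Hfree + KFfree)
  )
}

# pH + TA -> full system, vectorized, no validation. TA mol/kg.
# Returns list of mol/kg quantities; carbonate alkalinity `ca` may be <= 0
# for infeasible inputs (caller decides whether to error or exclude).
.carb_ph_ta <- function(pH, TA, k) {
  H <- 10^(-pH)
  a <- .alk_terms(H, k)
  ca <- TA - a$boh4 - a$oh + a$Hfree + a$hso4 + a$hf
  denom <- H^2 + k$K1 * H + k$K1 * k$K2
  dic <- ca * denom / (k$K1 * (H + 2 * k$K2))
  list(
    H = H, ca = ca, dic = dic,
    co2 = dic * H^2 / denom,
    hco3 = dic * k$K1 * H / denom,
    co3 = dic * k$K1 * k$K2 / denom
  )
}

# TA implied by (pH, DIC), mol/kg. Monotone increasing in pH.
.ta_from_ph_dic <- function(pH, DIC, k) {
  H <- 10^(-pH)
  a <- .alk_terms(H, k)
  denom <- H^2 + k$K1 * H + k$K1 * k$K2
  DIC * k$K1 * (H + 2 * k$K2) / denom + a$boh4 + a$oh -
    a$Hfree - a$hso4 - a$hf
}

.carbsys_frame <- function(pH, TA_mol, sp, k) {
  pco2 <- sp$co2 / k$K0 * 1e6
  omega <- k$Ca * sp$co3 / k$KspAr
  out <- data.frame(
    pH_total = pH,
    TA_umol_kg = TA_mol * 1e6,
    DIC_umol_kg = sp$dic * 1e6,
    pCO2_uatm = pco2,
    co2_umol_kg = sp$co2 * 1e6,
    hco3_umol_kg = sp$hco3 * 1e6,
    co3_umol_kg = sp$co3 * 1e6,
    omega_ar = omega,
    temp_C = k$temperature,
    sal = k$salinity
  )
  class(out) <- c("carbsys", "data.frame")
  out
}

#' Solve the seawater CO2 system from pH and total alkalinity
#'
#' Direct algebraic solution on the total pH scale at surface pressure.
#' Carbonate alkalinity is obtained by subtracting the borate, hydroxide,
#' free-proton, bisulfate and fluoride contributions from total alkalinity
#' (phosphate, silicate and ammonia terms are not modelled); DIC speciation
#' then follows from \[H+\] and the carbonic-acid constants, pCO2 from the
#' solubility constant, and the aragonite saturation state from
#' \eqn{\Omega = [Ca][CO3]/Ksp}.
#'
#' @param pH total-scale pH, in \[3, 12\].
#' @param TA total alkalinity, umol kg-1, in (0, 5000\].
#' @param temperature,salinity seawater conditions (see [carb_constants()]).
#' @return A data.frame of class `carbsys` with one row per input state and
#'   columns `pH_total`, `TA_umol_kg`, `DIC_umol_kg`, `pCO2_uatm`,
#'   `co2_umol_kg`, `hco3_umol_kg`, `co3_umol_kg`, `omega_ar`, `temp_C`,
#'   `sal`.
#' @examples
#' carb_from_ph_ta(8.1, 2300, temperature = 25, salinity = 35)
#' @seealso [carb_from_dic_ta()], [speciate()], [propagate_uncertainty()]
#' @export
carb_from_ph_ta <- function(pH, TA, temperature, salinity) {
  if (any(!is.finite(pH)) || any(pH < 3 | pH > 12))
    stop("`pH` must lie in [3, 12] (total scale)", call. = FALSE)
  if (any(!is.finite(TA)) || any(TA <= 0 | TA > 5000))
    stop("`TA` must lie in (0, 5000] umol/kg", call. = FALSE)
  k <- carb_constants(temperature, salinity)
  n <- max(length(pH), length(TA), length(k$K1))
  pH <- rep_len(pH, n); TA <- rep_len(TA, n)
  if (length(k$K1) != n) k <- carb_constants(rep_len(k$temperature, n),
                                             rep_len(k$salinity, n))
  sp <- .carb_ph_ta(pH, TA * 1e-6, k)
  if (any(sp$ca <= 0))
    stop("infeasible state: non-carbonate alkalinity exceeds TA at ",
         "pH = ", pH[which(sp$ca <= 0)[1]], call. = FALSE)
  .carbsys_frame(pH, TA * 1e-6, sp, k)
}

#' Solve the seawater CO2 system from DIC and total alkalinity
#'
#' Finds the total-scale pH whose implied alkalinity at the given DIC matches
#' the measured TA, by safeguarded bracketed root-finding on pH in \[3, 12\]
#' (tolerance 1e-10 pH units), then completes the state as
#' [carb_from_ph_ta()].
#'
#' @param DIC dissolved inorganic carbon, umol kg-1, in (0, 5000\].
#' @param TA total alkalinity, umol kg-1, in (0, 5000\].
#' @inheritParams carb_from_ph_ta
#' @return A `carbsys` data.frame (see [carb_from_ph_ta()]).
#' @examples
#' # the low-pH coastal parcel used throughout the package documentation
#' carb_from_dic_ta(2200, 2100, temperature = 11, salinity = 30)
#' @export
carb_from_dic_ta <- function(DIC, TA, temperature, salinity) {
  if (any(!is.finite(DIC)) || any(DIC <= 0 | DIC > 5000))
    stop("`DIC` must lie in (0, 5000] umol/kg", call. = FALSE)
  if (any(!is.finite(TA)) || any(TA <= 0 | TA > 5000))
    stop("`TA` must lie in (0, 5000] umol/kg", call. = FALSE)
  k <- carb_constants(temperature, salinity)
  n <- max(length(DIC), length(TA), length(k$K1))
  DIC <- rep_len(DIC, n); TA <- rep_len(TA, n)
  if (length(k$K1) != n) k <- carb_constants(rep_len(k$temperature, n),
                                             rep_len(k$salinity, n))
  pH <- vapply(seq_len(n), function(i) {
    ki <- lapply(k, `[`, i)
    f <- function(p) .ta_from_ph_dic(p, DIC[i] * 1e-6, ki) - TA[i] * 1e-6
    lo <- f(3); hi <- f(12)
    if (is.na(lo) || is.na(hi) || lo * hi > 0)
      stop("infeasible state: no pH in [3, 12] matches DIC = ", DIC[i],
           ", TA = ", TA[i], call. = FALSE)
    stats::uniroot(f, c(3, 12), tol = 1e-10)$root
  }, numeric(1))
  sp <- .carb_ph_ta(pH, TA * 1e-6, k)
  .carbsys_frame(pH, TA * 1e-6, sp, k)
}

#' Speciate DIC at a given pH
#'
#' Partitions dissolved inorganic carbon into aqueous CO2, bicarbonate and
#' carbonate from total-scale pH and the carbonic-acid constants. Fractions
#' sum to one and the components sum to DIC exactly.
#'
#' @param pH total-scale pH.
#' @param DIC dissolved inorganic carbon, umol kg-1, > 0.
#' @param constants a `carb_constants` object from [carb_constants()].
#' @return data.frame with columns `co2_umol_kg`, `hco3_umol_kg`,
#'   `co3_umol_kg`.
#' @examples
#' k <- carb_constants(25, 35)
#' speciate(8.1, 2000, k)
#' @export
speciate <- function(pH, DIC, constants) {
  if (!inherits(constants, "carb_constants"))
    stop("`constants` must come from carb_constants()", call. = FALSE)
  if (any(!is.finite(pH)) || any(pH < 3 | pH > 12))
    stop("`pH` must lie in [3, 12]", call. = FALSE)
  if (any(!is.finite(DIC)) || any(DIC <= 0))
    stop("`DIC` must be positive", call. = FALSE)
  H <- 10^(-pH)
  denom <- H^2 + constants$K1 * H + constants$K1 * constants$K2
  f_co2 <- H^2 / denom
  f_hco3 <- constants$K1 * H / denom
  f_co3 <- 1 - f_co2 - f_hco3   # fractions sum to 1 exactly
  data.frame(co2_umol_kg = DIC * f_co2,
             hco3_umol_kg = DIC * f_hco3,
             co3_umol_kg = DIC * f_co3)
}

#' Convert between volumetric and gravimetric concentration
#'
#' Fixed-density conversion using 1 L of seawater = 1.024 kg, the factor
#' used for translating field predictions in umol/L into the gravimetric
#' units of the carbonate solver. Not a full equation of state.
#'
#' @param x concentration, umol L-1 (`umol_l_to_kg`) or umol kg-1
#'   (`umol_kg_to_l`).
#' @return The converted concentration.
#' @examples
#' umol_l_to_kg(22.5)  # 21.97 umol/kg
#' @export
umol_l_to_kg <- function(x) {
  stopifnot(is.numeric(x))
  x / .SW_KG_PER_L
}

#' @rdname umol_l_to_kg
#' @export
umol_kg_to_l <- function(x) {
  stopifnot(is.numeric(x))
  x * .SW_KG_PER_L
}

#' @export
print.carbsys <- function(x, digits = 4, ...) {
  cat("Seawater CO2 system (total pH scale, surface pressure)\n")
  print.data.frame(format(as.data.frame(x), digits = digits), ...)
  invisible(x)
}

# pH at which the system's pCO2 equals a target, used by the synthetic
# generators to set up treatment inflow water from a target pCO2 and TA.
.ph_from_pco2_ta <- function(pCO2, TA, temperature, salinity) {
  k <- carb_constants(temperature, salinity)
  f <- function(p) {
    sp <- .carb_ph_ta(p, TA * 1e-6, k)
    sp$co2 / k$K0 * 1e6 - pCO2
  }
  stats::uniroot(f, c(4, 11), tol = 1e-10)$root
}
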