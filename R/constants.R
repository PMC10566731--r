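#' Equilibrium constants of the seawater CO2 system
#'
#' Evaluates the dissociation and solubility constants needed to close the
#' carbonate system at surface pressure, together with the conservative
#' element totals derived from salinity. Hydrogen-ion constants are on the
#' total pH scale except the bisulfate constant `KS`, which is defined on the
#' free scale and used for free/total conversions.
#'
#' Formulations: carbonic acid `K1`/`K2` from Lueker et al. (2000); bisulfate
#' `KS` from Dickson (1990a); hydrogen fluoride `KF` from Perez & Fraga
#' (1987); CO2 solubility `K0` from Weiss (1974); boric acid `KB` from
#' Dickson (1990b); water `KW` from Millero (1995); aragonite solubility
#' `KspAr` from Mucci (1983). Totals: boron from Uppstrom (1974), sulfate
#' from Morris & Riley (1966), fluoride from Riley (1965), calcium from
#' Riley & Tongudai (1967). This is the default constant set of the
#' CO2SYS/seacarb family at surface pressure.
#'
#' @param temperature water temperature, degrees Celsius, in \[-2, 40\].
#' @param salinity practical salinity, in \[0, 45\].
#' @return An object of class `carb_constants`: a list of numeric vectors
#'   `K0` (mol kg-1 atm-1), `K1`, `K2`, `KB`, `KF` (mol kg-1), `KW`,
#'   `KspAr` (mol2 kg-2), `KS` (mol kg-1, free scale), and totals `BT`,
#'   `ST`, `FT`, `Ca` (mol kg-1), plus the inputs. Vectorized over
#'   temperature/salinity (recycled to a common length).
#' @examples
#' k <- carb_constants(temperature = 11, salinity = 30)
#' -log10(k$K1)  # pK1 on the total scale
#' @export
carb_constants <- function(temperature, salinity) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)))
    stop("`temperature` must be finite numeric", call. = FALSE)
  if (!is.numeric(salinity) || any(!is.finite(salinity)))
    stop("`salinity` must be finite numeric", call. = FALSE)
  if (any(temperature < -2 | temperature > 40))
    stop("`temperature` outside supported range [-2, 40] degC", call. = FALSE)
  if (any(salinity < 0 | salinity > 45))
    stop("`salinity` outside supported range [0, 45]", call. = FALSE)
  n <- max(length(temperature), length(salinity))
  TC <- rep_len(temperature, n)
  S <- rep_len(salinity, n)

  TK <- TC + 273.15
  lnT <- log(TK)
  sqS <- sqrt(S)

  # CO2 solubility, Weiss 1974 (mol kg-1 atm-1)
  K0 <- exp(-60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
              S * (0.023517 - 0.023656 * (TK / 100) +
                     0.0047036 * (TK / 100)^2))

  # Carbonic acid, Lueker et al. 2000, total scale
  pK1 <- 3633.86 / TK - 61.2172 + 9.6777 * lnT - 0.011555 * S +
    0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.929 - 3.16967 * lnT - 0.01781 * S +
    0.0001122 * S^2
  K1 <- 10^(-pK1)
  K2 <- 10^(-pK2)

  # Boric acid, Dickson 1990b, total scale
  KB <- exp((-8966.90 - 2890.53 * sqS - 77.942 * S + 1.728 * S^1.5 -
               0.0996 * S^2) / TK +
              148.0248 + 137.1942 * sqS + 1.62142 * S +
              (-24.4344 - 25.085 * sqS - 0.2474 * S) * lnT +
              0.053105 * sqS * TK)

  # Water, Millero 1995, total scale
  KW <- exp(148.9802 - 13847.26 / TK - 23.6521 * lnT +
              (118.67 / TK - 5.977 + 1.0495 * lnT) * sqS - 0.01615 * S)

  # Bisulfate, Dickson 1990a, free scale (ionic strength from salinity)
  IS <- 19.924 * S / (1000 - 1.005 * S)
  KS <- exp(-4276.1 / TK + 141.328 - 23.093 * lnT +
              (-13856 / TK + 324.57 - 47.986 * lnT) * sqrt(IS) +
              (35474 / TK - 771.54 + 114.723 * lnT) * IS -
              2698 / TK * IS^1.5 + 1776 / TK * IS^2 +
              log(1 - 0.001005 * S))

  # Hydrogen fluoride, Perez & Fraga 1987, total scale
  KF <- exp(874 / TK - 9.68 + 0.111 * sqS)

  # Aragonite solubility product, Mucci 1983
  KspAr <- 10^(-171.945 - 0.077993 * TK + 2903.293 / TK +
                 71.595 * log10(TK) +
                 (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqS -
                 0.10018 * S + 0.0059415 * S^1.5)

  out <- list(
    K0 = K0, K1 = K1, K2 = K2, KB = KB, KW = KW, KS = KS, KF = KF,
    KspAr = KspAr,
    BT = 0.000232 / 10.811 * S / 1.80655,
    ST = 0.14 / 96.062 * S / 1.80655,
    FT = 0.000067 / 18.998 * S / 1.80655,
    Ca = 0.02128 / 40.087 * S / 1.80655,
    temperature = TC, salinity = S, pressure = rep_len(0, n)
  )
  class(out) <- "carb_constants"
  out
}

#' @export
print.carb_constants <- function(x, ...) {
  n <- length(x$K1)
  cat("Seawater CO2-system constants (total pH scale, surface pressure)\n")
  cat(sprintf("  %d condition%s; T = %s degC, S = %s\n", n,
              if (n == 1) "" else "s",
              paste(signif(utils::head(x$temperature, 3), 4),
                    collapse = ", "),
              paste(signif(utils::head(x$salinity, 3), 4),
                    collapse = ", ")))
  cat(sprintf("  pK1 = %s, pK2 = %s\n",
              paste(round(-log10(utils::head(x$K1, 3)), 4), collapse = ", "),
              paste(round(-log10(utils::head(x$K2, 3)), 4), collapse = ", ")))
  invisible(x)
}
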