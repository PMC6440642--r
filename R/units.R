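# Physical constants and unit conversions used across the pipeline.
# Rates are mg/s in every user-facing interface; the evaporation module
# works in g/h internally, so the conversions live here, in one place.

#' Universal gas constant, J mol^-1 K^-1
#' @keywords internal
R_GAS <- 8.314462618

#' Molar mass of metofluthrin, g/mol (product literature)
#' @keywords internal
MW_METOFLUTHRIN <- 360.45

#' Default air state used for ppm conversion: 298.15 K, 101325 Pa
#' @keywords internal
DEFAULT_AIR_TEMPERATURE_K <- 298.15

#' @keywords internal
DEFAULT_AIR_PRESSURE_PA <- 101325

g_per_h_to_mg_per_s <- function(x) x * 1000 / 3600
mg_per_s_to_g_per_h <- function(x) x * 3600 / 1000

#' Convert a mass concentration to parts-per-million by volume
#'
#' Converts an active-ingredient mass concentration (mg/m^3) to a volume
#' mixing ratio in ppm, assuming ideal-gas behaviour of the vapour at the
#' given air temperature and pressure:
#' \deqn{ppmv = c \; \frac{R T}{P M} \times 10^{3}}
#' with \eqn{c} in mg/m^3 and \eqn{M} in g/mol.
#'
#' @param c_mg_m3 mass concentration(s), mg/m^3
#' @param molar_mass molar mass of the compound, g/mol
#'   (default: metofluthrin, 360.45)
#' @param temperature_K air temperature, K
#' @param pressure_Pa air pressure, Pa
#' @return numeric vector of volume mixing ratios in ppm
#' @examples
#' mass_conc_to_ppmv(1)  # 1 mg/m^3 of metofluthrin at 298.15 K, 1 atm
#' @export
mass_conc_to_ppmv <- function(c_mg_m3, molar_mass = MW_METOFLUTHRIN,
                              temperature_K = DEFAULT_AIR_TEMPERATURE_K,
                              pressure_Pa = DEFAULT_AIR_PRESSURE_PA) {
  if (molar_mass <= 0 || temperature_K <= 0 || pressure_Pa <= 0) {
    stop("molar mass, temperature and pressure must all be positive")
  }
  c_mg_m3 * (R_GAS * temperature_K / pressure_Pa) / molar_mass * 1e3
}

#' Inverse of [mass_conc_to_ppmv()]
#'
#' @param ppmv volume mixing ratio(s), ppm
#' @inheritParams mass_conc_to_ppmv
#' @return mass concentration(s), mg/m^3
#' @export
ppmv_to_mass_conc <- function(ppmv, molar_mass = MW_METOFLUTHRIN,
                              temperature_K = DEFAULT_AIR_TEMPERATURE_K,
                              pressure_Pa = DEFAULT_AIR_PRESSURE_PA) {
  if (molar_mass <= 0 || temperature_K <= 0 || pressure_Pa <= 0) {
    stop("molar mass, temperature and pressure must all be positive")
  }
  ppmv / ((R_GAS * temperature_K / pressure_Pa) / molar_mass * 1e3)
}
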