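# Headspace/dissolved gas accounting: ideal-gas headspace moles plus
# Henry's-law dissolved gas, with pH-dependent carbonate speciation for CO2.

GAS_CONSTANT_L_ATM <- 0.082057 # L atm / (mol K)

#' Default Henry's-law and carbonate constants
#'
#' Standard-compilation defaults: Henry solubilities at 298.15 K
#' (mol/(L atm)) with van 't Hoff temperature coefficients (K), and the
#' carbonic-acid dissociation constants at 25 C used for CO2 speciation.
#' Every value can be overridden, since published incubation studies rarely
#' print the exact constants they used.
#'
#' @param kh_298 named list/vector of Henry constants at 298.15 K for
#'   `CO2` and `CH4`, mol/(L atm).
#' @param vant_hoff_c named list/vector of van 't Hoff coefficients (K).
#' @param k1,k2 first and second carbonic-acid dissociation constants.
#' @return a list of class `henry_constants`.
#' @export
henry_constants <- function(kh_298 = c(CO2 = 3.4e-2, CH4 = 1.4e-3),
                            vant_hoff_c = c(CO2 = 2400, CH4 = 1700),
                            k1 = 10^-6.35, k2 = 10^-10.33) {
  stopifnot(all(unlist(kh_298) > 0), all(unlist(vant_hoff_c) > 0),
            k1 > 0, k2 > 0)
  structure(list(kh_298 = kh_298, vant_hoff_c = vant_hoff_c,
                 k1 = k1, k2 = k2),
            class = "henry_constants")
}

#' One headspace gas measurement
#'
#' @param sample_id sample identifier.
#' @param day day of incubation.
#' @param gas `"CO2"` or `"CH4"`.
#' @param headspace_ppm mixing ratio in ppm (>= 0).
#' @param temperature_K incubation temperature in kelvin.
#' @param pH medium pH (0 < pH < 14).
#' @param headspace_volume_L,liquid_volume_L tube geometry in litres.
#' @param total_pressure_atm total pressure (default 1 atm).
#' @return a `gas_sample` list.
#' @export
gas_sample <- function(sample_id, day, gas, headspace_ppm, temperature_K,
                       pH, headspace_volume_L, liquid_volume_L,
                       total_pressure_atm = 1) {
  gas <- match.arg(gas, c("CO2", "CH4"))
  stopifnot(headspace_ppm >= 0, temperature_K > 0, pH > 0, pH < 14,
            headspace_volume_L > 0, liquid_volume_L >= 0,
            total_pressure_atm > 0)
  structure(list(sample_id = sample_id, day = day, gas = gas,
                 headspace_ppm = headspace_ppm,
                 temperature_K = temperature_K, pH = pH,
                 headspace_volume_L = headspace_volume_L,
                 liquid_volume_L = liquid_volume_L,
                 total_pressure_atm = total_pressure_atm),
            class = "gas_sample")
}

#' Moles of gas in the headspace
#'
#' Ideal-gas moles from the headspace mixing ratio:
#' n = ppm * 1e-6 * P * V / (R T) with R = 0.082057 L atm / (mol K).
#'
#' @param sample a [gas_sample()].
#' @return moles of gas in the headspace.
#' @export
headspace_moles <- function(sample) {
  stopifnot(inherits(sample, "gas_sample"))
  sample$headspace_ppm * 1e-6 * sample$total_pressure_atm *
    sample$headspace_volume_L /
    (GAS_CONSTANT_L_ATM * sample$temperature_K)
}

#' Temperature-adjusted Henry's-law constant
#'
#' KH(T) = KH(298.15) * exp(C * (1/T - 1/298.15)).
#'
#' @param gas `"CO2"` or `"CH4"`.
#' @param temperature_K temperature in kelvin.
#' @param constants a [henry_constants()] object.
#' @return Henry solubility in mol/(L atm).
#' @export
henry_constant <- function(gas, temperature_K,
                           constants = henry_constants()) {
  gas <- match.arg(gas, c("CO2", "CH4"))
  stopifnot(temperature_K > 0)
  kh <- constants$kh_298[[gas]]
  cc <- constants$vant_hoff_c[[gas]]
  kh * exp(cc * (1 / temperature_K - 1 / 298.15))
}

#' CO2 carbonate speciation factor
#'
#' Multiplier converting dissolved CO2(aq) to total dissolved inorganic
#' carbon (CO2(aq) + HCO3- + CO3^2-): 1 + K1/[H+] + K1 K2/[H+]^2.
#'
#' @param pH medium pH.
#' @param constants a [henry_constants()] object.
#' @return dimensionless speciation factor (>= 1).
#' @export
co2_speciation_factor <- function(pH, constants = henry_constants()) {
  h <- 10^(-pH)
  1 + constants$k1 / h + constants$k1 * constants$k2 / h^2
}

#' Dissolved gas concentration from partial pressure
#'
#' CH4: c = KH(T) * p. CO2: c = KH(T) * p * speciation factor, so the total
#' dissolved pool includes carbonic acid, bicarbonate and carbonate.
#'
#' @param gas `"CO2"` or `"CH4"`.
#' @param partial_pressure_atm partial pressure (>= 0).
#' @param pH medium pH (used for CO2 only).
#' @param temperature_K temperature in kelvin.
#' @param constants a [henry_constants()] object.
#' @return concentration in mol/L.
#' @export
dissolved_concentration <- function(gas, partial_pressure_atm, pH,
                                    temperature_K,
                                    constants = henry_constants()) {
  gas <- match.arg(gas, c("CO2", "CH4"))
  stopifnot(partial_pressure_atm >= 0)
  kh <- henry_constant(gas, temperature_K, constants)
  c_aq <- kh * partial_pressure_atm
  if (gas == "CO2") c_aq <- c_aq * co2_speciation_factor(pH, constants)
  c_aq
}

#' Total (headspace + dissolved) moles of gas
#'
#' The sum of the gaseous and dissolved phases, the quantity reported as
#' total production in closed-tube incubations.
#'
#' @param sample a [gas_sample()].
#' @param constants a [henry_constants()] object.
#' @param peat_mass_g optional peat dry mass; when supplied, the result also
#'   carries a `umol_per_g` attribute.
#' @return total moles; with `umol_per_g` attribute if `peat_mass_g` given.
#' @export
total_gas <- function(sample, constants = henry_constants(),
                      peat_mass_g = NULL) {
  stopifnot(inherits(sample, "gas_sample"))
  p <- sample$headspace_ppm * 1e-6 * sample$total_pressure_atm
  total <- headspace_moles(sample) +
    dissolved_concentration(sample$gas, p, sample$pH,
                            sample$temperature_K, constants) *
      sample$liquid_volume_L
  if (!is.null(peat_mass_g)) {
    attr(total, "umol_per_g") <- total * 1e6 / peat_mass_g
  }
  total
}

#' Total gas for a table of measurements
#'
#' Vectorised [total_gas()] over a data frame in the gas CSV dialect
#' (columns `sample_id`, `day`, `gas`, `ppm`, `temp_C`, `pH`,
#' `headspace_mL`, `liquid_mL`).
#'
#' @param df data frame of measurements.
#' @param constants a [henry_constants()] object.
#' @return the input with a `total_mol` column appended.
#' @export
total_gas_table <- function(df, constants = henry_constants()) {
  need <- c("sample_id", "day", "gas", "ppm", "temp_C", "pH",
            "headspace_mL", "liquid_mL")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gas table missing columns: ",
                         paste(miss, collapse = ", "))
  df$total_mol <- vapply(seq_len(nrow(df)), function(i) {
    s <- gas_sample(df$sample_id[i], df$day[i], df$gas[i], df$ppm[i],
                    df$temp_C[i] + 273.15, df$pH[i],
                    df$headspace_mL[i] / 1000, df$liquid_mL[i] / 1000)
    total_gas(s, constants)
  }, numeric(1))
  df
}

#' Balch-tube incubation preset
#'
#' Geometry and temperature of the study-style anaerobic incubations:
#' ~26 mL Balch tube with 11 mL liquid medium at 19 C.
#'
#' @return list with `headspace_volume_L`, `liquid_volume_L`,
#'   `temperature_K`.
#' @export
balch_tube_preset <- function() {
  list(headspace_volume_L = 0.015, liquid_volume_L = 0.011,
       temperature_K = 19 + 273.15)
}
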