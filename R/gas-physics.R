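#' Adjust measured wind speed to the 10 m reference height
#'
#' Extrapolates a wind speed measured at sensor height `zu` to the standard
#' 10 m reference height assuming a logarithmic profile with neutral
#' stability, `U10 = U + (u*/kappa) * ln(10/zu)`, with the von Karman
#' constant kappa = 0.4.  The formula does not guarantee a non-negative
#' result for measurement heights above 10 m with strong friction
#' velocities; negative adjusted winds are clamped to zero with a warning.
#'
#' @param u Measured wind speed at height `zu`, m s^-1 (vector).
#' @param ustar Friction velocity, m s^-1 (vector, recycled).
#' @param zu Measurement height, m (vector, recycled); must be > 0.
#' @return Wind speed at 10 m, m s^-1, same length as `u`.
#' @examples
#' adjust_wind_to_10m(5, 0.2, 1.5)
#' @export
adjust_wind_to_10m <- function(u, ustar, zu) {
  if (any(zu <= 0, na.rm = TRUE)) {
    abort("`zu` (sensor height) must be strictly positive.")
  }
  if (any(u < 0, na.rm = TRUE) || any(ustar < 0, na.rm = TRUE)) {
    abort("`u` and `ustar` must be non-negative.")
  }
  kappa <- physical_constants()$kappa
  u10 <- u + (ustar / kappa) * log(10 / zu)
  neg <- !is.na(u10) & u10 < 0
  if (any(neg)) {
    warn(sprintf(
      "%d adjusted wind speed(s) were negative and have been clamped to 0.",
      sum(neg)
    ))
    u10[neg] <- 0
  }
  u10
}

#' Gas solubility in brackish water
#'
#' Evaluates the published temperature/salinity fit
#' `ln x = A1 + A2*(100/T) + A3*ln(T/100) + S*(B1 + B2*(T/100) + B3*(T/100)^2)`
#' for the gas's solubility.  For CH4 the fitted quantity `x` is the
#' dimensionless Bunsen coefficient beta (mL gas at STP per mL water per
#' atm); the volumetric solubility follows from ideal-gas behaviour as
#' `K0 = beta / (R * T_STD)`.  For CO2 the fitted quantity is the
#' volumetric solubility K0 (mol L^-1 atm^-1) directly, and beta is
#' back-computed through the same ideal-gas relation, so both gases expose
#' the same `{beta, k0}` contract.
#'
#' @param gas `"CO2"` or `"CH4"`.
#' @param temp_k Water temperature, kelvin (vector).
#' @param salinity Salinity, PSU (vector, recycled).
#' @return A tibble with columns `beta` (dimensionless Bunsen coefficient)
#'   and `k0` (mol m^-3 atm^-1).
#' @examples
#' solubility("CH4", temp_k = 283.15, salinity = 6.8)
#' @export
solubility <- function(gas, temp_k, salinity) {
  gas <- match_gas(gas)
  info <- gas_info(gas)
  sol <- info$solubility
  tr <- sol$temp_range_k
  sr <- sol$sal_range
  bad_t <- !is.na(temp_k) & (temp_k < tr[1] | temp_k > tr[2])
  bad_s <- !is.na(salinity) & (salinity < sr[1] | salinity > sr[2])
  if (any(bad_t)) {
    abort(sprintf(
      "Temperature out of range for the %s solubility fit (valid %.2f-%.2f K).",
      gas, tr[1], tr[2]
    ))
  }
  if (any(bad_s)) {
    abort(sprintf(
      "Salinity out of range for the %s solubility fit (valid %g-%g).",
      gas, sr[1], sr[2]
    ))
  }
  phys <- physical_constants()
  rt_std <- phys$R_m3_atm * phys$t_std_k            # m^3 atm mol^-1
  t100 <- temp_k / 100
  lnx <- sol$A1 + sol$A2 * (100 / temp_k) + sol$A3 * log(t100) +
    salinity * (sol$B1 + sol$B2 * t100 + sol$B3 * t100^2)
  x <- exp(lnx)
  if (identical(sol$form, "bunsen_beta")) {
    beta <- x
    k0 <- beta / rt_std                              # mol m^-3 atm^-1
  } else if (identical(sol$form, "k0_mol_l_atm")) {
    k0 <- x * 1000                                   # mol m^-3 atm^-1
    beta <- x * (phys$R_m3_atm * 1000) * phys$t_std_k
  } else {
    abort(sprintf("Unknown solubility form \"%s\" in constants file.", sol$form))
  }
  tibble(beta = beta, k0 = k0)
}

#' Schmidt number with brackish-water interpolation
#'
#' Evaluates the fourth-order Schmidt number polynomials in temperature
#' (deg C) for fresh water (salinity 0) and seawater (salinity 35), then
#' interpolates linearly in salinity:
#' `Sc = Sc_fresh + (Sc_sea - Sc_fresh) * S / 35`.  Salinities above 35
#' are refused (no extrapolation).
#'
#' @param gas `"CO2"` or `"CH4"`.
#' @param temp_c Water temperature, deg C (vector).
#' @param salinity Salinity, PSU in `[0, 35]` (vector, recycled).
#' @return Dimensionless Schmidt number, same length as the inputs.
#' @examples
#' schmidt_number("CO2", 20, 35)  # ~668, the k-parameterization reference gas
#' @export
schmidt_number <- function(gas, temp_c, salinity) {
  gas <- match_gas(gas)
  info <- gas_info(gas)
  tr <- info$schmidt$temp_range_c
  if (any(!is.na(temp_c) & (temp_c < tr[1] | temp_c > tr[2]))) {
    abort(sprintf(
      "Temperature out of range for the %s Schmidt polynomial (valid %g-%g degC).",
      gas, tr[1], tr[2]
    ))
  }
  sal_max <- physical_constants()$reference_salinity_sea
  if (any(!is.na(salinity) & (salinity < 0 | salinity > sal_max))) {
    abort(sprintf(
      "Salinity must lie in [0, %g]; the Schmidt interpolation is not extrapolated.",
      sal_max
    ))
  }
  sc_fresh <- eval_sc_poly(info$schmidt$fresh, temp_c)
  sc_sea <- eval_sc_poly(info$schmidt$sea, temp_c)
  sc_fresh + (sc_sea - sc_fresh) * salinity / sal_max
}

eval_sc_poly <- function(coefs, t) {
  coefs <- as.numeric(coefs)
  coefs[1] + coefs[2] * t + coefs[3] * t^2 + coefs[4] * t^3 + coefs[5] * t^4
}

#' Gas transfer velocity from wind speed
#'
#' Quadratic wind-speed parameterization
#' `k = 0.251 * U10^2 * (Sc/660)^-0.5` with `k` in cm h^-1; the value is
#' also converted to m s^-1 (divide by 3.6e5), the unit used in the bulk
#' flux equation.
#'
#' @param u10 Wind speed at 10 m, m s^-1 (vector).
#' @param sc Schmidt number of the gas at in-situ temperature and salinity
#'   (vector, recycled); must be > 0.
#' @return A tibble with columns `k_cmh` (cm h^-1) and `k_ms` (m s^-1).
#' @examples
#' gas_transfer_velocity(5, 660)  # 6.275 cm/h
#' @export
gas_transfer_velocity <- function(u10, sc) {
  if (any(u10 < 0, na.rm = TRUE)) {
    abort("`u10` must be non-negative.")
  }
  if (any(sc <= 0, na.rm = TRUE)) {
    abort("`sc` (Schmidt number) must be strictly positive.")
  }
  sc_ref <- physical_constants()$sc_reference
  k_cmh <- 0.251 * u10^2 * (sc / sc_ref)^(-0.5)
  tibble(k_cmh = k_cmh, k_ms = k_cmh / 3.6e5)
}

#' Bulk sea-air gas flux
#'
#' Computes the sea-air flux `F = k * K0 * (pGas_sea - pGas_air)` and
#' converts it from mol m^-2 s^-1 to mg m^-2 d^-1 using the gas molar
#' mass.  Positive fluxes are effluxes from the water to the atmosphere;
#' negative fluxes are uptake of atmospheric gas.  `NA` inputs propagate
#' to `NA` fluxes (missing records).
#'
#' @param gas `"CO2"` or `"CH4"` (sets the molar mass).
#' @param k_ms Gas transfer velocity, m s^-1.
#' @param k0 Volumetric solubility, mol m^-3 atm^-1.
#' @param p_sea_uatm,p_air_uatm Partial pressures of the gas in surface
#'   water and air, micro-atm.
#' @return Flux in mg m^-2 d^-1, vectorized over the inputs.
#' @examples
#' sea_air_flux("CH4", k_ms = 1.7e-5, k0 = 1.5,
#'              p_sea_uatm = 35, p_air_uatm = 1.9)
#' @export
sea_air_flux <- function(gas, k_ms, k0, p_sea_uatm, p_air_uatm) {
  gas <- match_gas(gas)
  if (any(k_ms < 0, na.rm = TRUE)) {
    abort("`k_ms` must be non-negative.")
  }
  if (any(k0 <= 0, na.rm = TRUE)) {
    abort("`k0` must be strictly positive.")
  }
  m <- gas_info(gas)$molar_mass
  f_mol <- k_ms * k0 * (p_sea_uatm - p_air_uatm) * 1e-6   # mol m^-2 s^-1
  f_mol * m * 1e3 * 86400                                  # mg m^-2 d^-1
}
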