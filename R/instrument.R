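#' Instrument configuration for a drift-tube ion mobility spectrometer
#'
#' Holds the geometry and operating conditions that fix the drift-time axis:
#' tube length \eqn{L}, drift voltage \eqn{U} (field \eqn{E = U/L}), drift-gas
#' temperature and pressure, and the reference conditions \eqn{T_0, p_0} used
#' for reduced mobility \eqn{K_0}. Defaults reproduce a compact Tritium-source
#' drift-tube instrument: 56 mm tube, 2470 V, 80 degC drift gas, ambient
#' pressure, 100 us shutter opening.
#'
#' @param drift_length_m drift-tube length \eqn{L} in metres.
#' @param drift_voltage_V drift voltage \eqn{U} in volts.
#' @param tube_temperature_K drift-gas temperature \eqn{T} in kelvin.
#' @param pressure_hPa ambient pressure \eqn{p} in hectopascal; a warning is
#'   emitted outside the plausible ambient range 950--1050 hPa.
#' @param reference_temperature_K reference temperature \eqn{T_0} for
#'   \eqn{K_0} (kelvin). The conventional 273.15 K.
#' @param reference_pressure_hPa reference pressure \eqn{p_0} (hPa),
#'   conventionally 1013.25 hPa.
#' @param shutter_open_us ion-gate opening time in microseconds (metadata
#'   only; it does not enter the drift-time calculation).
#'
#' @return An object of class `instrument_config`: a list with the above
#'   fields plus the derived field strength `field_V_per_m`.
#' @examples
#' inst <- instrument_config()
#' inst$field_V_per_m # 2470 V over 56 mm
#' @export
instrument_config <- function(drift_length_m = 0.056,
                              drift_voltage_V = 2470,
                              tube_temperature_K = 353.15,
                              pressure_hPa = 1013.25,
                              reference_temperature_K = 273.15,
                              reference_pressure_hPa = 1013.25,
                              shutter_open_us = 100) {
  check_number(drift_length_m, "drift_length_m", positive = TRUE)
  check_number(drift_voltage_V, "drift_voltage_V", positive = TRUE)
  check_number(tube_temperature_K, "tube_temperature_K", positive = TRUE)
  check_number(pressure_hPa, "pressure_hPa", positive = TRUE)
  check_number(reference_temperature_K, "reference_temperature_K", positive = TRUE)
  check_number(reference_pressure_hPa, "reference_pressure_hPa", positive = TRUE)
  check_number(shutter_open_us, "shutter_open_us", positive = TRUE)
  if (pressure_hPa < 950 || pressure_hPa > 1050) {
    warning(sprintf("pressure %.1f hPa outside typical ambient range 950-1050 hPa",
                    pressure_hPa))
  }
  structure(list(
    drift_length_m = drift_length_m,
    drift_voltage_V = drift_voltage_V,
    field_V_per_m = drift_voltage_V / drift_length_m,
    tube_temperature_K = tube_temperature_K,
    pressure_hPa = pressure_hPa,
    reference_temperature_K = reference_temperature_K,
    reference_pressure_hPa = reference_pressure_hPa,
    shutter_open_us = shutter_open_us
  ), class = "instrument_config")
}

#' @export
print.instrument_config <- function(x, ...) {
  cat("<instrument_config>\n")
  cat(sprintf("  drift tube: L = %.3f m, U = %.0f V (E = %.0f V/m)\n",
              x$drift_length_m, x$drift_voltage_V, x$field_V_per_m))
  cat(sprintf("  conditions: T = %.2f K, p = %.2f hPa (T0 = %.2f K, p0 = %.2f hPa)\n",
              x$tube_temperature_K, x$pressure_hPa,
              x$reference_temperature_K, x$reference_pressure_hPa))
  invisible(x)
}

#' Convert mobility at instrument conditions to reduced mobility
#'
#' Reduced mobility standardizes the measured mobility \eqn{K} to reference
#' temperature and pressure: \eqn{K_0 = K \cdot (T_0/T) \cdot (p/p_0)}.
#' It is the exact inverse of the conversion applied inside [drift_time()],
#' so the round trip reproduces the input to floating-point accuracy.
#'
#' @param K mobility at instrument conditions, cm^2 V^-1 s^-1.
#' @param T_K,p_hPa instrument temperature (K) and pressure (hPa).
#' @param T0_K,p0_hPa reference temperature and pressure.
#' @return Reduced mobility \eqn{K_0} in cm^2 V^-1 s^-1.
#' @examples
#' reduced_mobility(2.0, T_K = 353.15, p_hPa = 1013.25)
#' @seealso [drift_time()], [mobility_at_conditions()]
#' @export
reduced_mobility <- function(K, T_K, p_hPa,
                             T0_K = 273.15, p0_hPa = 1013.25) {
  check_number(K, "K", positive = TRUE)
  check_number(T_K, "T_K", positive = TRUE)
  check_number(p_hPa, "p_hPa", positive = TRUE)
  check_number(T0_K, "T0_K", positive = TRUE)
  check_number(p0_hPa, "p0_hPa", positive = TRUE)
  K * (T0_K / T_K) * (p_hPa / p0_hPa)
}

#' Convert reduced mobility to mobility at instrument conditions
#'
#' \eqn{K = K_0 \cdot (T/T_0) \cdot (p_0/p)}; inverse of [reduced_mobility()].
#'
#' @param K0 reduced mobility, cm^2 V^-1 s^-1.
#' @inheritParams reduced_mobility
#' @return Mobility \eqn{K} at the given conditions, cm^2 V^-1 s^-1.
#' @export
mobility_at_conditions <- function(K0, T_K, p_hPa,
                                   T0_K = 273.15, p0_hPa = 1013.25) {
  check_number(K0, "K0", positive = TRUE)
  check_number(T_K, "T_K", positive = TRUE)
  check_number(p_hPa, "p_hPa", positive = TRUE)
  K0 * (T_K / T0_K) * (p0_hPa / p_hPa)
}

#' Drift time of an ion from its reduced mobility
#'
#' An ion with mobility \eqn{K} drifts the tube length \eqn{L} at velocity
#' \eqn{v = K E}, so \eqn{t_d = L/(E K) = L^2/(U K)}. The reduced mobility
#' `k0` is first converted to the mobility at the instrument's temperature
#' and pressure (\eqn{K = K_0 (T/T_0)(p_0/p)}).
#'
#' @param k0 reduced mobility \eqn{K_0} in cm^2 V^-1 s^-1.
#' @param instrument an [instrument_config()].
#' @return Drift time in milliseconds.
#' @examples
#' # protonated water cluster (RIP) on the default instrument
#' drift_time(2.1, instrument_config())
#' @export
drift_time <- function(k0, instrument = instrument_config()) {
  check_number(k0, "k0", positive = TRUE)
  stopifnot(inherits(instrument, "instrument_config"))
  K_cm2 <- mobility_at_conditions(
    k0,
    T_K = instrument$tube_temperature_K,
    p_hPa = instrument$pressure_hPa,
    T0_K = instrument$reference_temperature_K,
    p0_hPa = instrument$reference_pressure_hPa
  )
  K_m2 <- K_cm2 * 1e-4 # cm^2/(V s) -> m^2/(V s)
  td_s <- instrument$drift_length_m^2 / (instrument$drift_voltage_V * K_m2)
  td_s * 1e3
}
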