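#' Physical constants and unit conventions
#'
#' All quantities in the package use one fixed unit system: voltage in mV,
#' time in ms, length in um, conductance in pS (1e-6 uS), current in pA,
#' concentration in mM (derived quantities reported in uM where noted),
#' temperature in Kelvin unless a function documents degrees Celsius.
#' Conversions are centralized here; no other file hard-codes a unit factor.
#'
#' @format A named list with elements
#' \describe{
#'   \item{FARADAY}{Faraday constant, C/mol.}
#'   \item{GAS_CONSTANT}{Molar gas constant R, J/(mol K).}
#'   \item{ZERO_C_KELVIN}{0 degrees Celsius in Kelvin.}
#'   \item{PS_PER_US}{picosiemens per microsiemens.}
#'   \item{PA_PER_NA}{picoamperes per nanoampere.}
#'   \item{UM2_PER_CM2}{square micrometres per square centimetre.}
#'   \item{L_PER_UM3}{litres per cubic micrometre.}
#' }
#' @export
PHYS <- list(
  FARADAY      = 96485.332,
  GAS_CONSTANT = 8.314462,
  ZERO_C_KELVIN = 273.15,
  PS_PER_US    = 1e6,
  PA_PER_NA    = 1e3,
  UM2_PER_CM2  = 1e8,
  L_PER_UM3    = 1e-15
)

#' Convert degrees Celsius to Kelvin
#' @param celsius temperature in degrees Celsius
#' @return temperature in Kelvin
#' @export
celsius_to_kelvin <- function(celsius) celsius + PHYS$ZERO_C_KELVIN

# RT/F in mV at temperature T (Kelvin); thermal voltage for a monovalent ion.
rt_over_f_mv <- function(temp_k) {
  1e3 * PHYS$GAS_CONSTANT * temp_k / PHYS$FARADAY
}
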