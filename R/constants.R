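#' Gyromagnetic ratio of the proton
#'
#' 2.675e8 rad s^-1 T^-1, the value used for all ppm and microtesla unit
#' conversions in this package.
#'
#' @export
GAMMA_1H <- 2.675e8

#' Unit conversions between ppm / microtesla and angular frequency
#'
#' Chemical-shift offsets are stated in parts per million (ppm) of the Larmor
#' frequency `gamma * b0`; saturation amplitudes in microtesla. Internally the
#' Bloch-McConnell evolution matrix works in rad s^-1.
#'
#' @param ppm Frequency offset in ppm.
#' @param b0 Static field strength in Tesla.
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1.
#' @param b1_uT Saturation amplitude in microtesla.
#' @return Angular frequency in rad s^-1.
#' @examples
#' ppm_to_rads(3, b0 = 3) / (2 * pi) # offset in Hz
#' @export
ppm_to_rads <- function(ppm, b0, gamma = GAMMA_1H) {
  ppm * 1e-6 * gamma * b0
}

#' @rdname ppm_to_rads
#' @export
rads_to_ppm <- function(ppm, b0, gamma = GAMMA_1H) {
  ppm / (1e-6 * gamma * b0)
}

#' @rdname ppm_to_rads
#' @export
b1_to_rads <- function(b1_uT, gamma = GAMMA_1H) {
  gamma * b1_uT * 1e-6
}
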