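#' Hounsfield-unit conversion from linear attenuation coefficients
#'
#' The Hounsfield scale is the affine remapping of X-ray attenuation that
#' fixes water at 0 HU and vacuum/air at -1000 HU:
#' `HU = 1000 * (rho_material - rho_water) / rho_water`.
#'
#' @param rhoMaterial attenuation coefficient of the material (>= 0); may be
#'   a vector.
#' @param rhoWater attenuation coefficient of water (> 0).
#' @return the HU value(s).
#' @examples
#' huFromAttenuation(0.19, 0.19)   # water -> 0
#' huFromAttenuation(0, 0.19)      # air   -> -1000
#' huFromAttenuation(0.38, 0.19)   # twice water -> 1000
#' @export
huFromAttenuation <- function(rhoMaterial, rhoWater) {
  if (!is.numeric(rhoWater) || length(rhoWater) != 1L || !is.finite(rhoWater) ||
      rhoWater <= 0)
    ctsimStop("invalidParameter", "rhoWater must be a single positive value")
  if (!is.numeric(rhoMaterial) || any(!is.finite(rhoMaterial)) ||
      any(rhoMaterial < 0))
    ctsimStop("invalidParameter", "rhoMaterial must be non-negative")
  ## grouped so the water and air anchors are exact in floating point
  1000 * ((rhoMaterial - rhoWater) / rhoWater)
}

#' The representable integer HU range of 12-bit CT storage
#'
#' Medical scanners provide HU values between -1024 and +3071: 4096 distinct
#' integer values, i.e. exactly 12 bits.  Values outside this range are
#' clamped when a [VoxelVolume-class] is constructed.
#'
#' @return integer(2), `c(-1024, 3071)`.
#' @export
huRange <- function() c(.HU_MIN, .HU_MAX)
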