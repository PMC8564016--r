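# Unit conventions: the data layer (trees, lesions, flows, pressures at user
# interfaces) is clinical -- mm, mm^2, mL/s, mmHg, g -- matching the file
# schema and the usual catheter-lab units. The physics kernels in
# pressure_ffr.R take strict SI (m, m^2, m^3/s, Pa). Conversions happen only
# at the kernel boundary, through the constants below.

#' Unit conversion constants
#'
#' `MMHG_PA` is the conversion factor between mmHg and pascal, pinned so that
#' pressure round-trips are bit-stable across the package.
#'
#' @format Numeric scalars.
#' @export
MMHG_PA <- 133.322387415

#' @rdname MMHG_PA
#' @export
MM_M <- 1e-3

#' @rdname MMHG_PA
#' @export
MM2_M2 <- 1e-6

#' @rdname MMHG_PA
#' @export
MLS_M3S <- 1e-6

pa_to_mmhg <- function(p) p / MMHG_PA
mmhg_to_pa <- function(p) p * MMHG_PA

# equivalent circular radius (same units as sqrt(area))
area_to_radius <- function(area) sqrt(area / pi)
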