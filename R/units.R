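#' Unit conversion helpers
#'
#' The model works internally in centimetres and years, with pore-water
#' solutes in umol cm^-3 of pore water and solids in umol cm^-3 of solid
#' phase. Boundary fluxes and diagnostics are reported in the field's
#' customary umol m^-2 d^-1 (mmol m^-2 d^-1 for carbon).
#'
#' @param x numeric flux value(s).
#' @return converted numeric value(s).
#' @name units
NULL

#: days per year used throughout
DAYS_PER_YEAR <- 365.25

#' @rdname units
#' @export
flux_day_to_yr <- function(x) x * DAYS_PER_YEAR / 1e4   # umol m-2 d-1 -> umol cm-2 yr-1

#' @rdname units
#' @export
flux_yr_to_day <- function(x) x * 1e4 / DAYS_PER_YEAR   # umol cm-2 yr-1 -> umol m-2 d-1
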