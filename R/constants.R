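#' Physical and instrument constants used throughout the model
#'
#' A single named list collecting every fixed constant of the pipeline, so
#' there is exactly one place where each value lives:
#'
#' \describe{
#'   \item{`irga_f_slope`}{9.73e-4 (per mmol mol⁻¹) — default slope of the
#'     humidity correction factor \eqn{F} relating the sample/reference water
#'     vapour difference to the CO₂ dilution artefact in the sample IRGA.
#'     Re-derivable from a wet-paper calibration via
#'     [fit_correction_slope()].}
#'   \item{`heskel_b`, `heskel_c`}{0.1012 and −0.0005 — the fixed
#'     log-quadratic temperature coefficients of the Heskel-form respiration
#'     exponent \eqn{f + 0.1012\,T - 0.0005\,T^2}. These are global
#'     empirical constants, not fitted per species.}
#'   \item{`mw_co2`}{44.01 g mol⁻¹ — molecular weight of CO₂, used to convert
#'     integrated μmol CO₂ m⁻² to g CO₂ m⁻² in daily NPP.}
#'   \item{`aqe_default`}{0.0144 μmol CO₂ μmol⁻¹ photons — apparent quantum
#'     efficiency (initial slope of the light-response curve), averaged from
#'     light curves at 25 °C and treated as temperature-invariant over
#'     15–35 °C.}
#'   \item{`step_seconds`}{1800 s — the half-hourly meteorological forcing
#'     interval over which each modelled flux is assumed constant.}
#'   \item{`steps_per_day`}{48 — half-hour steps in one day.}
#' }
#'
#' @examples
#' sphagnum_constants$aqe_default
#' @export
sphagnum_constants <- list(
  irga_f_slope  = 9.73e-4,
  heskel_b      = 0.1012,
  heskel_c      = -0.0005,
  mw_co2        = 44.01,
  aqe_default   = 0.0144,
  step_seconds  = 1800,
  steps_per_day = 48L
)
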