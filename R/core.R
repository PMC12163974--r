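#' IRGA humidity correction factor
#'
#' Water evaporating from a wet moss dilutes CO₂ in the sample air stream;
#' the correction factor `F` applied to the sample CO₂ reading is a linear
#' function of the water-vapour difference between sample and reference
#' analysers: `F = slope * (H2OS - H2OR) + 1`.
#'
#' @param H2OS,H2OR Sample and reference water vapour (mmol mol⁻¹). Vectors
#'   recycle as usual.
#' @param slope Calibration slope (per mmol mol⁻¹); default the wet-paper
#'   calibration value [sphagnum_constants]`$irga_f_slope`.
#' @return Dimensionless correction factor(s); exactly 1 when sample and
#'   reference humidity are equal.
#' @export
irga_correction_factor <- function(H2OS, H2OR,
                                   slope = sphagnum_constants$irga_f_slope) {
  slope * (H2OS - H2OR) + 1
}

#' Humidity-corrected net CO2 assimilation from raw IRGA readings
#'
#' `A_N = flow_mol * (CO2R - CO2S * F) / area`, where `flow_mol` is the
#' chamber flow converted from the instrument's μmol air s⁻¹ to mol air s⁻¹.
#' Positive values mean the sample depletes CO₂ from the air stream
#' (net uptake).
#'
#' @param CO2R,CO2S Reference and sample CO₂ (μmol mol⁻¹).
#' @param flow Chamber flow (μmol air s⁻¹), > 0.
#' @param area Projected capitula area (m²), > 0.
#' @param F Humidity correction factor from [irga_correction_factor()].
#' @return Net assimilation (μmol CO₂ m⁻² s⁻¹).
#' @export
corrected_an <- function(CO2R, CO2S, flow, area, F = 1) {
  if (any(!is.finite(flow)) || any(flow <= 0))
    stop("invalid input: flow must be a positive chamber flow (umol air/s)")
  if (any(!is.finite(area)) || any(area <= 0))
    stop("invalid input: area must be a positive projected area (m^2)")
  if (any(CO2R < 0) || any(CO2S < 0))
    stop("invalid input: CO2 concentrations must be >= 0")
  (flow * 1e-6) * (CO2R - CO2S * F) / area
}

#' Tissue water content
#'
#' `WC = (FW - DW) / DW` in g H₂O g⁻¹ DW. Fresh weights slightly below dry
#' weight (weighing noise on desiccated samples) are allowed and give small
#' negative values.
#'
#' @param FW Fresh weight (g).
#' @param DW Dry weight (g), > 0.
#' @return Water content (g H₂O g⁻¹ DW).
#' @export
water_content <- function(FW, DW) {
  if (any(!is.finite(DW)) || any(DW <= 0))
    stop("invalid input: DW must be > 0")
  (FW - DW) / DW
}

#' Light-saturated assimilation surface over temperature and water content
#'
#' Evaluates the polynomial response surface of light-saturated net
#' assimilation. Under the default multiplicative grouping
#' `A_sat = (a*T^2 + b*T + c) * (-d*WC^2 + e*WC)`, which forces A_sat to 0
#' as the tissue dries out at every temperature and gives one
#' temperature-independent water-content optimum `e/(2d)`. The additive
#' variant `a*T^2 + b*T + c - d*WC^2 + e*WC` is selected by the parameter
#' set's `grouping` field. No clamping: negative values at extreme
#' temperature or water content are legitimate model output.
#'
#' @param T_moss Moss surface temperature (°C).
#' @param WC Water content (g H₂O g⁻¹ DW), ≥ 0.
#' @param params An [an_params()] object.
#' @return A_sat (μmol m⁻² s⁻¹).
#' @export
asat_surface <- function(T_moss, WC, params) {
  stopifnot(inherits(params, "an_params"))
  if (any(WC < 0)) stop("invalid input: WC must be >= 0")
  tpoly  <- params$a * T_moss^2 + params$b * T_moss + params$c
  wcpoly <- -params$d * WC^2 + params$e * WC
  if (params$grouping == "multiplicative") tpoly * wcpoly else tpoly + wcpoly
}

#' Dark respiration surface over temperature and water content
#'
#' Heskel-form log-quadratic temperature response with additive
#' water-content terms:
#' `R_D = exp(f + 0.1012*T - 0.0005*T^2) - g*WC + h + i*log(WC)*T`
#' (log base set by the parameter set, natural by default). Respiration is
#' reported positive. The raw surface crosses zero near WC ≈ 0; with
#' `clamp_nonnegative = TRUE` the result is floored at 0, the convention
#' used during prediction and NPP integration (night respiration cannot be
#' a CO₂ sink). Calibration fits the raw (unclamped) surface.
#'
#' @param T_moss Moss surface temperature (°C).
#' @param WC Water content (g H₂O g⁻¹ DW), > 0 (log term).
#' @param params An [an_params()] object (fields `f`–`i`, `log_base`).
#' @param clamp_nonnegative Floor the result at zero? Default `FALSE`.
#' @return R_D (μmol CO₂ m⁻² s⁻¹, positive = efflux).
#' @export
rd_surface <- function(T_moss, WC, params, clamp_nonnegative = FALSE) {
  stopifnot(inherits(params, "an_params"))
  if (any(WC <= 0)) stop("invalid input: WC must be > 0 (log term)")
  rd <- exp(params$f + sphagnum_constants$heskel_b * T_moss +
              sphagnum_constants$heskel_c * T_moss^2) -
    params$g * WC + params$h +
    params$i * .model_log(WC, params$log_base) * T_moss
  if (clamp_nonnegative) pmax(rd, 0) else rd
}

#' Smith light-response equation for net assimilation
#'
#' Non-rectangular saturating light response:
#' \deqn{A_N = \frac{(A_{sat}+R_D)\,PAR\,AQE}
#'   {\sqrt{AQE^2 PAR^2 + (A_{sat}+R_D)^2}} - R_D}
#' with dark value exactly −R_D, asymptote A_sat as PAR → ∞, and initial
#' slope AQE.
#'
#' @param PAR Photosynthetically active radiation (μmol photons m⁻² s⁻¹), ≥ 0.
#' @param A_sat Light-saturated net assimilation (μmol m⁻² s⁻¹).
#' @param R_D Dark respiration (μmol m⁻² s⁻¹, positive).
#' @param AQE Apparent quantum efficiency, > 0.
#' @return Net assimilation (μmol m⁻² s⁻¹).
#' @export
smith_net_assimilation <- function(PAR, A_sat, R_D,
                                   AQE = sphagnum_constants$aqe_default) {
  if (any(!is.finite(AQE)) || any(AQE <= 0))
    stop("invalid input: AQE must be > 0")
  if (any(PAR < 0)) stop("invalid input: PAR must be >= 0")
  gross <- A_sat + R_D
  gross * PAR * AQE / sqrt(AQE^2 * PAR^2 + gross^2) - R_D
}

#' Net assimilation predicted from temperature, water content and light
#'
#' Composes the dark-respiration surface, the light-saturated assimilation
#' surface and the Smith light response into the full point-wise model:
#' modelled A_N from `T_moss`, `WC`, `PAR` and a fitted parameter set.
#' At PAR = 0 the result is exactly −R_D.
#'
#' @param T_moss Moss surface temperature (°C).
#' @param WC Water content (g H₂O g⁻¹ DW), > 0.
#' @param PAR Irradiance (μmol m⁻² s⁻¹), ≥ 0.
#' @param params An [an_params()] object.
#' @param clamp_rd Floor R_D at zero before entering the light response?
#'   Default `TRUE`, the prediction/NPP convention; calibration uses the raw
#'   surface (`FALSE`).
#' @return Net assimilation (μmol m⁻² s⁻¹); negative values (net efflux) are
#'   legitimate output.
#' @export
predict_an <- function(T_moss, WC, PAR, params, clamp_rd = TRUE) {
  rd <- rd_surface(T_moss, WC, params, clamp_nonnegative = clamp_rd)
  asat <- asat_surface(T_moss, WC, params)
  smith_net_assimilation(PAR, asat, rd, params$AQE)
}

#' Moss-canopy surface temperature from air temperature, light and hydration
#'
#' `T_moss = T_air + j*PAR^2 + k*PAR + l + m*log(WC)`: air temperature plus
#' a concave radiative warming term in PAR, buffered by tissue water
#' content (m < 0 — evaporative and heat-capacity cooling of wet canopies).
#'
#' @param T_air Air temperature (°C).
#' @param PAR Irradiance (μmol m⁻² s⁻¹).
#' @param WC Water content (g H₂O g⁻¹ DW), > 0.
#' @param params A [tmoss_params()] object.
#' @return Moss surface temperature (°C).
#' @export
tmoss_model <- function(T_air, PAR, WC, params) {
  stopifnot(inherits(params, "tmoss_params"))
  if (any(WC <= 0)) stop("invalid input: WC must be > 0 (log term)")
  T_air + params$j * PAR^2 + params$k * PAR + params$l +
    params$m * .model_log(WC, params$log_base)
}
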