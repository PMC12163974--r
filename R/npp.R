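#' Read half-hourly meteorological forcing
#'
#' CSV dialect: `timestamp_iso,T_air_C,PAR_umol_m2_s`, timestamps on a
#' strictly increasing regular 30-minute grid, PAR ≥ 0. Gaps are errors
#' (no gap-filling): the message names the first missing timestamp.
#'
#' @param path CSV file path.
#' @param tz Time zone for parsing (default `"UTC"`).
#' @return A forcing data frame with columns `timestamp` (POSIXct),
#'   `T_air`, `PAR`.
#' @export
read_meteo_csv <- function(path, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_iso", "T_air_C", "PAR_umol_m2_s")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("forcing CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  ts <- as.POSIXct(df$timestamp_iso, tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (any(is.na(ts))) stop("unparseable timestamp(s) in forcing CSV")
  out <- data.frame(timestamp = ts, T_air = df$T_air_C, PAR = df$PAR_umol_m2_s)
  validate_forcing(out)
  out
}

#' Write half-hourly forcing in the package CSV dialect
#' @param forcing Forcing data frame (`timestamp`, `T_air`, `PAR`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meteo_csv <- function(forcing, path) {
  validate_forcing(forcing)
  utils::write.csv(
    data.frame(timestamp_iso = format(forcing$timestamp, "%Y-%m-%dT%H:%M:%S"),
               T_air_C = forcing$T_air, PAR_umol_m2_s = forcing$PAR),
    path, row.names = FALSE)
  invisible(path)
}

# Regular-grid validation shared by readers and integrators.
validate_forcing <- function(forcing) {
  stopifnot(all(c("timestamp", "T_air", "PAR") %in% names(forcing)))
  if (nrow(forcing) < 2) stop("forcing needs at least two records")
  dt <- diff(as.numeric(forcing$timestamp))
  if (any(dt <= 0)) stop("forcing timestamps must be strictly increasing")
  step <- sphagnum_constants$step_seconds
  bad <- which(dt != step)
  if (length(bad) > 0)
    stop("incomplete forcing: missing 30-min step at ",
         format(forcing$timestamp[bad[1]] + step, "%Y-%m-%d %H:%M:%S"),
         " (no gap-filling is performed)")
  if (any(!is.finite(forcing$T_air)) || any(!is.finite(forcing$PAR)))
    stop("missing or non-finite T_air/PAR in forcing")
  if (any(forcing$PAR < 0)) stop("PAR must be >= 0")
  invisible(forcing)
}

#' Modelled assimilation time series over a forcing period
#'
#' For each half-hour record: moss surface temperature from the canopy
#' model, then net assimilation from the light-response composition with
#' respiration floored at zero (night respiration is never a CO₂ sink in
#' prediction).
#'
#' @param forcing Forcing data frame (`timestamp`, `T_air`, `PAR`).
#' @param WC Tissue water content held constant over the period (g g⁻¹).
#' @param an_params An [an_params()] object.
#' @param tmoss_params A [tmoss_params()] object.
#' @return The forcing with added columns `T_moss` and `A_N`.
#' @export
an_timeseries <- function(forcing, WC, an_params, tmoss_params) {
  validate_forcing(forcing)
  if (length(WC) != 1 || !is.finite(WC) || WC <= 0)
    stop("WC must be a single positive value held constant over the period")
  out <- forcing
  out$T_moss <- tmoss_model(forcing$T_air, forcing$PAR, WC, tmoss_params)
  out$A_N <- predict_an(out$T_moss, WC, forcing$PAR, an_params,
                        clamp_rd = TRUE)
  out
}

# sum of A_N (umol m-2 s-1) over 30-min steps -> g CO2 m-2
an_sum_to_grams <- function(an) {
  sum(an) * sphagnum_constants$step_seconds * sphagnum_constants$mw_co2 / 1e6
}

#' Daily net primary productivity from one day of forcing
#'
#' Integrates modelled net assimilation over the 48 half-hour steps of one
#' day: `NPP_day = sum(A_N) * 1800 * 44.01 / 1e6` g CO₂ m⁻² of projected
#' capitula area.
#'
#' @param forcing_day Forcing data frame covering exactly one complete day
#'   (48 contiguous half-hour steps).
#' @param WC Water content held constant over the day.
#' @param an_params,tmoss_params Model parameter sets.
#' @return Daily NPP (g CO₂ m⁻², scalar).
#' @export
npp_day <- function(forcing_day, WC, an_params, tmoss_params) {
  if (nrow(forcing_day) != sphagnum_constants$steps_per_day)
    stop("incomplete day: need exactly ", sphagnum_constants$steps_per_day,
         " half-hour steps, got ", nrow(forcing_day))
  ts <- an_timeseries(forcing_day, WC, an_params, tmoss_params)
  an_sum_to_grams(ts$A_N)
}

#' Per-day NPP over a multi-day forcing period
#'
#' Splits the forcing at local midnight into complete days and integrates
#' each. Partial first or last days are rejected rather than prorated.
#'
#' @inheritParams an_timeseries
#' @return Data frame with one row per day: `date`, `npp` (g CO₂ m⁻² d⁻¹).
#' @export
npp_period <- function(forcing, WC, an_params, tmoss_params) {
  validate_forcing(forcing)
  day <- as.Date(format(forcing$timestamp, "%Y-%m-%d"))
  counts <- table(day)
  if (any(counts != sphagnum_constants$steps_per_day))
    stop("partial day(s) in forcing: ",
         paste(names(counts)[counts != sphagnum_constants$steps_per_day],
               collapse = ", "),
         " — provide complete days (48 steps from midnight)")
  ts <- an_timeseries(forcing, WC, an_params, tmoss_params)
  npp <- tapply(ts$A_N, day, an_sum_to_grams)
  data.frame(date = as.Date(names(npp)), npp = as.numeric(npp),
             row.names = NULL)
}
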