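#' Required columns of the raw dehydration-curve CSV dialect
#' @noRd
.curve_columns <- c("species", "curve_id", "t_min", "light", "T_set_C",
                    "PAR", "FW_g", "DW_g", "CO2R", "CO2S", "H2OR", "H2OS",
                    "flow_umol_s", "area_m2")

#' Read raw dehydration-curve recordings
#'
#' Reads the package's dehydration-curve CSV dialect: one row per
#' gas-exchange record, UTF-8, header required, columns
#' `species,curve_id,t_min,light,T_set_C,PAR,FW_g,DW_g,CO2R,CO2S,H2OR,H2OS,flow_umol_s,area_m2`
#' with `light` one of `dark`/`sat`. Missing values anywhere are an error —
#' raw curves are expected complete, not NaN-propagated.
#'
#' @param path CSV file path.
#' @return A data.frame of raw records (possibly several curves, keyed by
#'   `curve_id`).
#' @seealso [process_curve()], [generate_dehydration_curve()]
#' @export
read_dehydration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_raw_curve(df)
  df
}

#' Write raw dehydration-curve recordings
#' @param df Data frame in the raw-curve dialect.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dehydration_csv <- function(df, path) {
  validate_raw_curve(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# shared validation of the raw-curve dialect
validate_raw_curve <- function(df) {
  missing_cols <- setdiff(.curve_columns, names(df))
  if (length(missing_cols) > 0)
    stop("raw curve is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(.curve_columns, c("species", "curve_id", "light"))
  for (col in num_cols) {
    if (any(!is.finite(df[[col]])))
      stop("missing or non-finite values in column '", col,
           "' (missing values are errors in raw curves)")
  }
  if (!all(df$light %in% c("dark", "sat")))
    stop("column 'light' must be one of 'dark', 'sat'")
  invisible(df)
}

#' Process one raw dehydration curve into analysis-ready observations
#'
#' Derives, per record, the tissue water content from fresh and dry weight
#' ([water_content()]), the humidity correction factor from the IRGA water
#' vapour channels ([irga_correction_factor()]) and the corrected net
#' assimilation ([corrected_an()]). Dark-condition assimilation is also
#' reported as respiration `R_D = -A_N`.
#'
#' @param raw Data frame holding exactly one curve in the raw-curve dialect
#'   (single `curve_id`, single `light` condition, single `T_set_C`,
#'   constant `DW_g`), ≥ 3 records, ordered by `t_min`.
#' @param slope Humidity-correction slope (see [irga_correction_factor()]).
#' @return An object of class `"dehydration_curve"`: the input data frame
#'   with added columns `WC`, `F`, `A_N` (and `R_D` for dark curves), plus
#'   attributes `species`, `curve_id`, `T_set`, `light`, `DW`.
#'   Deterministic and idempotent: processing an already consistent curve
#'   again yields identical values.
#' @export
process_curve <- function(raw, slope = sphagnum_constants$irga_f_slope) {
  validate_raw_curve(raw)
  if (length(unique(raw$curve_id)) != 1)
    stop("process_curve expects a single curve (one curve_id); got ",
         length(unique(raw$curve_id)))
  if (nrow(raw) < 3)
    stop("curve too short: need >= 3 records, got ", nrow(raw))
  if (length(unique(raw$light)) != 1 || length(unique(raw$T_set_C)) != 1)
    stop("a curve must have a single light condition and chamber setpoint")
  if (is.unsorted(raw$t_min))
    stop("elapsed time t_min must be non-decreasing within a curve")
  light <- raw$light[1]
  if (light == "sat" && any(raw$PAR <= 0))
    stop("saturating-light curve must have PAR > 0 on all records")
  if (light == "dark" && any(raw$PAR != 0))
    stop("dark curve must have PAR = 0 on all records")
  out <- raw
  out$WC  <- water_content(raw$FW_g, raw$DW_g)
  out$F   <- irga_correction_factor(raw$H2OS, raw$H2OR, slope = slope)
  out$A_N <- corrected_an(raw$CO2R, raw$CO2S, raw$flow_umol_s, raw$area_m2,
                          F = out$F)
  if (light == "dark") out$R_D <- -out$A_N
  structure(out,
            species = raw$species[1], curve_id = raw$curve_id[1],
            T_set = raw$T_set_C[1], light = light, DW = raw$DW_g[1],
            f_slope = slope,
            class = c("dehydration_curve", "data.frame"))
}

#' Summarise a processed dehydration curve
#'
#' Locates the assimilation maximum on the observed records (no
#' interpolation) and the water content at which net assimilation crosses
#' zero during drying, by linear interpolation between the bracketing
#' records (absent — `NA` — if A_N never changes sign along the curve).
#'
#' @param curve A `"dehydration_curve"` from [process_curve()].
#' @return A list: `WC_at_max_AN`, `max_AN`, `WC_at_zero_AN` (NA when no
#'   sign change).
#' @export
curve_summary <- function(curve) {
  if (!inherits(curve, "dehydration_curve") || is.null(curve$A_N))
    stop("curve_summary needs a processed dehydration_curve ",
         "(run process_curve first)")
  i_max <- which.max(curve$A_N)
  wc_zero <- NA_real_
  s <- sign(curve$A_N)
  cross <- which(s[-1] * s[-length(s)] < 0)
  if (any(curve$A_N == 0)) {
    wc_zero <- curve$WC[which(curve$A_N == 0)[1]]
  } else if (length(cross) > 0) {
    ii <- cross[1]  # first sign change along the drying trajectory
    a1 <- curve$A_N[ii]; a2 <- curve$A_N[ii + 1]
    w1 <- curve$WC[ii];  w2 <- curve$WC[ii + 1]
    wc_zero <- w1 + (0 - a1) * (w2 - w1) / (a2 - a1)
  }
  list(WC_at_max_AN = curve$WC[i_max],
       max_AN = curve$A_N[i_max],
       WC_at_zero_AN = wc_zero)
}

#' Pool processed curves into calibration observations
#'
#' Splits a set of processed curves into the two calibration datasets of the
#' two-step procedure: dark observations `(T_moss, WC, R_D)` and
#' saturating-light observations `(T_moss, WC, PAR, A_N)`. The chamber
#' setpoint serves as the moss temperature for chamber data.
#'
#' @param curves A list of `"dehydration_curve"` objects.
#' @return A list of two data frames, `dark` and `light`.
#' @export
curves_to_observations <- function(curves) {
  stopifnot(all(vapply(curves, inherits, TRUE, "dehydration_curve")))
  dark_list <- list(); light_list <- list()
  for (cu in curves) {
    if (attr(cu, "light") == "dark") {
      dark_list[[length(dark_list) + 1L]] <-
        data.frame(T_moss = cu$T_set_C, WC = cu$WC, R_D = cu$R_D)
    } else {
      light_list[[length(light_list) + 1L]] <-
        data.frame(T_moss = cu$T_set_C, WC = cu$WC, PAR = cu$PAR,
                   A_N = cu$A_N)
    }
  }
  list(dark = do.call(rbind, dark_list), light = do.call(rbind, light_list))
}
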