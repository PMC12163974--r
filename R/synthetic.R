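#' Configuration of the synthetic-data generators
#'
#' Collects the ground-truth parameters and study-design settings that the
#' generators emulate: chamber dehydration curves at five setpoint
#' temperatures with five biological replicates each, field
#' canopy-temperature observations, and a July boreal diurnal meteorology
#' (night minimum 12.4 °C at 03:00, midday maximum 19.4 °C at 14:00, peak
#' PAR 750 μmol m⁻² s⁻¹ over a 20.5 h photoperiod).
#'
#' The dehydration rate is interpreted as g H₂O g⁻¹ DW min⁻¹ in the range
#' 0.097–0.25, interpolated linearly across the chamber temperatures
#' (hotter chambers dry faster), which brings an initially oversaturated
#' sample (WC 17) down through the physiological range within the ~2 h of
#' a measurement cycle.
#'
#' @param an_params True assimilation parameters
#'   (default [an_params_synthetic()]).
#' @param tmoss_params True canopy-temperature parameters
#'   (default [tmoss_params_hyytiala()]).
#' @param chamber_temps Chamber setpoints (°C).
#' @param replicates Biological replicates per setpoint and light condition.
#' @param wc_initial Initial water content of the oversaturated sample.
#' @param wc_final Water content at which a curve stops.
#' @param dehydration_rates Range (g g⁻¹ min⁻¹) mapped linearly onto
#'   `chamber_temps`.
#' @param sample_interval_min Minutes between gas-exchange records.
#' @param max_duration_min Maximum curve duration.
#' @param sd_an_light,sd_an_dark Gaussian noise SD on light/dark net
#'   assimilation (μmol m⁻² s⁻¹).
#' @param sd_tmoss Gaussian noise SD on field moss temperature (°C).
#' @param DW Sample dry weight (g).
#' @param PAR_sat Saturating chamber irradiance (μmol m⁻² s⁻¹).
#' @param CO2R Reference CO₂ of the incoming air (μmol mol⁻¹).
#' @param flow Chamber flow (μmol air s⁻¹).
#' @param area Projected capitula area (m²).
#' @param night_min_T,day_max_T Diurnal air-temperature extremes (°C).
#' @param t_min_hour,t_max_hour Hours of the daily extremes.
#' @param peak_par Midday PAR maximum (μmol m⁻² s⁻¹).
#' @param daylength Hours of non-zero PAR per day.
#' @param days Days of meteorology to generate.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(an_params = an_params_synthetic(),
                             tmoss_params = tmoss_params_hyytiala(),
                             chamber_temps = c(15, 20, 25, 30, 35),
                             replicates = 5,
                             wc_initial = 17, wc_final = 0.5,
                             dehydration_rates = c(0.097, 0.25),
                             sample_interval_min = 5,
                             max_duration_min = 120,
                             sd_an_light = 0.15, sd_an_dark = 0.05,
                             sd_tmoss = 1.0,
                             DW = 0.2, PAR_sat = 800,
                             CO2R = 420, flow = 400, area = 6e-4,
                             night_min_T = 12.4, day_max_T = 19.4,
                             t_min_hour = 3, t_max_hour = 14,
                             peak_par = 750, daylength = 20.5,
                             days = 14) {
  stopifnot(inherits(an_params, "an_params"),
            inherits(tmoss_params, "tmoss_params"),
            sd_an_light >= 0, sd_an_dark >= 0, sd_tmoss >= 0,
            daylength > 0, daylength <= 24,
            wc_initial > wc_final, wc_final > 0)
  structure(as.list(environment()), class = "generator_config")
}

# Per-setpoint dehydration rate: linear across the chamber-temperature range.
.dehydration_rate <- function(config, T_set) {
  tr <- range(config$chamber_temps)
  frac <- if (diff(tr) == 0) 0.5 else (T_set - tr[1]) / diff(tr)
  config$dehydration_rates[1] +
    frac * diff(config$dehydration_rates)
}

#' Generate one raw synthetic dehydration curve
#'
#' Simulates a rehydrated sample drying inside the gas-exchange chamber at
#' one setpoint temperature under darkness or saturating light. Water
#' content declines linearly at the configured rate; the true net
#' assimilation comes from the full model (−R_D in darkness) plus Gaussian
#' noise. The IRGA readings are then reverse-engineered so that
#' [process_curve()] reproduces the noisy assimilation exactly: the sample
#' humidity is drawn to vary the correction factor realistically in
#' [1, 1.03] and the sample CO₂ is solved from the corrected-assimilation
#' formula given flow, area and that correction factor. This exercises the
#' humidity-correction and flux equations in every end-to-end test.
#'
#' @param config A [generator_config()].
#' @param T_set Chamber setpoint (one of `config$chamber_temps`).
#' @param light_condition `"sat"` or `"dark"`.
#' @param seed RNG seed; same inputs give bit-identical rows.
#' @param curve_id Identifier written into the rows.
#' @return A raw-curve data frame in the dialect of
#'   [read_dehydration_csv()], with attribute `true_an` (the noiseless
#'   model values).
#' @export
generate_dehydration_curve <- function(config, T_set,
                                       light_condition = c("sat", "dark"),
                                       seed = 1, curve_id = "c1") {
  stopifnot(inherits(config, "generator_config"))
  light_condition <- match.arg(light_condition)
  rate <- .dehydration_rate(config, T_set)
  t_min <- seq(0, config$max_duration_min, by = config$sample_interval_min)
  wc <- config$wc_initial - rate * t_min
  keep <- wc >= config$wc_final
  t_min <- t_min[keep]; wc <- wc[keep]
  par <- if (light_condition == "sat") config$PAR_sat else 0
  true_an <- if (light_condition == "sat") {
    predict_an(T_set, wc, par, config$an_params, clamp_rd = FALSE)
  } else {
    -rd_surface(T_set, wc, config$an_params)
  }
  sd_an <- if (light_condition == "sat") config$sd_an_light else
    config$sd_an_dark
  n <- length(t_min)
  draws <- withr_local_seed(seed, {
    list(noise = stats::rnorm(n, 0, sd_an),
         h2os = stats::runif(n, 0, 30))
  })
  an_noisy <- true_an + draws$noise
  F <- irga_correction_factor(draws$h2os, 0)
  # invert A_N = flow_mol * (CO2R - CO2S*F) / area for CO2S
  co2s <- (config$CO2R - an_noisy * config$area / (config$flow * 1e-6)) / F
  out <- data.frame(
    species = config$an_params$species, curve_id = curve_id,
    t_min = t_min, light = light_condition, T_set_C = T_set, PAR = par,
    FW_g = config$DW * (1 + wc), DW_g = config$DW,
    CO2R = config$CO2R, CO2S = co2s, H2OR = 0, H2OS = draws$h2os,
    flow_umol_s = config$flow, area_m2 = config$area,
    stringsAsFactors = FALSE)
  attr(out, "true_an") <- true_an
  out
}

#' Generate the full synthetic dehydration-curve dataset
#'
#' The chamber study design: every setpoint temperature × replicate ×
#' light condition, each as one curve with its own derived seed.
#'
#' @param config A [generator_config()].
#' @param seed Base seed; curve `i` uses `seed * 1000 + i` (keep
#'   `seed` below ~2e6 so derived seeds stay within integer range).
#' @return A list of raw-curve data frames.
#' @export
generate_dehydration_dataset <- function(config, seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  curves <- list()
  i <- 0L
  for (light in c("dark", "sat")) {
    for (T_set in config$chamber_temps) {
      for (rep in seq_len(config$replicates)) {
        i <- i + 1L
        curves[[i]] <- generate_dehydration_curve(
          config, T_set, light, seed = seed * 1000 + i,
          curve_id = sprintf("%s_T%g_r%d", light, T_set, rep))
      }
    }
  }
  curves
}

#' Generate synthetic field canopy-temperature observations
#'
#' Covariates drawn uniformly over their field ranges; moss surface
#' temperature from the true canopy model plus Gaussian noise.
#'
#' @param config A [generator_config()] (truth and noise SD).
#' @param n Number of observations.
#' @param T_air_range,PAR_range,WC_range Sampling ranges (field defaults:
#'   air 13–26 °C, PAR 0–1600, WC 1–17).
#' @param seed RNG seed.
#' @return A data frame with columns `T_air`, `PAR`, `WC`, `T_moss`.
#' @export
generate_field_observations <- function(config, n = 200,
                                        T_air_range = c(13, 26),
                                        PAR_range = c(0, 1600),
                                        WC_range = c(1, 17),
                                        seed = 1) {
  stopifnot(inherits(config, "generator_config"), n >= 1)
  for (rg in list(T_air_range, PAR_range, WC_range))
    if (diff(rg) <= 0) stop("config error: degenerate covariate range")
  withr_local_seed(seed, {
    T_air <- stats::runif(n, T_air_range[1], T_air_range[2])
    PAR <- stats::runif(n, PAR_range[1], PAR_range[2])
    WC <- stats::runif(n, WC_range[1], WC_range[2])
    T_moss <- tmoss_model(T_air, PAR, WC, config$tmoss_params) +
      stats::rnorm(n, 0, config$sd_tmoss)
    data.frame(T_air = T_air, PAR = PAR, WC = WC, T_moss = T_moss)
  })
}

#' Generate synthetic half-hourly boreal summer meteorology
#'
#' Emulates the July forcing regime: air temperature follows a piecewise
#' half-cosine between the nightly minimum (03:00 by default) and the
#' afternoon maximum (14:00) — a single sinusoid cannot place extremes
#' 11 h apart, so the rise and fall are separate half-cosines that hit both
#' stated extremes exactly. PAR is a half-sine over the photoperiod window
#' centred on solar noon, peaking at `peak_par` and exactly zero outside
#' the window (24 − daylength hours per day). A 24 h photoperiod is treated
#' as midnight sun: PAR is floored at its half-step twilight value so no
#' step is fully dark. Optional day-to-day Gaussian jitter offsets each
#' day's temperatures.
#'
#' @param config A [generator_config()].
#' @param start Date of the first day.
#' @param jitter_sd_T Day-to-day SD of a whole-day temperature offset (°C);
#'   0 (default) makes all days identical.
#' @param seed RNG seed (used only when `jitter_sd_T > 0`).
#' @return A forcing data frame (`timestamp`, `T_air`, `PAR`) of
#'   `config$days` complete days.
#' @export
generate_meteorology <- function(config, start = "2023-07-03",
                                 jitter_sd_T = 0, seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  h <- seq(0, 23.5, by = 0.5)
  t_min <- config$t_min_hour; t_max <- config$t_max_hour
  Tmin <- config$night_min_T; Tmax <- config$day_max_T
  rise_len <- (t_max - t_min) %% 24
  fall_len <- 24 - rise_len
  phase <- (h - t_min) %% 24
  frac <- ifelse(phase <= rise_len,
                 (1 - cos(pi * phase / rise_len)) / 2,
                 (1 + cos(pi * (phase - rise_len) / fall_len)) / 2)
  T_day_profile <- Tmin + (Tmax - Tmin) * frac
  win_start <- 12 - config$daylength / 2
  par_profile <- ifelse(
    h > win_start & h < win_start + config$daylength,
    config$peak_par * sin(pi * (h - win_start) / config$daylength), 0)
  if (config$daylength >= 24) {
    # midnight sun: the sky never goes fully dark, so PAR is floored at the
    # half-sine's value half a grid step inside the window
    twilight <- config$peak_par * sin(pi * 0.25 / config$daylength)
    par_profile <- pmax(par_profile, twilight)
  }
  offsets <- if (jitter_sd_T > 0) {
    withr_local_seed(seed, stats::rnorm(config$days, 0, jitter_sd_T))
  } else rep(0, config$days)
  t0 <- as.POSIXct(start, tz = "UTC")
  out <- do.call(rbind, lapply(seq_len(config$days), function(d) {
    data.frame(timestamp = t0 + ((d - 1) * 24 + h) * 3600,
               T_air = T_day_profile + offsets[d],
               PAR = par_profile)
  }))
  validate_forcing(out)
  out
}
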