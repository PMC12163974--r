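#' Square-wave day/night forcing for photoperiod and night-temperature runs
#'
#' Builds one synthetic day of half-hourly forcing with set values instead
#' of meteorological data: light steps carry `(T_day, PAR_day)`, dark steps
#' `(T_night, 0)`. The light window is centred on noon.
#'
#' @param day_hours,night_hours Photoperiod split; must sum to 24 h in
#'   multiples of 0.5 h.
#' @param T_day,T_night Day and night air temperatures (°C).
#' @param PAR_day Daytime irradiance (μmol m⁻² s⁻¹), default 800
#'   (saturating).
#' @param date Calendar date of the synthetic day.
#' @return A forcing data frame of 48 half-hour steps.
#' @export
square_wave_forcing <- function(day_hours, night_hours,
                                T_day = 25, T_night = 15, PAR_day = 800,
                                date = "2023-07-03") {
  if (!isTRUE(all.equal(day_hours + night_hours, 24)))
    stop("photoperiod config error: day and night hours must sum to 24")
  if (day_hours < 0 || night_hours < 0 ||
      day_hours %% 0.5 != 0 || night_hours %% 0.5 != 0)
    stop("photoperiod config error: hours must be non-negative multiples of 0.5")
  hours <- seq(0, 23.5, by = 0.5)
  light <- hours >= 12 - day_hours / 2 & hours < 12 + day_hours / 2
  data.frame(
    timestamp = as.POSIXct(date, tz = "UTC") + hours * 3600,
    T_air = ifelse(light, T_day, T_night),
    PAR = ifelse(light, PAR_day, 0))
}

#' Apply one scenario point to a forcing period
#'
#' Produces the modified forcing and water-content policy for a single
#' point of a scenario sweep:
#' \describe{
#'   \item{`wc_sweep`}{forcing unchanged; WC fixed at the sweep value.}
#'   \item{`tair_offset`}{the offset is added to every air temperature
#'     before the canopy-temperature model; WC at the species optimum
#'     unless overridden.}
#'   \item{`par_factor`}{every PAR value is multiplied before both the
#'     warming term and the light response (the temperature and
#'     assimilation effects of radiation are coupled).}
#'   \item{`photoperiod`}{meteorological forcing is replaced by a
#'     square-wave day (`value = c(day_hours, night_hours)`).}
#'   \item{`night_temperature`}{square-wave day with
#'     `value = c(T_day, T_night)` at the scenario photoperiod.}
#' }
#'
#' @param forcing Base forcing data frame (ignored for the square-wave
#'   kinds).
#' @param kind Scenario kind (see above).
#' @param value Sweep value: scalar for `wc_sweep`/`tair_offset`/
#'   `par_factor`, length-2 numeric for the square-wave kinds.
#' @param wc Water-content policy: fixed value, or `NULL` to use the
#'   species optimum from `an_params`.
#' @param an_params Parameter set used to resolve the optimum WC when
#'   `wc = NULL`.
#' @param T_day,T_night,PAR_day,photoperiod Square-wave settings (defaults:
#'   25/15 °C, PAR 800, 20/4 h).
#' @return A list with elements `forcing` and `WC`.
#' @export
apply_scenario <- function(forcing, kind, value, wc = NULL, an_params = NULL,
                           T_day = 25, T_night = 15, PAR_day = 800,
                           photoperiod = c(20, 4)) {
  resolve_wc <- function() {
    if (!is.null(wc)) return(wc)
    if (is.null(an_params))
      stop("config error: supply a fixed wc or an_params for the optimum")
    optimum_wc(an_params)
  }
  switch(kind,
    wc_sweep = {
      stopifnot(length(value) == 1)
      list(forcing = forcing, WC = value)
    },
    tair_offset = {
      stopifnot(length(value) == 1)
      f <- forcing; f$T_air <- f$T_air + value
      list(forcing = f, WC = resolve_wc())
    },
    par_factor = {
      stopifnot(length(value) == 1, value >= 0)
      f <- forcing; f$PAR <- f$PAR * value
      list(forcing = f, WC = resolve_wc())
    },
    photoperiod = {
      stopifnot(length(value) == 2)
      list(forcing = square_wave_forcing(value[1], value[2],
                                         T_day = T_day, T_night = T_night,
                                         PAR_day = PAR_day),
           WC = resolve_wc())
    },
    night_temperature = {
      stopifnot(length(value) == 2)
      list(forcing = square_wave_forcing(photoperiod[1], photoperiod[2],
                                         T_day = value[1], T_night = value[2],
                                         PAR_day = PAR_day),
           WC = resolve_wc())
    },
    stop("config error: unknown scenario kind '", kind, "'")
  )
}

# Evaluate the prediction pipeline for an arbitrary coefficient draw
# (the draw may leave the constructor-validated region, so the surfaces are
# evaluated directly). R_D is clamped at zero, the prediction convention.
an_series_from_draw <- function(T_air, PAR, WC, th, grouping, log_base, AQE) {
  lw <- .model_log(WC, log_base)
  T_moss <- T_air + th[["j"]] * PAR^2 + th[["k"]] * PAR + th[["l"]] +
    th[["m"]] * lw
  rd <- exp(th[["f"]] + sphagnum_constants$heskel_b * T_moss +
              sphagnum_constants$heskel_c * T_moss^2) -
    th[["g"]] * WC + th[["h"]] + th[["i"]] * lw * T_moss
  rd <- pmax(rd, 0)
  tpoly <- th[["a"]] * T_moss^2 + th[["b"]] * T_moss + th[["c"]]
  wcpoly <- -th[["d"]] * WC^2 + th[["e"]] * WC
  asat <- if (grouping == "multiplicative") tpoly * wcpoly else tpoly + wcpoly
  gross <- asat + rd
  gross * PAR * AQE / sqrt(AQE^2 * PAR^2 + gross^2) - rd
}

#' Parametric-bootstrap uncertainty of period NPP
#'
#' Propagates parameter uncertainty through the NPP integration: each draw
#' samples every model coefficient `a`–`m` independently from a normal
#' distribution with its fitted mean and standard deviation, holds the draw
#' fixed across all timesteps of the period, and computes the period NPP.
#' The reported uncertainty is the standard deviation of period NPP across
#' draws (parameter uncertainty treated as fully time-correlated). A
#' per-timestep variant — averaging the draws per half-hour record and
#' summing the per-record standard deviations over the period — is
#' available via `per_timestep = TRUE` for comparison.
#'
#' @param forcing Forcing data frame covering complete days.
#' @param WC Water content held constant over the period.
#' @param an_params,tmoss_params Mean parameter sets.
#' @param an_sds Named SDs for any of `a`–`i` (missing names default to 0).
#' @param tmoss_sds Named SDs for any of `j`–`m` (missing default 0).
#' @param n_draws Number of bootstrap draws (default 1000).
#' @param seed RNG seed; fixed seed gives bit-identical results.
#' @param per_timestep Use the per-record aggregation variant?
#' @return A list of class `"npp_boot"`: `npp_total` and `npp_days` (point
#'   estimates at the mean parameters), `boot_mean`, `boot_sd` (period
#'   totals), `n_draws`, `seed`, `per_timestep`.
#' @export
bootstrap_npp <- function(forcing, WC, an_params, tmoss_params,
                          an_sds = NULL, tmoss_sds = NULL,
                          n_draws = 1000, seed = 1, per_timestep = FALSE) {
  stopifnot(inherits(an_params, "an_params"),
            inherits(tmoss_params, "tmoss_params"))
  if (n_draws < 2) stop("invalid input: n_draws must be >= 2")
  point_days <- npp_period(forcing, WC, an_params, tmoss_params)

  an_names <- c("a", "b", "c", "d", "e", "f", "g", "h", "i")
  tm_names <- c("j", "k", "l", "m")
  means <- c(unlist(an_params[an_names]), unlist(tmoss_params[tm_names]))
  sds <- stats::setNames(numeric(13), c(an_names, tm_names))
  if (!is.null(an_sds)) sds[names(an_sds)[names(an_sds) %in% an_names]] <-
      an_sds[names(an_sds) %in% an_names]
  if (!is.null(tmoss_sds)) sds[names(tmoss_sds)[names(tmoss_sds) %in% tm_names]] <-
      tmoss_sds[names(tmoss_sds) %in% tm_names]
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("invalid input: parameter SDs must be finite and >= 0")

  n_steps <- nrow(forcing)
  draws_an <- matrix(NA_real_, nrow = n_draws, ncol = n_steps)
  draw_mat <- withr_local_seed(seed, {
    m <- matrix(stats::rnorm(n_draws * 13, mean = rep(means, each = n_draws),
                             sd = rep(sds, each = n_draws)),
                nrow = n_draws)
    colnames(m) <- c(an_names, tm_names)
    m
  })
  for (b in seq_len(n_draws)) {
    draws_an[b, ] <- an_series_from_draw(
      forcing$T_air, forcing$PAR, WC, draw_mat[b, ],
      grouping = an_params$grouping, log_base = an_params$log_base,
      AQE = an_params$AQE)
  }
  per_draw_npp <- apply(draws_an, 1, an_sum_to_grams)
  if (per_timestep) {
    step_mean <- colMeans(draws_an)
    step_sd <- apply(draws_an, 2, stats::sd)
    boot_mean <- an_sum_to_grams(step_mean)
    boot_sd <- an_sum_to_grams(step_sd)
  } else {
    boot_mean <- mean(per_draw_npp)
    boot_sd <- stats::sd(per_draw_npp)
  }
  structure(list(npp_total = sum(point_days$npp), npp_days = point_days,
                 boot_mean = boot_mean, boot_sd = boot_sd,
                 n_draws = n_draws, seed = seed,
                 per_timestep = per_timestep),
            class = "npp_boot")
}

#' @export
print.npp_boot <- function(x, ...) {
  cat(sprintf(
    "Period NPP %.3f g CO2 m-2 over %d day(s); bootstrap %.3f +/- %.3f (n=%d, seed=%d%s)\n",
    x$npp_total, nrow(x$npp_days), x$boot_mean, x$boot_sd, x$n_draws,
    x$seed, if (x$per_timestep) ", per-timestep" else ""))
  invisible(x)
}

#' Run a scenario sweep with bootstrap uncertainty
#'
#' Evaluates one scenario family over its sweep values: each point modifies
#' the forcing or builds a square-wave day via [apply_scenario()], then the
#' period NPP and its bootstrap uncertainty are computed. Results carry
#' scenario coordinates, seeds and the parameter-set configuration.
#'
#' @param forcing Base forcing (meteorological kinds) or `NULL` for the
#'   square-wave kinds.
#' @param kind Scenario kind, as in [apply_scenario()].
#' @param values Sweep values: numeric vector, or list of length-2 numerics
#'   for the square-wave kinds.
#' @param an_params,tmoss_params Mean parameter sets.
#' @param an_sds,tmoss_sds Parameter SDs (both `NULL` skips the bootstrap).
#' @param n_draws,seed Bootstrap control; sweep point `i` uses `seed + i - 1`.
#' @param wc Fixed water content, or `NULL` for the species optimum.
#' @param ... Square-wave settings forwarded to [apply_scenario()].
#' @return A data frame with one row per sweep value: `kind`, `value`
#'   (label), `v1`, `v2`, `WC`, `days`, `npp_total`, `npp_day_mean`,
#'   `npp_day_max`, `boot_mean`, `boot_sd`, `n_draws`, `seed`, `grouping`,
#'   `log_base`.
#' @export
run_scenario_sweep <- function(forcing, kind, values, an_params, tmoss_params,
                               an_sds = NULL, tmoss_sds = NULL,
                               n_draws = 1000, seed = 1, wc = NULL, ...) {
  if (!is.list(values)) values <- as.list(values)
  rows <- vector("list", length(values))
  for (idx in seq_along(values)) {
    val <- values[[idx]]
    pt <- apply_scenario(forcing, kind, val, wc = wc, an_params = an_params,
                         ...)
    seed_i <- seed + idx - 1L
    if (is.null(an_sds) && is.null(tmoss_sds)) {
      days <- npp_period(pt$forcing, pt$WC, an_params, tmoss_params)
      boot_mean <- sum(days$npp); boot_sd <- 0; nd <- 0L
      total <- sum(days$npp)
    } else {
      bt <- bootstrap_npp(pt$forcing, pt$WC, an_params, tmoss_params,
                          an_sds = an_sds, tmoss_sds = tmoss_sds,
                          n_draws = n_draws, seed = seed_i)
      days <- bt$npp_days; total <- bt$npp_total
      boot_mean <- bt$boot_mean; boot_sd <- bt$boot_sd; nd <- n_draws
    }
    rows[[idx]] <- data.frame(
      kind = kind,
      value = paste(val, collapse = "/"),
      v1 = val[1], v2 = if (length(val) > 1) val[2] else NA_real_,
      WC = pt$WC, days = nrow(days),
      npp_total = total, npp_day_mean = mean(days$npp),
      npp_day_max = max(days$npp),
      boot_mean = boot_mean, boot_sd = boot_sd,
      n_draws = nd, seed = seed_i,
      grouping = an_params$grouping, log_base = an_params$log_base,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
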