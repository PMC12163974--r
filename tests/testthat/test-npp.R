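test_that("daily integration applies the flux-to-mass unit conversion", {
  # constant 1 umol m-2 s-1 over 48 half-hour steps
  expect_equal(sphagnumflux:::an_sum_to_grams(rep(1, 48)),
               86400 * 44.01 / 1e6)
  expect_equal(sphagnumflux:::an_sum_to_grams(rep(1, 48)), 3.80246,
               tolerance = 1e-5)
  expect_equal(sphagnumflux:::an_sum_to_grams(rep(0, 48)), 0)
  # linearity: scaling the flux scales the mass
  set.seed(2); an <- rnorm(48)
  expect_equal(sphagnumflux:::an_sum_to_grams(3 * an),
               3 * sphagnumflux:::an_sum_to_grams(an))
})

test_that("npp_day demands a complete day and respires all-dark days", {
  p <- truth_an(); tp <- truth_tmoss()
  dark_day <- square_wave_forcing(0, 24, T_night = 15)
  expect_lt(npp_day(dark_day, 7.2, p, tp), 0)
  expect_error(npp_day(dark_day[1:47, ], 7.2, p, tp), "incomplete day")
  gap <- dark_day[-10, ]
  expect_error(npp_period(gap, 7.2, p, tp), "04:30")
  expect_error(npp_day(dark_day, -1, p, tp), "WC")
})

test_that("period NPP is the sum of its daily NPPs", {
  cfg <- generator_config(days = 3)
  met <- generate_meteorology(cfg)
  p <- truth_an(); tp <- truth_tmoss()
  days <- npp_period(met, 7.2, p, tp)
  expect_equal(nrow(days), 3)
  by_hand <- vapply(0:2, function(d) {
    npp_day(met[(d * 48 + 1):((d + 1) * 48), ], 7.2, p, tp)
  }, numeric(1))
  expect_equal(days$npp, by_hand)
  # partial days are rejected, not prorated
  expect_error(npp_period(met[25:nrow(met), ], 7.2, p, tp), "partial day")
})

test_that("scenario modifications act exactly as defined", {
  cfg <- generator_config(days = 1)
  met <- generate_meteorology(cfg)
  p <- truth_an(); tp <- truth_tmoss()
  id1 <- apply_scenario(met, "tair_offset", 0, an_params = p)
  id2 <- apply_scenario(met, "par_factor", 1, an_params = p)
  expect_identical(id1$forcing, met)
  expect_identical(id2$forcing, met)
  expect_equal(id1$WC, optimum_wc(p))
  # +5 degC offset shifts every T_moss by exactly +5 at fixed PAR and WC
  off <- apply_scenario(met, "tair_offset", 5, an_params = p)
  ts0 <- an_timeseries(met, 7.2, p, tp)
  ts5 <- an_timeseries(off$forcing, 7.2, p, tp)
  expect_equal(ts5$T_moss, ts0$T_moss + 5)
  # PAR factor applies to both the warming term and the light response
  fac <- apply_scenario(met, "par_factor", 1.3, an_params = p)
  i750 <- which(met$PAR == 750)
  expect_equal(fac$forcing$PAR[i750], 975)
  tsf <- an_timeseries(fac$forcing, 7.2, p, tp)
  expect_equal(tsf$T_moss[i750],
               tmoss_model(met$T_air[i750], 975, 7.2, tp))
  expect_error(apply_scenario(met, "volcano", 1, wc = 7.2), "unknown")
  expect_error(apply_scenario(met, "tair_offset", 1), "config error")
})

test_that("square-wave days honour the photoperiod split", {
  sw <- square_wave_forcing(12, 12)
  expect_equal(sum(sw$PAR > 0), 24)
  expect_equal(sum(sw$PAR == 0), 24)
  sw2 <- square_wave_forcing(20, 4, T_day = 25, T_night = 15, PAR_day = 800)
  expect_equal(sum(sw2$PAR == 800 & sw2$T_air == 25), 40)
  expect_equal(sum(sw2$PAR == 0 & sw2$T_air == 15), 8)
  expect_error(square_wave_forcing(20, 5), "sum to 24")
  expect_error(square_wave_forcing(20.25, 3.75), "multiples of 0.5")
})

test_that("longer photoperiods always fix more carbon", {
  p <- truth_an(); tp <- truth_tmoss()
  sweep <- run_scenario_sweep(NULL, "photoperiod",
                              list(c(12, 12), c(18, 6), c(20, 4), c(24, 0)),
                              p, tp)
  expect_true(all(diff(sweep$npp_total) > 0))
})

test_that("warmer nights weakly reduce daily carbon gain", {
  p <- truth_an(); tp <- truth_tmoss()
  sweep <- run_scenario_sweep(NULL, "night_temperature",
                              list(c(25, 15), c(25, 20), c(25, 25)),
                              p, tp)
  expect_true(all(diff(sweep$npp_total) <= 0))
})

test_that("the water-content sweep peaks at the surface optimum", {
  # run at a saturating-light day near the temperature optimum, where the
  # water-content response is not confounded by the canopy cooling that
  # drier moss experiences under cool forcing
  day <- square_wave_forcing(20, 4, T_day = 25, T_night = 15, PAR_day = 800)
  p <- truth_an(); tp <- truth_tmoss()
  sweep <- run_scenario_sweep(day, "wc_sweep", c(4.5, 7.2, 17), p, tp)
  expect_equal(sweep$v1[which.max(sweep$npp_total)], 7.2)
})

test_that("bootstrap collapses to the point estimate without uncertainty", {
  cfg <- generator_config(days = 2)
  met <- generate_meteorology(cfg)
  p <- truth_an(); tp <- truth_tmoss()
  b <- bootstrap_npp(met, 7.2, p, tp, n_draws = 50, seed = 3)
  expect_equal(b$boot_mean, b$npp_total)
  expect_equal(b$boot_sd, 0)
})

test_that("bootstrap is bit-identical under a fixed seed", {
  cfg <- generator_config(days = 1)
  met <- generate_meteorology(cfg)
  p <- truth_an(); tp <- truth_tmoss()
  sds <- list(an = c(a = 0.002, e = 0.05), tm = c(m = 0.2))
  b1 <- bootstrap_npp(met, 7.2, p, tp, an_sds = sds$an, tmoss_sds = sds$tm,
                      n_draws = 200, seed = 11)
  b2 <- bootstrap_npp(met, 7.2, p, tp, an_sds = sds$an, tmoss_sds = sds$tm,
                      n_draws = 200, seed = 11)
  expect_identical(b1, b2)
  b3 <- bootstrap_npp(met, 7.2, p, tp, an_sds = sds$an, tmoss_sds = sds$tm,
                      n_draws = 200, seed = 12)
  expect_false(identical(b1$boot_mean, b3$boot_mean))
})

test_that("a single uncertain parameter spreads but does not shift NPP", {
  cfg <- generator_config(days = 1)
  met <- generate_meteorology(cfg)
  p <- truth_an(); tp <- truth_tmoss()
  # 10% uncertainty on the WC-scale coefficient e alone
  b <- bootstrap_npp(met, 7.2, p, tp, an_sds = c(e = 0.1 * p$e),
                     n_draws = 1000, seed = 7)
  expect_gt(b$boot_sd, 0)
  se <- b$boot_sd / sqrt(b$n_draws)
  expect_lt(abs(b$boot_mean - b$npp_total), 3 * se)
  # per-timestep aggregation runs and reports a non-negative spread
  bt <- bootstrap_npp(met, 7.2, p, tp, an_sds = c(e = 0.1 * p$e),
                      n_draws = 200, seed = 7, per_timestep = TRUE)
  expect_gt(bt$boot_sd, 0)
  expect_error(bootstrap_npp(met, 7.2, p, tp, an_sds = c(e = -1),
                             n_draws = 10, seed = 1), "SDs")
  expect_error(bootstrap_npp(met, 7.2, p, tp, n_draws = 1, seed = 1),
               "n_draws")
})

test_that("bootstrap spread stabilises as draws grow", {
  cfg <- generator_config(days = 1)
  met <- generate_meteorology(cfg)
  p <- truth_an(); tp <- truth_tmoss()
  sd_across_seeds <- function(n_draws) {
    sd(vapply(1:6, function(s) {
      bootstrap_npp(met, 7.2, p, tp, an_sds = c(e = 0.05),
                    n_draws = n_draws, seed = s)$boot_sd
    }, numeric(1)))
  }
  expect_lt(sd_across_seeds(400), sd_across_seeds(25))
})

test_that("forcing CSV round-trips and flags gaps by timestamp", {
  cfg <- generator_config(days = 2)
  met <- generate_meteorology(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_meteo_csv(met, path)
  back <- read_meteo_csv(path)
  expect_equal(back$T_air, met$T_air, tolerance = 1e-9)
  expect_equal(as.numeric(back$timestamp), as.numeric(met$timestamp))
  gap <- met[-5, ]
  expect_error(write_meteo_csv(gap, path), "02:00")
})
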