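# shared synthetic observation builders ------------------------------------

dark_obs_from_truth <- function(p = truth_an(), noise_sd = 0, seed = 1) {
  grid <- expand.grid(T_moss = c(15, 20, 25, 30, 35),
                      WC = seq(0.5, 16, by = 0.5))
  set.seed(seed)
  grid$R_D <- rd_surface(grid$T_moss, grid$WC, p) +
    rnorm(nrow(grid), 0, noise_sd)
  grid
}

light_obs_from_truth <- function(p = truth_an(), noise_sd = 0, seed = 1) {
  grid <- expand.grid(T_moss = c(15, 20, 25, 30, 35),
                      WC = seq(0.5, 16, by = 0.5))
  grid$PAR <- 800
  set.seed(seed)
  grid$A_N <- predict_an(grid$T_moss, grid$WC, grid$PAR, p,
                         clamp_rd = FALSE) + rnorm(nrow(grid), 0, noise_sd)
  grid
}

test_that("respiration parameters are recovered from noiseless dark data", {
  p <- truth_an()
  fit <- fit_rd_params(dark_obs_from_truth(p))
  expect_true(fit$converged)
  expect_equal(coef(fit), c(f = p$f, g = p$g, h = p$h, i = p$i),
               tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("noisy dark data recovery stays within posterior uncertainty", {
  p <- truth_an()
  fit <- fit_rd_params(dark_obs_from_truth(p, noise_sd = 0.05, seed = 9))
  truthv <- c(f = p$f, g = p$g, h = p$h, i = p$i)
  expect_true(all(abs(coef(fit) - truthv) <= 3 * fit$sd))
  expect_true(all(fit$sd >= 0))
  expect_gte(fit$r_squared, 0)
  expect_lte(fit$r_squared, 1)
})

test_that("degenerate dark designs raise rank-deficiency errors", {
  one_point <- data.frame(T_moss = rep(25, 10), WC = rep(5, 10),
                          R_D = rep(0.8, 10))
  expect_error(fit_rd_params(one_point), "rank-deficiency")
  expect_error(fit_rd_params(dark_obs_from_truth()[1:5, ]), ">= 8")
})

test_that("A_sat parameters are recovered noiselessly in the normalised convention", {
  p <- truth_an()
  rd_fixed <- c(f = p$f, g = p$g, h = p$h, i = p$i)
  fit <- fit_asat_params(light_obs_from_truth(p), rd_fixed, AQE = p$AQE)
  expect_true(fit$converged)
  # the truth T-polynomial already has vertex value 1, so estimates are
  # directly comparable
  expect_equal(coef(fit), c(a = p$a, b = p$b, c = p$c, d = p$d, e = p$e),
               tolerance = 1e-3)
})

test_that("normalisation reports the same surface for rescaled truths", {
  # a truth whose T-polynomial has vertex value 2 describes the same
  # A_sat surface as the normalised (vertex 1) set with doubled WC-poly
  p <- truth_an()
  light <- light_obs_from_truth(p)
  scaled <- an_params(a = 2 * p$a, b = 2 * p$b, c = 2 * p$c,
                      d = p$d / 2, e = p$e / 2,
                      f = p$f, g = p$g, h = p$h, i = p$i, AQE = p$AQE)
  expect_equal(asat_surface(22, 5, scaled), asat_surface(22, 5, p))
  fit <- fit_asat_params(light, c(f = p$f, g = p$g, h = p$h, i = p$i))
  expect_equal(coef(fit)[["e"]] / (2 * coef(fit)[["d"]]),
               optimum_wc(scaled), tolerance = 1e-3)
})

test_that("noisy light-data fit reaches the expected goodness of fit", {
  cfg <- generator_config()  # study design: 5 temperatures x 5 replicates
  obs <- curves_to_observations(
    lapply(generate_dehydration_dataset(cfg, seed = 21), process_curve))
  cal <- calibrate_an(obs$dark, obs$light)
  expect_gte(cal$asat_fit$r_squared, 0.9)
  expect_equal(optimum_wc(cal$params), 7.2, tolerance = 0.3)
  expect_equal(optimum_temperature(cal$params), 25, tolerance = 1)
})

test_that("single-temperature light designs are rejected", {
  p <- truth_an()
  light <- light_obs_from_truth(p)
  light$T_moss <- 25
  expect_error(
    fit_asat_params(light, c(f = p$f, g = p$g, h = p$h, i = p$i)),
    "rank-deficiency")
})

test_that("the two calibration steps are independent", {
  cfg <- generator_config(replicates = 2)
  obs <- curves_to_observations(
    lapply(generate_dehydration_dataset(cfg, seed = 31), process_curve))
  cal1 <- calibrate_an(obs$dark, obs$light)
  perturbed <- obs$light
  perturbed$A_N <- perturbed$A_N + 0.5
  cal2 <- calibrate_an(obs$dark, perturbed)
  expect_identical(coef(cal1$rd_fit), coef(cal2$rd_fit))
  expect_false(identical(coef(cal1$asat_fit), coef(cal2$asat_fit)))
})

test_that("canopy-temperature fit recovers field coefficients exactly", {
  grid <- tmoss_refit_grid()
  fit <- fit_tmoss_params(grid)
  expect_equal(coef(fit),
               c(j = -8.2e-6, k = 0.017, l = -0.734, m = -1.624),
               tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("canopy-temperature fit equals the closed-form normal equations", {
  cfg <- generator_config()
  obs <- generate_field_observations(cfg, n = 150, seed = 12)
  fit <- fit_tmoss_params(obs)
  X <- cbind(1, obs$PAR^2, obs$PAR, log(obs$WC))
  beta <- oracle_normal_equations(X, obs$T_moss - obs$T_air)
  expect_equal(unname(coef(fit)[c("l", "j", "k", "m")]), unname(beta),
               tolerance = 1e-8)
})

test_that("noisy canopy-temperature fit matches its design-implied R2", {
  cfg <- generator_config(sd_tmoss = 1)
  obs <- generate_field_observations(cfg, n = 200, seed = 4)
  fit <- fit_tmoss_params(obs)
  # with 1 degC noise the expected R2 follows from the signal variance of
  # the sampled design: var(T_moss signal) / (var(T_moss signal) + sd^2)
  signal <- tmoss_model(obs$T_air, obs$PAR, obs$WC, cfg$tmoss_params)
  expected_r2 <- var(signal) / (var(signal) + cfg$sd_tmoss^2)
  expect_equal(fit$r_squared, expected_r2, tolerance = 0.03)
  expect_gt(fit$r_squared, 0.6)
})

test_that("collinear canopy designs are rejected", {
  obs <- data.frame(T_moss = rnorm(10, 20), T_air = 15,
                    PAR = 500, WC = 5)
  expect_error(fit_tmoss_params(obs), "rank-deficiency")
})

test_that("correction-slope regression recovers the calibration line", {
  d <- data.frame(dH2O = seq(0, 25, by = 1))
  d$F <- irga_correction_factor(d$dH2O, 0)
  fit <- fit_correction_slope(d)
  expect_equal(coef(fit)[["slope"]], 9.73e-4, tolerance = 1e-10)
  expect_equal(coef(fit)[["intercept"]], 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # two points: the exact interpolating line
  two <- data.frame(dH2O = c(0, 10), F = c(1, 1.02))
  fit2 <- fit_correction_slope(two)
  expect_equal(coef(fit2)[["slope"]], 0.002)
  expect_equal(fit2$r_squared, 1)
  expect_error(fit_correction_slope(data.frame(dH2O = rep(1, 5), F = 1:5)),
               "rank-deficiency")
  # noisy pairs stay within 10% of the true slope
  set.seed(6)
  noisy <- data.frame(dH2O = runif(50, 0, 25))
  noisy$F <- irga_correction_factor(noisy$dH2O, 0) + rnorm(50, 0, 1e-4)
  fit3 <- fit_correction_slope(noisy)
  expect_equal(coef(fit3)[["slope"]], 9.73e-4, tolerance = 0.1)
})

test_that("three-parameter light-curve fit recovers its generating values", {
  par <- seq(0, 1500, by = 100)
  for (tr in list(c(AQE = 0.0144, A_sat = 2.8, R_D = 0.5),
                  c(AQE = 0.05, A_sat = 5, R_D = 1))) {
    curve <- data.frame(
      PAR = par,
      A_N = smith_net_assimilation(par, tr[["A_sat"]], tr[["R_D"]],
                                   tr[["AQE"]]))
    fit <- fit_aqe(curve)
    expect_equal(coef(fit), tr, tolerance = 1e-6)
  }
  # a flat curve carries no curvature information
  flat <- data.frame(PAR = par, A_N = 2.8)
  expect_warning(fit_aqe(flat), "ill-conditioned")
  expect_error(fit_aqe(data.frame(PAR = c(0, 500), A_N = c(0, 1))),
               ">= 5")
})

test_that("fitted estimates are unbiased across repeated noisy simulations", {
  # canopy-temperature fit, 50 seeds: the mean estimate of each coefficient
  # stays within 2 standard errors of the truth
  cfg <- generator_config(sd_tmoss = 1)
  ests <- t(vapply(1:50, function(s) {
    coef(fit_tmoss_params(generate_field_observations(cfg, n = 80, seed = s)))
  }, numeric(4)))
  truthv <- c(j = -8.2e-6, k = 0.017, l = -0.734, m = -1.624)
  for (nm in colnames(ests)) {
    se <- sd(ests[, nm]) / sqrt(nrow(ests))
    expect_lt(abs(mean(ests[, nm]) - truthv[[nm]]), 2 * se + 1e-12)
  }
})

test_that("surface optima follow the vertex formulas with guards", {
  expect_equal(optimum_wc(c(d = 0.05, e = 0.72)), 7.2)
  expect_equal(optimum_wc(c(d = 1, e = 2)), 1)
  expect_equal(optimum_wc(c(d = 0.05, e = 0.86)), 8.6)
  expect_error(optimum_wc(c(d = -1, e = 2)), "d must be > 0")
  expect_equal(optimum_temperature(c(a = -0.01, b = 0.5)), 25)
  expect_equal(optimum_temperature(c(a = -1, b = 0)), 0)
  expect_equal(optimum_temperature(c(a = -0.02, b = 1.2)), 30)
  expect_error(optimum_temperature(c(a = 0.01, b = 1)), "no interior optimum")
})

test_that("fitted parameter sets serialise and read back losslessly", {
  p <- truth_an()
  path <- withr::local_tempfile(fileext = ".dcf")
  write_params(p, path, sds = c(a = 0.001, e = 0.05))
  back <- read_params(path)
  expect_equal(back[names(back) != "species"],
               p[names(p) != "species"], tolerance = 1e-15)
  expect_equal(attr(back, "sds"), c(a = 0.001, e = 0.05))
  tp <- truth_tmoss()
  write_params(tp, path)
  expect_equal(read_params(path), tp, ignore_attr = TRUE, tolerance = 1e-15)
})
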