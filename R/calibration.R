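#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

# Construct the common fit-result container.
new_moss_fit <- function(estimates, sd, r_squared, n_obs, converged,
                         method, diagnostics, config) {
  structure(list(estimates = estimates, sd = sd, r_squared = r_squared,
                 n_obs = n_obs, converged = converged, method = method,
                 diagnostics = diagnostics, config = config),
            class = "moss_fit")
}

#' @export
coef.moss_fit <- function(object, ...) object$estimates

#' @export
print.moss_fit <- function(x, ...) {
  cat("Least-squares fit (", x$method, "), n = ", x$n_obs,
      ", converged: ", x$converged, "\n", sep = "")
  tab <- cbind(estimate = x$estimates, sd = x$sd)
  print(signif(tab, 6))
  cat(sprintf("R^2 (obs vs pred) = %.4f\n", x$r_squared))
  cfg <- x$config
  cat("config:", paste(names(cfg), unlist(lapply(cfg, format)),
                       sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# Squared Pearson correlation of observed vs predicted values — the
# goodness-of-fit convention used for all model fits in this package.
r_squared_obs_pred <- function(obs, pred) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
  stats::cor(obs, pred)^2
}

# Multi-start Levenberg-Marquardt least squares. `residual` maps a named
# parameter vector to the residual vector. Starts are the heuristic initial
# plus (n_starts - 1) jitters of +/-50%; the lowest-deviance solution wins.
nls_multistart <- function(residual, start, n_starts = 5, seed = 1,
                           lower = NULL, upper = NULL) {
  p <- length(start)
  starts <- list(start)
  if (n_starts > 1) {
    jit <- withr_local_seed(seed, {
      matrix(stats::runif((n_starts - 1) * p, 0.5, 1.5), ncol = p)
    })
    for (s in seq_len(n_starts - 1)) {
      st <- start * jit[s, ]
      names(st) <- names(start)
      starts[[s + 1L]] <- st
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = residual, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-10, ptol = 1e-10, maxfev = 10000, maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("convergence error: no optimizer start produced a valid fit")
  best
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
withr_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Parameter standard deviations from the Jacobian at the optimum.
lm_fit_sds <- function(fit, n_obs) {
  p <- length(fit$par)
  sds <- rep(NA_real_, p)
  if (n_obs > p) {
    sigma2 <- fit$deviance / (n_obs - p)
    # fit$hessian is J'J at the optimum; guard against singularity
    cov <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
    if (is.null(cov))
      cov <- tryCatch(sigma2 * MASS_ginv(fit$hessian), error = function(e) NULL)
    if (!is.null(cov)) sds <- sqrt(pmax(diag(cov), 0))
  } else {
    sds <- rep(0, p)
  }
  names(sds) <- names(fit$par)
  sds
}

# Tiny Moore-Penrose pseudoinverse (avoids importing MASS for one call).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(array(0, dim(X)[2:1]))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fit the dark-respiration surface (step one of the two-step calibration)
#'
#' Nonlinear least squares of the raw (unclamped) respiration surface
#' `exp(f + 0.1012 T - 0.0005 T^2) - g WC + h + i log(WC) T` to pooled dark
#' observations. Fitting uses Levenberg–Marquardt with five jittered starts
#' around heuristic initials (`f` from the log mean respiration minus the
#' temperature exponent at the mean temperature; `g`, `h`, `i` small
#' positives).
#'
#' @param dark Data frame with columns `T_moss`, `WC`, `R_D` (respiration
#'   positive); ≥ 8 observations spanning ≥ 2 temperatures and ≥ 2 water
#'   contents.
#' @param log_base Base of the log(WC) term (`"natural"` default).
#' @param n_starts Number of optimizer starts (default 5).
#' @param seed Seed for start jitter (default 1).
#' @return A `"moss_fit"` with estimates `f`, `g`, `h`, `i`, per-parameter
#'   standard deviations from the Jacobian at the optimum, and R² as the
#'   squared observed-vs-predicted Pearson correlation.
#' @export
fit_rd_params <- function(dark, log_base = c("natural", "log10"),
                          n_starts = 5, seed = 1) {
  log_base <- match.arg(log_base)
  stopifnot(all(c("T_moss", "WC", "R_D") %in% names(dark)))
  if (nrow(dark) < 8)
    stop("need >= 8 dark observations, got ", nrow(dark))
  if (length(unique(dark$T_moss)) < 2 || length(unique(dark$WC)) < 2)
    stop("rank-deficiency error: dark design needs >= 2 distinct ",
         "temperatures and >= 2 distinct water contents")
  if (any(dark$WC <= 0)) stop("invalid input: WC must be > 0")

  hb <- sphagnum_constants$heskel_b; hc <- sphagnum_constants$heskel_c
  lw <- .model_log(dark$WC, log_base)
  mt <- mean(dark$T_moss)
  f0 <- log(max(mean(dark$R_D), 1e-3)) - (hb * mt + hc * mt^2)
  start <- c(f = f0, g = 0.01, h = 0.1, i = 0.005)
  residual <- function(par) {
    pred <- exp(par[["f"]] + hb * dark$T_moss + hc * dark$T_moss^2) -
      par[["g"]] * dark$WC + par[["h"]] + par[["i"]] * lw * dark$T_moss
    dark$R_D - pred
  }
  fit <- nls_multistart(residual, start, n_starts = n_starts, seed = seed)
  pred <- dark$R_D - residual(fit$par)
  est <- fit$par
  new_moss_fit(
    estimates = est, sd = lm_fit_sds(fit, nrow(dark)),
    r_squared = r_squared_obs_pred(dark$R_D, pred),
    n_obs = nrow(dark), converged = fit$info %in% 1:3,
    method = "Levenberg-Marquardt (multi-start)",
    diagnostics = list(deviance = fit$deviance, info = fit$info,
                       message = fit$message, n_starts = n_starts),
    config = list(surface = "rd", log_base = log_base, seed = seed))
}

#' Fit the light-saturated assimilation surface (step two)
#'
#' Nonlinear least squares of the full light-response composition (Smith
#' equation over the A_sat and raw R_D surfaces) to saturating-light
#' observations, with the respiration coefficients `f`–`i` and AQE held
#' fixed at their step-one values. Holding them fixed keeps the much larger
#' light dataset from re-weighting the respiration fit.
#'
#' Under the multiplicative grouping the product of the temperature and
#' water-content polynomials is invariant to reciprocal rescaling of the
#' factors; identifiability is restored by fitting the normalised form
#' `(1 + alpha (T - T_opt)^2) * (-d WC^2 + e WC)` and reporting `a`, `b`,
#' `c` in the convention where the temperature polynomial equals 1 at its
#' vertex. Standard deviations for `a`, `b`, `c` follow by the delta method.
#' Under the additive grouping all five coefficients are fitted directly.
#'
#' @param light Data frame with columns `T_moss`, `WC`, `PAR`, `A_N`;
#'   must span ≥ 3 distinct temperatures.
#' @param rd_params Fixed respiration coefficients: a `"moss_fit"` from
#'   [fit_rd_params()] or a named vector with `f`, `g`, `h`, `i`.
#' @param AQE Fixed apparent quantum efficiency.
#' @param grouping `"multiplicative"` (default) or `"additive"`.
#' @param log_base Log base for the respiration surface.
#' @param n_starts,seed Multi-start control, as in [fit_rd_params()].
#' @return A `"moss_fit"` with estimates `a`–`e` (normalised convention for
#'   the multiplicative grouping).
#' @export
fit_asat_params <- function(light, rd_params,
                            AQE = sphagnum_constants$aqe_default,
                            grouping = c("multiplicative", "additive"),
                            log_base = c("natural", "log10"),
                            n_starts = 5, seed = 1) {
  grouping <- match.arg(grouping)
  log_base <- match.arg(log_base)
  stopifnot(all(c("T_moss", "WC", "PAR", "A_N") %in% names(light)))
  if (inherits(rd_params, "moss_fit")) rd_params <- coef(rd_params)
  stopifnot(all(c("f", "g", "h", "i") %in% names(rd_params)))
  if (length(unique(light$T_moss)) < 3)
    stop("rank-deficiency error: light design needs >= 3 distinct ",
         "temperatures to identify the temperature polynomial")
  if (length(unique(light$WC)) < 3)
    stop("rank-deficiency error: light design needs >= 3 distinct ",
         "water contents")
  if (any(light$WC <= 0)) stop("invalid input: WC must be > 0")

  hb <- sphagnum_constants$heskel_b; hc <- sphagnum_constants$heskel_c
  lw <- .model_log(light$WC, log_base)
  rd_fixed <- exp(rd_params[["f"]] + hb * light$T_moss + hc * light$T_moss^2) -
    rd_params[["g"]] * light$WC + rd_params[["h"]] +
    rd_params[["i"]] * lw * light$T_moss

  smith <- function(asat) {
    gross <- asat + rd_fixed
    gross * light$PAR * AQE / sqrt(AQE^2 * light$PAR^2 + gross^2) - rd_fixed
  }

  # Heuristic initials: temperature optimum and curvature from a quadratic
  # through per-temperature maxima; WC parabola from peak height and its
  # location at the best-sampled temperature.
  per_t_max <- tapply(light$A_N, light$T_moss, max)
  tvals <- as.numeric(names(per_t_max))
  topt0 <- tvals[which.max(per_t_max)]
  alpha0 <- -0.01
  if (length(tvals) >= 3) {
    qf <- stats::lm(y ~ x + I(x^2),
                    data = data.frame(x = tvals, y = as.numeric(per_t_max)))
    qa <- stats::coef(qf)[["I(x^2)"]]; qb <- stats::coef(qf)[["x"]]
    if (is.finite(qa) && qa < 0) {
      vtx <- -qb / (2 * qa)
      vval <- unname(stats::predict(qf, data.frame(x = vtx)))
      if (is.finite(vval) && vval > 0) {
        topt0 <- vtx
        alpha0 <- unname(qa / vval)
      }
    }
  }
  i_best <- which.max(light$A_N)
  wcopt0 <- max(light$WC[i_best], 1)
  peak0 <- max(light$A_N[i_best] + max(rd_fixed[i_best], 0), 0.5)
  e0 <- 2 * peak0 / wcopt0
  d0 <- peak0 / wcopt0^2

  if (grouping == "multiplicative") {
    start <- c(alpha = alpha0, Topt = topt0, d = d0, e = e0)
    residual <- function(par) {
      tpoly <- 1 + par[["alpha"]] * (light$T_moss - par[["Topt"]])^2
      asat <- tpoly * (-par[["d"]] * light$WC^2 + par[["e"]] * light$WC)
      light$A_N - smith(asat)
    }
  } else {
    c0 <- -(alpha0 * topt0^2) * peak0  # rough additive offset
    start <- c(a = alpha0 * peak0, b = -2 * alpha0 * topt0 * peak0, c = c0,
               d = d0, e = e0)
    residual <- function(par) {
      asat <- par[["a"]] * light$T_moss^2 + par[["b"]] * light$T_moss +
        par[["c"]] - par[["d"]] * light$WC^2 + par[["e"]] * light$WC
      light$A_N - smith(asat)
    }
  }
  fit <- nls_multistart(residual, start, n_starts = n_starts, seed = seed)
  pred <- light$A_N - residual(fit$par)
  sds_int <- lm_fit_sds(fit, nrow(light))

  if (grouping == "multiplicative") {
    al <- fit$par[["alpha"]]; to <- fit$par[["Topt"]]
    est <- c(a = al, b = -2 * al * to, c = 1 + al * to^2,
             d = fit$par[["d"]], e = fit$par[["e"]])
    # delta method for (a, b, c) from (alpha, Topt)
    sds <- c(a = NA_real_, b = NA_real_, c = NA_real_,
             d = sds_int[["d"]], e = sds_int[["e"]])
    if (all(is.finite(sds_int))) {
      n <- nrow(light); p <- length(fit$par)
      sigma2 <- if (n > p) fit$deviance / (n - p) else 0
      covi <- tryCatch(sigma2 * solve(fit$hessian),
                       error = function(e) sigma2 * MASS_ginv(fit$hessian))
      J <- rbind(a = c(1, 0, 0, 0),
                 b = c(-2 * to, -2 * al, 0, 0),
                 c = c(to^2, 2 * al * to, 0, 0),
                 d = c(0, 0, 1, 0),
                 e = c(0, 0, 0, 1))
      covo <- J %*% covi %*% t(J)
      sds <- sqrt(pmax(diag(covo), 0))
      names(sds) <- c("a", "b", "c", "d", "e")
    }
  } else {
    est <- fit$par
    sds <- sds_int
  }
  new_moss_fit(
    estimates = est, sd = sds,
    r_squared = r_squared_obs_pred(light$A_N, pred),
    n_obs = nrow(light), converged = fit$info %in% 1:3,
    method = "Levenberg-Marquardt (multi-start)",
    diagnostics = list(deviance = fit$deviance, info = fit$info,
                       message = fit$message, n_starts = n_starts,
                       internal_par = fit$par),
    config = list(surface = "asat", grouping = grouping,
                  log_base = log_base, AQE = AQE, seed = seed,
                  normalised = grouping == "multiplicative"))
}

#' Two-step calibration of the full assimilation model
#'
#' Runs [fit_rd_params()] on the dark dataset, then [fit_asat_params()] on
#' the saturating-light dataset with the respiration coefficients held
#' fixed. The two steps are independent by construction: the light data
#' never influence `f`–`i`.
#'
#' @param dark,light Calibration data frames (see the step functions), e.g.
#'   from [curves_to_observations()].
#' @param AQE Fixed apparent quantum efficiency.
#' @param grouping,log_base Model configuration switches.
#' @param n_starts,seed Optimizer control.
#' @param species Label carried into the returned parameter set.
#' @return A list with the two `"moss_fit"` objects (`rd_fit`, `asat_fit`)
#'   and `params`, the assembled [an_params()] object.
#' @export
calibrate_an <- function(dark, light,
                         AQE = sphagnum_constants$aqe_default,
                         grouping = c("multiplicative", "additive"),
                         log_base = c("natural", "log10"),
                         n_starts = 5, seed = 1,
                         species = NA_character_) {
  grouping <- match.arg(grouping)
  log_base <- match.arg(log_base)
  rd_fit <- fit_rd_params(dark, log_base = log_base,
                          n_starts = n_starts, seed = seed)
  asat_fit <- fit_asat_params(light, rd_fit, AQE = AQE, grouping = grouping,
                              log_base = log_base, n_starts = n_starts,
                              seed = seed)
  est <- c(coef(asat_fit), coef(rd_fit))
  params <- an_params(a = est[["a"]], b = est[["b"]], c = est[["c"]],
                      d = est[["d"]], e = est[["e"]], f = est[["f"]],
                      g = est[["g"]], h = est[["h"]], i = est[["i"]],
                      AQE = AQE, grouping = grouping, log_base = log_base,
                      species = species)
  list(rd_fit = rd_fit, asat_fit = asat_fit, params = params)
}

#' Fit the canopy-temperature model to field observations
#'
#' The warming function is linear in its coefficients given the regressors
#' `PAR^2`, `PAR`, `log(WC)` and an intercept, so the least-squares optimum
#' is the closed-form linear solution of `T_moss - T_air` on those
#' regressors.
#'
#' @param obs Data frame with columns `T_moss`, `T_air`, `PAR`, `WC`;
#'   ≥ 6 observations with variation in PAR and WC.
#' @param log_base Log base for the log(WC) regressor.
#' @return A `"moss_fit"` with estimates `j`, `k`, `l`, `m`; R² is the
#'   squared Pearson correlation of observed vs predicted T_moss.
#' @export
fit_tmoss_params <- function(obs, log_base = c("natural", "log10")) {
  log_base <- match.arg(log_base)
  stopifnot(all(c("T_moss", "T_air", "PAR", "WC") %in% names(obs)))
  if (nrow(obs) < 6)
    stop("need >= 6 field observations, got ", nrow(obs))
  if (any(obs$WC <= 0)) stop("invalid input: WC must be > 0")
  lw <- .model_log(obs$WC, log_base)
  X <- cbind(1, obs$PAR^2, obs$PAR, lw)
  if (qr(X)$rank < 4)
    stop("rank-deficiency error: PAR and WC must both vary (collinear ",
         "design for the canopy-temperature model)")
  y <- obs$T_moss - obs$T_air
  df <- data.frame(y = y, par2 = obs$PAR^2, par = obs$PAR, lw = lw)
  lmfit <- stats::lm(y ~ par2 + par + lw, data = df)
  cf <- stats::coef(lmfit)
  se <- tryCatch(suppressWarnings(summary(lmfit))$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  est <- c(j = cf[["par2"]], k = cf[["par"]], l = cf[["(Intercept)"]],
           m = cf[["lw"]])
  sds <- c(j = se[["par2"]], k = se[["par"]], l = se[["(Intercept)"]],
           m = se[["lw"]])
  pred_tmoss <- obs$T_air + stats::fitted(lmfit)
  new_moss_fit(
    estimates = est, sd = sds,
    r_squared = r_squared_obs_pred(obs$T_moss, pred_tmoss),
    n_obs = nrow(obs), converged = TRUE,
    method = "linear least squares (closed form)",
    diagnostics = list(sigma = suppressWarnings(summary(lmfit))$sigma),
    config = list(surface = "tmoss", log_base = log_base))
}

#' Fit the humidity-correction slope from wet-paper calibration pairs
#'
#' Ordinary least-squares line of the correction factor against the
#' sample/reference water-vapour difference, re-deriving the slope of
#' [irga_correction_factor()] from a user's own empty-chamber calibration.
#'
#' @param pairs Data frame with columns `dH2O` (mmol mol⁻¹) and `F`.
#' @return A `"moss_fit"` with estimates `slope` and `intercept`.
#' @export
fit_correction_slope <- function(pairs) {
  stopifnot(all(c("dH2O", "F") %in% names(pairs)))
  if (nrow(pairs) < 2) stop("need >= 2 calibration pairs")
  if (length(unique(pairs$dH2O)) < 2)
    stop("rank-deficiency error: dH2O is constant across pairs")
  lmfit <- stats::lm(F ~ dH2O, data = pairs)
  cf <- stats::coef(lmfit)
  se <- tryCatch(suppressWarnings(summary(lmfit))$coefficients[, "Std. Error"],
                 error = function(e) c(NA_real_, NA_real_))
  r2 <- if (stats::sd(pairs$F) == 0) 1 else
    r_squared_obs_pred(pairs$F, stats::fitted(lmfit))
  new_moss_fit(
    estimates = c(slope = cf[["dH2O"]], intercept = cf[["(Intercept)"]]),
    sd = c(slope = unname(se[2]), intercept = unname(se[1])),
    r_squared = r2, n_obs = nrow(pairs), converged = TRUE,
    method = "linear least squares (closed form)",
    diagnostics = list(), config = list(surface = "irga_slope"))
}

#' Fit the Smith light response to a single light curve
#'
#' Three-parameter nonlinear fit of apparent quantum efficiency,
#' light-saturated assimilation and dark respiration to `(PAR, A_N)` pairs
#' measured at fixed temperature and water content — the procedure that
#' yields the species-averaged AQE.
#'
#' @param curve Data frame with columns `PAR` and `A_N`; ≥ 5 PAR levels
#'   including one at or near darkness.
#' @param n_starts,seed Multi-start control.
#' @return A `"moss_fit"` with estimates `AQE`, `A_sat`, `R_D`. A curve with
#'   no low-light curvature information triggers an ill-conditioned warning.
#' @export
fit_aqe <- function(curve, n_starts = 5, seed = 1) {
  stopifnot(all(c("PAR", "A_N") %in% names(curve)))
  if (length(unique(curve$PAR)) < 5)
    stop("need >= 5 distinct PAR levels")
  if (min(curve$PAR) > 50)
    warning("ill-conditioned: no PAR level at or near darkness; ",
            "AQE is weakly identified")
  spread <- max(curve$A_N) - min(curve$A_N)
  if (spread < 1e-8 * max(1, abs(max(curve$A_N))))
    warning("ill-conditioned: assimilation shows no light-response ",
            "curvature (constant A_N); parameters are not identifiable")
  ord <- order(curve$PAR)
  p1 <- ord[1]; p2 <- ord[2]
  slope0 <- (curve$A_N[p2] - curve$A_N[p1]) /
    max(curve$PAR[p2] - curve$PAR[p1], 1)
  start <- c(AQE = max(min(slope0, 0.5), 1e-3),
             A_sat = max(max(curve$A_N), 0.1),
             R_D = max(-min(curve$A_N), 0.05))
  residual <- function(par) {
    gross <- par[["A_sat"]] + par[["R_D"]]
    pred <- gross * curve$PAR * par[["AQE"]] /
      sqrt(par[["AQE"]]^2 * curve$PAR^2 + gross^2) - par[["R_D"]]
    curve$A_N - pred
  }
  fit <- nls_multistart(residual, start, n_starts = n_starts, seed = seed,
                        lower = c(1e-6, 1e-6, 0))
  kappa <- tryCatch(kappa(fit$hessian, exact = TRUE),
                    error = function(e) Inf)
  if (!is.finite(kappa) || kappa > 1e10)
    warning("ill-conditioned light-response fit: the curve carries little ",
            "information on one or more parameters (condition number ",
            format(kappa, digits = 3), ")")
  pred <- curve$A_N - residual(fit$par)
  new_moss_fit(
    estimates = fit$par, sd = lm_fit_sds(fit, nrow(curve)),
    r_squared = r_squared_obs_pred(curve$A_N, pred),
    n_obs = nrow(curve), converged = fit$info %in% 1:3,
    method = "Levenberg-Marquardt (multi-start)",
    diagnostics = list(deviance = fit$deviance, info = fit$info,
                       condition_number = kappa),
    config = list(surface = "smith_light_curve", seed = seed))
}

#' Water-content optimum of the assimilation surface
#'
#' Vertex of the water-content parabola `-d WC^2 + e WC`: `WC* = e/(2d)`.
#' Under the multiplicative grouping this optimum is the same at every
#' temperature.
#'
#' @param params An [an_params()] object, a `"moss_fit"` from
#'   [fit_asat_params()], or anything with named elements `d`, `e`.
#' @return Optimum water content (g H₂O g⁻¹ DW).
#' @export
optimum_wc <- function(params) {
  v <- if (inherits(params, "moss_fit")) coef(params) else params
  d <- v[["d"]]; e <- v[["e"]]
  if (!is.finite(d) || d <= 0)
    stop("invalid parameter: d must be > 0 for a finite water-content optimum")
  e / (2 * d)
}

#' Temperature optimum of the assimilation surface
#'
#' Vertex of the temperature parabola `a T^2 + b T + c`: `T* = -b/(2a)`,
#' requiring downward curvature (`a < 0`).
#'
#' @param params An [an_params()] object, a `"moss_fit"`, or anything with
#'   named elements `a`, `b`.
#' @return Optimum temperature (°C).
#' @export
optimum_temperature <- function(params) {
  v <- if (inherits(params, "moss_fit")) coef(params) else params
  a <- v[["a"]]; b <- v[["b"]]
  if (!is.finite(a) || a >= 0)
    stop("no interior optimum: temperature polynomial needs a < 0")
  -b / (2 * a)
}
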