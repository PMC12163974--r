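#' Assimilation-model parameter set
#'
#' Bundles the nine fitted coefficients of the net-assimilation model plus
#' the apparent quantum efficiency into one species-level state object.
#' Coefficients `a`, `b`, `c` form the temperature polynomial of
#' light-saturated assimilation \eqn{A_{sat}}, `d` and `e` its water-content
#' polynomial \eqn{-d\,WC^2 + e\,WC}; `f`–`i` parameterise the dark
#' respiration surface (`f` offsets the Heskel temperature exponent, `g`,
#' `h`, `i` the additive water-content terms).
#'
#' Under the default multiplicative grouping,
#' \eqn{A_{sat} = (a T^2 + b T + c)\,(-d\,WC^2 + e\,WC)}, the water-content
#' optimum is `e/(2d)` at every temperature and the temperature optimum is
#' `-b/(2a)` at every water content. Fitted parameter sets returned by
#' [fit_asat_params()] are normalised so the temperature polynomial equals 1
#' at its vertex; coefficients in other scale conventions describe the same
#' surface but are not numerically comparable without renormalisation.
#'
#' @param a,b,c Temperature-polynomial coefficients of A_sat
#'   (μmol m⁻² s⁻¹ °C⁻², ... °C⁻¹, ...).
#' @param d,e Water-content polynomial coefficients; both must be positive so
#'   the WC response has a finite interior optimum at `e/(2d)`
#'   (units (g H₂O g⁻¹ DW)⁻² and (g H₂O g⁻¹ DW)⁻¹).
#' @param f,g,h,i Dark-respiration surface coefficients (f dimensionless).
#' @param AQE Apparent quantum efficiency (μmol CO₂ μmol⁻¹ photons),
#'   in (0, 1). Default [sphagnum_constants]`$aqe_default`.
#' @param grouping `"multiplicative"` (default) or `"additive"`: how the
#'   temperature and water-content polynomials of A_sat are combined.
#' @param log_base `"natural"` (default) or `"log10"`: base of the log(WC)
#'   terms in the respiration surface.
#' @param species Optional species label carried through outputs.
#'
#' @return An object of class `"an_params"`.
#' @seealso [tmoss_params()], [an_params_synthetic()]
#' @examples
#' p <- an_params(a = -0.01, b = 0.5, c = -5.25, d = 0.05, e = 0.72,
#'                f = -3, g = 0.01, h = 0.2, i = 0.005)
#' optimum_wc(p)
#' @export
an_params <- function(a, b, c, d, e, f, g, h, i,
                      AQE = sphagnum_constants$aqe_default,
                      grouping = c("multiplicative", "additive"),
                      log_base = c("natural", "log10"),
                      species = NA_character_) {
  grouping <- match.arg(grouping)
  log_base <- match.arg(log_base)
  vals <- c(a = a, b = b, c = c, d = d, e = e, f = f, g = g, h = h, i = i,
            AQE = AQE)
  if (any(!is.finite(vals)))
    stop("all assimilation-model coefficients must be finite numbers")
  if (d <= 0 || e <= 0)
    stop("invalid parameters: d and e must be > 0 so the water-content ",
         "response has a finite positive optimum e/(2d)")
  if (AQE <= 0 || AQE >= 1)
    stop("invalid parameters: AQE must lie in (0, 1)")
  structure(
    list(a = a, b = b, c = c, d = d, e = e, f = f, g = g, h = h, i = i,
         AQE = AQE, grouping = grouping, log_base = log_base,
         species = species),
    class = "an_params"
  )
}

#' Moss-canopy temperature model parameter set
#'
#' Coefficients of the surface-temperature model
#' \eqn{T_{moss} = T_{air} + j\,PAR^2 + k\,PAR + l + m\,\log(WC)}:
#' a concave radiative warming term in PAR (`j` < 0, `k` > 0, interior
#' maximum at −k/(2j)), a constant offset `l`, and a water-content buffering
#' term `m` (negative: wetter canopies warm less).
#'
#' @param j Quadratic PAR coefficient (°C (μmol m⁻² s⁻¹)⁻²), expected < 0.
#' @param k Linear PAR coefficient (°C (μmol m⁻² s⁻¹)⁻¹), expected > 0.
#' @param l Offset (°C).
#' @param m log-WC coefficient (°C per unit log WC).
#' @param log_base `"natural"` (default) or `"log10"` for the log(WC) term.
#' @return An object of class `"tmoss_params"`. A warning (not an error) is
#'   issued when `j >= 0` or `k <= 0`, since noisy refits may leave the
#'   concavity region while the surface stays evaluable.
#' @seealso [tmoss_model()], [tmoss_params_hyytiala()]
#' @export
tmoss_params <- function(j, k, l, m, log_base = c("natural", "log10")) {
  log_base <- match.arg(log_base)
  vals <- c(j = j, k = k, l = l, m = m)
  if (any(!is.finite(vals)))
    stop("all canopy-temperature coefficients must be finite numbers")
  if (j >= 0 || k <= 0)
    warning("expected j < 0 and k > 0 (concave PAR warming with an ",
            "interior maximum at -k/(2j))")
  structure(list(j = j, k = k, l = l, m = m, log_base = log_base),
            class = "tmoss_params")
}

#' Field-calibrated canopy-temperature coefficients (Hyytiälä, boreal mire)
#'
#' The canopy-temperature model refit bundled as a reference parameter set:
#' warming of the moss surface over air temperature of
#' `0.017·PAR − 8.2e-6·PAR² − 1.624·log(WC) − 0.734` (natural log),
#' calibrated on pooled field observations of two Sphagnum species under
#' natural sun exposure.
#'
#' @return A [tmoss_params()] object.
#' @export
tmoss_params_hyytiala <- function() {
  tmoss_params(j = -8.2e-6, k = 0.017, l = -0.734, m = -1.624)
}

#' Synthetic reference assimilation parameters
#'
#' The ground-truth parameter set used by the synthetic-data generators and
#' throughout the package's self-consistency tests. It is a synthetic
#' stand-in — not field-fitted coefficients — constructed to mimic a boreal
#' hollow species: optimum water content `e/(2d)` = 7.2 g H₂O g⁻¹ DW,
#' optimum temperature `−b/(2a)` = 25 °C, peak light-saturated assimilation
#' ≈ 2.6 μmol m⁻² s⁻¹, and dark respiration near 0.8 μmol m⁻² s⁻¹ at the
#' optimum. The temperature polynomial is already in the normalised
#' convention (value 1 at its vertex).
#'
#' @param ... Overrides passed to [an_params()].
#' @return An [an_params()] object.
#' @export
an_params_synthetic <- function(...) {
  defaults <- list(a = -0.01, b = 0.5, c = -5.25, d = 0.05, e = 0.72,
                   f = -3, g = 0.01, h = 0.2, i = 0.005,
                   species = "synthetic")
  args <- utils::modifyList(defaults, list(...))
  do.call(an_params, args)
}

#' @export
print.an_params <- function(x, ...) {
  cat("Net-assimilation model parameters",
      if (!is.na(x$species)) paste0("(", x$species, ")"), "\n")
  cat(sprintf("  A_sat T-poly : a=%.5g b=%.5g c=%.5g\n", x$a, x$b, x$c))
  cat(sprintf("  A_sat WC-poly: d=%.5g e=%.5g  (optimum WC %.3g g/g)\n",
              x$d, x$e, x$e / (2 * x$d)))
  cat(sprintf("  R_D surface  : f=%.5g g=%.5g h=%.5g i=%.5g\n",
              x$f, x$g, x$h, x$i))
  cat(sprintf("  AQE=%.4g  grouping=%s  log=%s\n",
              x$AQE, x$grouping, x$log_base))
  invisible(x)
}

#' @export
print.tmoss_params <- function(x, ...) {
  cat(sprintf(
    "Canopy-temperature model: T_moss = T_air %+.4g*PAR^2 %+.4g*PAR %+.4g %+.4g*log(WC) [%s log]\n",
    x$j, x$k, x$l, x$m, x$log_base))
  invisible(x)
}

# internal: natural vs base-10 log switch used by the surfaces
.model_log <- function(x, log_base) {
  if (log_base == "log10") log10(x) else log(x)
}
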