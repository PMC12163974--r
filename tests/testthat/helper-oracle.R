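# Independent brute-force transcriptions of the model formulas, written
# scalar-by-scalar and kept deliberately naive. They never call package
# code, so they can serve as an oracle for the vectorised implementations.

oracle_F <- function(h2os, h2or, slope = 9.73e-4) {
  slope * (h2os - h2or) + 1
}

oracle_an_corrected <- function(co2r, co2s, flow_umol, area, F) {
  flow_mol <- flow_umol / 1e6
  flow_mol * (co2r - co2s * F) / area
}

oracle_asat <- function(t, wc, a, b, c, d, e, grouping = "multiplicative") {
  tp <- a * t * t + b * t + c
  wp <- -d * wc * wc + e * wc
  if (grouping == "multiplicative") tp * wp else tp + wp
}

oracle_rd <- function(t, wc, f, g, h, i) {
  exp(f + 0.1012 * t - 0.0005 * t * t) - g * wc + h + i * log(wc) * t
}

oracle_smith <- function(par, asat, rd, aqe) {
  gross <- asat + rd
  gross * par * aqe / sqrt(aqe * aqe * par * par + gross * gross) - rd
}

oracle_tmoss <- function(tair, par, wc, j, k, l, m) {
  tair + j * par * par + k * par + l + m * log(wc)
}

# closed-form normal-equations solution for a linear least-squares fit
oracle_normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
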