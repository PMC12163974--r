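# Shared ground-truth parameter sets for recovery tests.

truth_an <- function(...) an_params_synthetic(...)

truth_tmoss <- function() tmoss_params_hyytiala()

# Covariate grid used for noiseless canopy-temperature refits.
tmoss_refit_grid <- function(params = truth_tmoss()) {
  grid <- expand.grid(T_air = c(10, 15, 20, 25),
                      PAR = seq(0, 1600, by = 200),
                      WC = c(1, 3, 5, 9, 13, 17))
  grid$T_moss <- tmoss_model(grid$T_air, grid$PAR, grid$WC, params)
  grid
}
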