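#!/usr/bin/env Rscript
# Fit the canopy-temperature model to the simulated field observations and
# compare against the bundled field-calibrated coefficient set.

suppressPackageStartupMessages(library(sphagnumflux))

out <- "results"
obs <- utils::read.csv(file.path(out, "field_observations.csv"))
fit <- fit_tmoss_params(obs)
print(fit)

ref <- tmoss_params_hyytiala()
cmp <- data.frame(coefficient = c("j", "k", "l", "m"),
                  fitted = unname(coef(fit)),
                  sd = unname(fit$sd),
                  reference = c(ref$j, ref$k, ref$l, ref$m))
utils::write.csv(cmp, file.path(out, "tmoss_fit.csv"), row.names = FALSE)
message("All coefficients within noise of the reference set: ",
        all(abs(cmp$fitted - cmp$reference) < 3 * cmp$sd))

write_params(tmoss_params(coef(fit)[["j"]], coef(fit)[["k"]],
                          coef(fit)[["l"]], coef(fit)[["m"]]),
             file.path(out, "tmoss_params_fitted.dcf"), sds = fit$sd)
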