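#!/usr/bin/env Rscript
# Generate the synthetic study inputs: chamber dehydration curves at five
# temperatures (dark + saturating light, 5 replicates each), field
# canopy-temperature observations, and 14 days of July-regime half-hourly
# meteorology. Everything downstream (02-04) reads the CSVs written here.

suppressPackageStartupMessages(library(sphagnumflux))

seed <- 42
out <- "results"
dir.create(file.path(out, "curves"), recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config()
message("Ground truth: optimum WC ", optimum_wc(cfg$an_params),
        " g/g, optimum T ", optimum_temperature(cfg$an_params), " degC")

curves <- generate_dehydration_dataset(cfg, seed = seed)
for (cu in curves)
  write_dehydration_csv(cu, file.path(out, "curves",
                                      paste0(cu$curve_id[1], ".csv")))
message("Wrote ", length(curves), " dehydration curves (",
        sum(vapply(curves, nrow, 0L)), " gas-exchange records)")

field <- generate_field_observations(cfg, n = 200, seed = seed)
utils::write.csv(field, file.path(out, "field_observations.csv"),
                 row.names = FALSE)
message("Wrote ", nrow(field), " field canopy-temperature observations")

met <- generate_meteorology(cfg)
write_meteo_csv(met, file.path(out, "meteorology.csv"))
message("Wrote ", nrow(met), " half-hourly forcing steps (",
        cfg$days, " days); T_air ", min(met$T_air), "-", max(met$T_air),
        " degC, peak PAR ", max(met$PAR))
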