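Package: sphagnumflux
Title: Semi-Empirical Modelling of Sphagnum Net CO2 Assimilation and Daily NPP
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models net CO2 assimilation of Sphagnum mosses as a function of
    moss surface temperature, tissue water content and irradiance. Provides
    the Smith light-response equation with a polynomial light-saturated
    assimilation surface and a Heskel-form dark-respiration surface, a
    moss-canopy temperature model driven by air temperature, radiation and
    water content, two-step nonlinear least-squares calibration from
    dehydration-curve gas-exchange data, daily net primary productivity
    integration over half-hourly meteorological forcing, climate and
    photoperiod scenario simulation, and parametric-bootstrap uncertainty
    propagation. Includes synthetic-data generators (dehydration curves at
    the infrared-gas-analyser reading level, field canopy-temperature
    observations, diurnal meteorology) so the whole pipeline is testable
    end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
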