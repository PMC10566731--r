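Package: phycarb
Title: Seawater Carbonate Chemistry and Macrophyte Amelioration of Ocean
    Acidification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how marine macrophytes (kelp, other seaweeds
    and seagrass) ameliorate seawater acidity. Solves the seawater CO2 system
    on the total pH scale from pH/alkalinity or DIC/alkalinity pairs,
    propagates measurement uncertainty into derived carbonate parameters by
    Monte Carlo, fits Jassby-Platt photosynthesis-irradiance curves with
    Welch comparisons of the derived parameters, normalizes closed-chamber
    incubation responses by biomass and time with species-by-pCO2 linear
    response models, and predicts the bulk change in dissolved oxygen, DIC,
    pH and aragonite saturation state for a given kelp biomass density,
    irradiance and water residence time. Includes deterministic synthetic
    generators for both experimental designs so every stage of the pipeline
    is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
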