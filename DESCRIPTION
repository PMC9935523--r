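Package: soilrisk
Title: Soil Metal(loid) Guideline Screening, Pollution Indices and Human
    Health Risk Assessment
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assessment chain for metal(loid) contamination of urban
    topsoil: screening of sample concentrations against regulatory
    guideline sets (the Mongolian soil-quality standard MNS 5850:2019 and
    the Dutch Soil Guideline target and intervention values), per-metal
    pollution indices and the integrated Nemerow pollution index with its
    five-class severity scale, and a US-EPA-style deterministic human
    health risk assessment (average daily doses via soil ingestion and
    dermal contact, hazard quotients, hazard index, carcinogenic risk) for
    adult and child receptors. Includes a synthetic soil-survey generator
    emulating hexagonal sampling networks with lognormal concentrations
    and pollution hotspots, inverse-distance and ordinary-kriging
    interpolation to regular rasters with ESRI ASCII grid output, and
    normality-gated between-town comparisons (Shapiro-Wilk, then one-way
    ANOVA or Kruskal-Wallis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
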