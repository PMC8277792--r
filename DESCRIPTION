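Package: oroshift
Title: Altitudinal Range-Shift Analysis for Mountain Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end inference of climate-driven altitudinal range shifts
    in mountain species from dated, georeferenced occurrence records and
    annual gridded climate. Provides a synthetic-data generator (parametric
    mountain landscapes, warming monthly climates, insolation proxies and
    virtual species with known niches and shift rates), annual bioclimatic
    variables, geographically weighted regression downscaling, PCA
    environmental spaces, a from-scratch maximum-entropy presence-background
    distribution model with cloglog output and bootstrap evaluation,
    one-class support-vector niche hypervolumes with Monte-Carlo volume
    integration, altitudinal shift statistics (z_alt, z_range, z_VMR,
    z_skew, decadal median anomalies, variance-mean ratios, skewness), and
    trait-based general linear models with partial eta-squared effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    emmeans,
    withr
Config/testthat/edition: 3
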