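Package: radonrecon
Title: Discrete Reconstruction of Community Radon Exposure from a Piecewise
    Silo Source Term and Joint-Frequency Meteorology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs long-term outdoor radon-222 concentrations around a
    ground-level circular area source (the Fernald K-65 residue silos) on a
    polar receptor grid, using a sector-averaged Gaussian plume model driven
    by a piecewise-constant emission timeline and monthly joint-frequency
    wind tables (speed class x Pasquill-Gifford stability x direction).
    Month-resolution residential histories are cleaned with SAS-era date
    conventions and combined with the concentration field to give
    duration-weighted per-subject annual exposures, cohort summary
    statistics, sector rankings, an exposure footprint by compass octet, and
    exceedance counts against regulatory action levels. A synthetic-data
    module generates cohorts and meteorological tables with the statistical
    structure of the study inputs, so the full pipeline is testable without
    access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
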