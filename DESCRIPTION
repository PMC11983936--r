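Package: fluorsense
Title: Fluorescence Turn-Off Chemosensor Analytics and Green Chemistry Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for fluorescent "turn-off"
    chemosensors of nitroaromatic analytes such as picric acid, together
    with green-chemistry reaction metrics. Parses molecular formulas and
    computes average molecular weights; derives atom economy, process mass
    intensity, carbon efficiency, reaction mass efficiency and E-factor
    from stoichiometric reaction specifications; extracts photophysical
    quantities (absorption/emission maxima, molar absorptivity, Stokes
    shift, solvatochromic ranges) from spectra; and fits sensing analytics
    (Stern-Volmer quenching constants, 3-sigma/slope detection limits,
    Job continuous-variation stoichiometry, selectivity and reversibility
    indices). A synthetic-data module generates band spectra, host-guest
    binding equilibria, titration and calibration series with known ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
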