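Package: omzniche
Title: Trait-Based Consumer-Resource Modeling of Anaerobic Marine
    Nitrogen Cycling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A chemostat consumer-resource model of the anaerobic
    nitrogen-cycling microbial community of oxygen minimum zones: seven
    functional types (four partial denitrifier modules, a complete
    denitrifier, a nitrite-to-nitrous-oxide module, and anammox bacteria)
    growing on five resources (organic matter, nitrate, nitrite, nitrous
    oxide, ammonium) under Liebig colimitation. Provides the ordinary
    differential equation dynamics, subsistence-concentration (R*) and
    consumption-vector theory, zero net growth isoclines, invasion and
    community-assembly analysis with priority-effect (multistability)
    detection, and two-dimensional supply-space sweeps that map community
    composition and nitrogen-loss pathways (N2 versus N2O production).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
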