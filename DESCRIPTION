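Package: infusim
Title: Prediction of Transient Dosing Errors in Multi-Pump Infusion Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the drug dose rates that actually reach a patient when
    several syringe pumps share one vascular access point. A lumped
    compliance-resistance hydraulic network produces the transient flow each
    pump line delivers into the mixing point after a set-flow change
    (including backflow into neighbouring lines), a volume-slice shift
    register tracks the drug composition of the shared dead volume and
    catheter, and a laminar residence-time kernel models the parabolic
    (Poiseuille) velocity profile of catheter flow. Deviations from the set
    dose rates are decomposed into push-out, Poiseuille-profile and
    mechanical-compliance contributions. Ships a catalog of typical
    components, four built-in teaching scenarios, a randomized scenario
    generator and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
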