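Package: tagsip
Title: Per-Taxon Detection of Stable Isotope Incorporation from
    Density-Gradient Amplicon Profiles (Tag-SIP)
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of DNA stable isotope probing experiments read out by
    amplicon ("tag") sequencing of CsCl density-gradient fractions. Builds
    per-OTU buoyant-density profiles from fraction-level read counts, calls
    DNA band peaks with a minimum-support rule, measures paired
    control/labeled density shifts, calibrates a limit of detection from a
    null treatment, and classifies isotopic enrichment per OTU with clade
    level summaries. Also provides closed-form isotope mass-balance
    calculators (substrate-pool atom percent 15N, semiconservative DNA
    labeling bounds, expected buoyant-density gain, cross-feeding budgets)
    and a gradient simulator that emulates isopycnic banding, fraction
    collection and multinomial read sampling for validation and parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
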