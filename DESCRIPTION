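Package: sensescape
Title: Landau Free-Energy Landscapes of Symptom Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing a quartic (Landau) free-energy model of the
    automatic perception of persistent symptoms such as nociplastic pain. The
    perception order parameter distinguishes alert-protection (negative),
    neutral (zero) and trust-explore (positive) states; control parameters
    encode sensory context, learned historical information and information
    from the expert culture. The package computes exact stationary points of
    the sense-making landscape, classifies landscapes into named regimes
    (Zen, baby, uncertainty, catastrophizing, hypervigilance bias,
    communicative, curiosity bias), locates critical contexts and spinodal
    fields, traces quasi-static hysteresis ("biopsychosocial") loops, and
    replays learning/unlearning scenarios as ordered parameter changes with
    hysteretic state carry-over. Includes serialization to CSV/JSON/YAML,
    publication-style figures and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grid,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
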