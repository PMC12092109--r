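Package: caudawhip
Title: Tail-Strike Biomechanics from Caudal Vertebral Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing defensive tail-strike capability of
    long-tailed reptiles from serial caudal vertebral measurements. Reads
    per-vertebra centrum-length and total-height tables, imputes missing
    elements by adjacent means, detects the transition point where centrum
    length surpasses total height (the onset of the whip-like distal
    segment), estimates tail and whip-segment masses with an elongate-cone
    volume model and radial soft-tissue scaling, evaluates kinetic-energy
    strike scenarios, and assembles multi-taxon comparative tables. An audit
    mode back-solves the velocities implied by published strike energies and
    checks published tables for internal arithmetic consistency. Includes a
    synthetic vertebral-series generator with closed-form ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
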