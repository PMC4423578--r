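Package: neutromer
Title: Typed MS1 Signal Provenance Model and Reference Feature Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An executable, typed data model for LC-MS precursor (MS1)
    signal provenance: molecules, chargites, neutromers, neutroids and
    their retention-time and m/z reductions (integrated, max, average,
    instantaneous; deisotoped, reduced). Includes a reference feature
    extraction pipeline (intensity-weighted centroiding, neutromer-trace
    construction with ppm linking and gap bridging, trace culling and
    splitting, isotopic-envelope grouping, charge-state reduction), a
    profile-mode MS1 run simulator with ground truth for end-to-end
    validation, mzML reading and writing, nomenclature-validated feature
    tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mzR,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
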