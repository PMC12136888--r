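Package: aavheat
Title: Thermal Stability and Heat-Induced Genome Ejection Analytics for rAAV Capsids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for biophysical characterisation of recombinant
    adeno-associated virus (rAAV) particles under thermal stress: two-state
    thermal-unfolding fits of nano-differential scanning fluorimetry
    (nano-DSF) thermograms with windowed baseline constraints and per-gram
    thermodynamic classification, Gaussian decomposition of mass-photometry
    particle populations with empty-particle ratio and unbinding statistics,
    Svedberg-equation and frictional-ratio interpretation of
    sedimentation-velocity peaks with A260/A230 species classification,
    theoretical particle-mass and genome-cargo enumeration, and
    hydrogen/deuterium-exchange differential-uptake flagging. A synthetic-data
    generator with known ground truth emulates each instrument so every fit
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
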