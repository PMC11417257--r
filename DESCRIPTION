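Package: fibremech
Title: Multi-Modal Damage Metrology for Single Hair Fibers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cumulative damage to single keratin fibers across four
    measurement modalities: atomic force microscopy (AFM) topography (cuticle
    step height detection and areal roughness Sa/Sz), AFM force-distance curve
    mechanics (contact stiffness, adhesion and attraction forces),
    single-fiber tensile stress-strain analysis (elastic modulus, yield and
    fracture), and FT-IR transmittance band quantification (amide, lipid,
    water, cysteic acid and amine bands). Includes a synthetic-data generator
    with known ground truth for every modality, group statistics (mean +/-
    SEM, pooled Student's t-tests, significance stars) for dose-response
    reporting over dye-cycle groups, and an end-to-end
    simulate/analyze/report pipeline with parameter-recovery tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
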