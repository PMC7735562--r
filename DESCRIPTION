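Package: npcscreen
Title: Image-Based High-Content Screening for NPC1 Pharmacological Chaperones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an image-based phenotypic screening pipeline that
    quantifies the subcellular localization of GFP-tagged NPC1 folding
    mutants in two-channel (GFP + Hoechst) epifluorescence field images.
    Provides the three image-processing chains of the assay (NPC1-GFP
    pattern extraction, cell-area extraction, and watershed nuclei
    segmentation), morphological feature scoring (circularity,
    small-object area ratio, and GFP intensity per cell area), plate-wise
    robust Z-score normalization with Z'-factor quality control,
    threshold calibration from marginally active positive controls, and
    multiparameter hit calling. Includes downstream quantification of
    filipin-stained cholesterol accumulation by intensity clustering and
    GFP-marker colocalization with nonparametric and parametric group
    comparisons, together with a seeded synthetic-plate generator that
    renders reticular (ER-like) versus punctate (late-endosomal/lysosomal)
    phenotypes with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    multcomp,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
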