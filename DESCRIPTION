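Package: cacpipe
Title: Label-Guided Self-Distillation for Coronary Artery Calcium Scoring on CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Three-stage pipeline for automated coronary artery calcium (CAC)
    quantification from non-contrast chest CT. A vision-transformer backbone is
    pre-trained by label-guided self-distillation (DINO-LG), in which a fraction
    of the multi-crop augmentation views are anchored inside annotated calcified
    regions; a linear classifier on the frozen slice embeddings flags slices
    likely to contain calcification; a U-Net segments calcified lesions per
    coronary artery (RCA/LAD/LCA/LCX) on the flagged slices; and lesions are
    quantified by Agatston scoring with standard risk stratification. Includes
    a synthetic chest-CT phantom generator with construction-time ground truth
    so the full pipeline is testable end-to-end at desk scale, NIfTI/DICOM/PNG
    input-output, and the complete evaluation-metric suite (confusion-matrix
    metrics, McNemar's paired test, per-artery IoU/Dice and detection metrics,
    risk-category confusion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
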