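Package: octhrombus
Title: Quantitative Typing of Intracoronary Thrombus in Intravascular OCT
Version: 0.1.0
Authors@R: person("OCT", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computer image analysis of intracoronary thrombus in intravascular
    optical coherence tomography (OCT) pullbacks. Implements per-pixel
    depth-resolved estimation of the light attenuation coefficient and a
    backscatter term along A-lines of polar OCT frames, attenuation-thresholded
    region-of-interest statistics with pixel-count-weighted patient-level
    aggregation, red/white thrombus discrimination by ROC analysis with
    Youden-index cutoffs, observer-agreement statistics (Bland-Altman,
    absolute-agreement ICC, Cohen's kappa, Spearman correlation), and a forward
    speckle-noise phantom simulator so the whole pipeline is testable without
    clinical data. Includes readers and writers for grayscale TIFF stacks,
    JSON metadata sidecars, region masks, and tabular outputs, plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
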