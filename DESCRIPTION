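Package: cequant
Title: Quantification of Single Synaptic Contacts in Expansion Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement pipeline for expansion-microscopy images of single
    synaptic contacts (zebrafish Mauthner-cell club endings): contact
    morphometry and expansion-isotropy statistics, gap-junction puncta
    segmentation with connexon-number estimation, thresholded Manders
    colocalization, center/periphery corrected-total-fluorescence analysis,
    labeling-occupancy analysis, and two-channel line-scan subpixel
    peak-offset measurement. Includes a synthetic contact-scene generator
    (ground-truth geometry, Gaussian PSF, Poisson and read noise) so every
    stage can be validated against known answers without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
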