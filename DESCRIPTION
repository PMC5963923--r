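Package: gapstress
Title: Inferring Epidermal Tensile Stress Patterns from Cell-Separation Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of cell-adhesion defects in plant epidermis
    as a readout of tissue tensile stress. Provides intensity-threshold
    segmentation of inter-cell separation gaps with per-region area,
    principal orientation and anisotropy from pixel-coordinate second
    moments; axial (0 == 180 degree) circular statistics including the
    weighted resultant vector length, circular mean/SD and Rao's spacing
    test for uniformity; nematic-tensor quantification of fibrillar
    (cortical microtubule) orientation per cell region; scoring of
    microtubule reorientation around ablations via the acute angle to the
    radial direction; apparent-stiffness extraction from AFM
    force-indentation curves and thin-shell pressure-vessel wall tension;
    and deterministic synthetic-data generators (tissue mosaics, fibril
    textures, ablation scenes, force curves) with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
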