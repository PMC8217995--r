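Package: echotype
Title: Quantitative Echogenicity Characterization of B-Mode Ultrasound for
    Lower-Limb Edema Typing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tissue characterization of B-mode ultrasound frames by pixel
    brightness: fascia-anchored intensity calibration to a fixed reference
    level, Gray Scale Median (GSM), pixel-mass histograms over a canonical
    14-interval echogenicity partition with five pseudocolor bands, and a
    distribution-based classifier that types lower-limb edema as venous,
    lymphatic, mixed, or absent. Includes a seeded speckle-phantom generator
    with prescribed echogenicity-interval mass vectors (lymphatic lakes,
    granular texture) so the whole pipeline is testable without clinical
    images, and a group-comparison report (Levene-gated ANOVA/Tukey or
    Kruskal-Wallis/Dunn) for per-limb GSM data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
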