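Package: vesselquant
Title: Vessel Density, Vessel Maturity and VEGF Scoring from Multiplex
    Immunofluorescence of Uterine Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for multiplex immunofluorescence images of
    endo-myometrial tissue. Segments marker channels (DAPI, CD31, alpha-SMA,
    podoplanin, CD10, VEGF) into binary layers, delineates endometrial stroma,
    glands and myometrium compartments, counts blood and lymphatic microvessels,
    computes blood/lymph vessel density per mm2, percent stained area, the
    mature-to-total vessel ratio (CD31/alpha-SMA double staining), and the VEGF
    immunohistochemical score (percentage bin times intensity, 0-16). Includes a
    seeded synthetic-tissue generator with full ground truth for validation, and
    the nonparametric group-comparison report (Kruskal-Wallis, Mann-Whitney U,
    median and range, phase and medication stratification) used in adenomyosis
    case-control studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
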