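Package: abusvol
Title: Pixel-Based Breast Tumor Volumetry from Automated Breast Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures breast tumor volume from automated breast ultrasound
    (ABUS) coronal slice images by the pixel method: calibrate a cm-per-pixel
    ratio from an in-image scale reference, count pixels inside a manually
    outlined tumor cross-section (planimetry), convert counts to areas, and
    sum areas across 0.1-cm coronal slices (Cavalieri principle). Also
    provides the traditional caliper volume (length x width x height / 2),
    the agreement statistics used to compare the two methods and two
    observers (Wilcoxon signed-rank test with exact and approximate
    p-values, Bland-Altman limits of agreement, ratio summaries), synthetic
    ellipsoid phantoms with analytically known volume for validation, and a
    packaged 42-lesion study table with full reproduction of its published
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
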