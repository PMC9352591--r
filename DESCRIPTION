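Package: fulm
Title: Functional Ultrasound Localization Microscopy of Microvascular Hyperemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for functional ultrasound localization microscopy (fULM):
    singular-value-decomposition clutter filtering of ultrafast contrast-enhanced
    frame blocks, sub-pixel microbubble localization and particle tracking,
    super-resolved count and velocity maps, sliding-window and stimulus-pattern
    averaged dynamic movies, Pearson-correlation and SVD activation analysis of
    stimulus-locked functional hyperemia, and per-vessel quantification
    (compartments, profiles, half-maximum diameters, perfusion areas). Includes a
    ground-truthed synthetic vascular phantom with Poisson microbubble arrivals,
    stimulus-locked flux, speed and diameter modulation, low-rank tissue clutter,
    noise and motion, so every stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    data.table,
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
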