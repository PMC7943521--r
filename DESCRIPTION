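Package: sigmalog
Title: Sigma-Lognormal Modeling of Speech Kinematics from Formant Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Transforms first- and second-formant tracks into a planar
    kinematic trajectory, decomposes its velocity into temporally
    overlapping lognormal strokes by reverse engineering, and computes
    derived neuromotor timing parameters together with lognormal-phoneme
    matching statistics.  The acoustic-to-kinematic map rests on an
    equilateral vowel-triangle fit of the F1/F2 space; the stroke model
    follows the kinematic theory of rapid human movements.  Includes a
    synthetic action-plan generator on a hexagonal sound map for fully
    offline validation, readers and writers for delimited-text and Praat
    Formant/TextGrid files, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
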