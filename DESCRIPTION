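Package: byssofact
Title: Factorial Analysis of Two-Color Loop-Design Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of two-color spotted cDNA microarray
    experiments laid out as non-reference loop designs over a 2x2x2x2
    factorial treatment structure, as used to study environmental control of
    zebra mussel (Dreissena polymorpha) byssogenesis. Provides design
    enumeration and sum-to-zero effect coding, a ground-truthed array
    simulator (intensity-dependent dye bias, additive background, self-self
    null slides), background correction and loess M-versus-A normalization,
    per-gene least-squares fitting of the full factorial model with log
    fold changes equal to twice the coefficients, empirical false-discovery
    calibration from self-self hybridizations, factor-overlap accounting and
    average-linkage clustering of effect profiles, and 2^-ddCt relative
    quantification for qPCR validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, grDevices
Suggests: testthat (>= 3.0.0), withr, jsonlite, pheatmap
Config/testthat/edition: 3
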