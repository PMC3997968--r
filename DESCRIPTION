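Package: stabref
Title: Discovery and Validation of Stably Expressed Reference miRNAs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for selecting reference miRNAs for RT-qPCR normalization
    from small RNA-seq count data and for validating them on the qPCR side.
    The sequencing arm normalizes raw miRNA read counts to a common library
    size, estimates pairwise log2 fold changes as residuals from a fixed
    slope-1 regression, filters candidates by a percent-variation threshold
    and an abundance floor, and intersects the stable sets across stress
    conditions. The qPCR arm fits primer amplification efficiencies from
    dilution series, converts quantification-cycle (Cq) panels into
    efficiency-corrected relative quantities, and runs a from-scratch geNorm
    stability analysis: per-gene M values, stepwise exclusion ranking,
    pairwise variation V(n/n+1) with a recommended reference-gene count, and
    per-gene coefficients of variation. A seeded simulator generates count
    matrices, Cq panels and dilution series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
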