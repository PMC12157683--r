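Package: fireseq
Title: Fiber-Seq Inferred Regulatory Elements from Single-Molecule m6A Footprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-molecule identification of accessible regulatory elements from
    m6A-stenciled long reads (Fiber-seq). Implements heuristic nucleosome and
    methyltransferase-sensitive-patch (MSP) calling on single fibers,
    semi-supervised gradient-boosted classification of MSPs with
    estimated-precision calibration, coverage-normalized aggregate accessibility
    scores with a shuffled-read empirical null and FDR-controlled peak calling,
    haplotype-selective accessibility testing (Fisher / Benjamini-Hochberg),
    X-chromosome inactivation classification, single-motif protein-occupancy
    footprinting, and a ground-truth simulator of m6A-stenciled fibers for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
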