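Package: epidrift
Title: Culture-Associated DNA Methylation Drift and Epigenetic Passage Clocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify CpG sites whose DNA methylation drifts with
    passage number during long-term cell culture, to train and apply
    multivariable epigenetic passage clocks (including the published four-CpG
    pyrosequencing model), to analyse per-read methylation patterns from
    barcoded bisulfite amplicon sequencing (pattern spectra, Shannon diversity,
    neighbor correlation, single-read passage prediction), to quantify
    hemimethylation from hairpin-ligated bisulfite reads with UMI-based
    deduplication, and to follow signature trajectories during reprogramming
    time courses. A seeded synthetic-data generator emulates epigenetic drift,
    targeted epigenetic writers, clonal culture dynamics, hairpin strand pairs
    and logistic reprogramming kinetics so that every stage of the pipeline can
    be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    car,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
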