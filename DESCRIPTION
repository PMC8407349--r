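Package: fermquant
Title: Quantitative Genome-Centered Meta-Omics for Fermentation Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Absolute quantification of fermentation microbiomes from
    multi-omic count tables. Converts amplicon counts into marker-copy
    absolute abundances anchored on qPCR totals, genome-mapped shotgun
    counts into genome-size-normalized relative abundances and
    copy-number-corrected genome densities, and mRNA counts into spike-in
    normalized RPKM expression aggregated by KEGG functional category and
    attributed to taxa. Includes a synthetic fermentation time-course
    generator with known ground truth (logistic growth while the substrate
    is present, exponential decay after its removal) that reproduces the
    observation biases the quantification chain must undo, and a
    reproducible pipeline runner with manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    deSolve,
    jsonlite
Config/testthat/edition: 3
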