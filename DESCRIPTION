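Package: synoribo
Title: Allele-Specific Translation Elongation Effects of Synonymous Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of how tumor-specific synonymous mutations alter codon
    optimality and local translation-elongation speed, from paired tumor/normal
    RNA-seq and ribosome-profiling data in transcript coordinates. Provides
    outgroup-based variant polarization with loose and strict tumor-specific
    filters, P-site offset calibration from start-codon metagenes and A-site
    read assignment, allele-specific A-site density statistics, gene-class
    (oncogene vs tumor-suppressor) enrichment of optimal and non-optimal
    synonymous mutations, translation-efficiency estimation and regression of
    translation-efficiency fold change on mutation counts. A synthetic-data
    generator produces tumor/normal datasets with full ground truth so every
    stage of the pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
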