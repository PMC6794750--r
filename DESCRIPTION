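Package: qtlmeta
Title: Meta-QTL Analysis and Candidate-Gene Prioritization on Consensus Genetic Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds consensus genetic linkage maps from published component
    maps, projects quantitative trait loci (QTLs) onto the consensus by
    homothetic scaling between shared flanking markers, collapses co-located
    QTLs into meta-QTLs with a heteroscedastic Gaussian-mixture model selected
    by five information criteria (AIC, AICc, AIC3, BIC, AWE), anchors meta-QTL
    confidence intervals to a genome assembly to retrieve positional candidate
    genes, and intersects them with transcriptomic candidates selected by
    expression-filtering rules. Includes a synthetic-data generator emulating
    every input with known ground truth, so the whole pipeline is testable
    without external downloads. Developed around the genetic control of
    veraison (ripening onset) time in grapevine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
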