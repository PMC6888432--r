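Package: evoscape
Title: Evolutionary Landscapes of Disordered Disease Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative molecular-evolution analysis of protein families with
    extensive intrinsically disordered regions. Estimates per-site evolutionary
    rates on a fixed phylogeny by the empirical Bayes method under the JTT
    amino-acid replacement model with a discrete-gamma prior, standardizes them
    as Z scores on a reference (human) sequence, integrates per-residue
    order/disorder and phosphorylation-propensity tracks over a master
    alignment, calls phosphosites conserved across orthologs by a majority
    rule, annotates pathogenic missense variants with structural and
    evolutionary context, clusters protein presence/absence profiles across
    species (Manhattan distance, Ward's method) into evolutionary classes, and
    flags tissue-specific expression from TPM tables. A synthetic-data
    generator produces every input with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
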