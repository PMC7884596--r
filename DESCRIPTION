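Package: hemocyanr
Title: Paralog-Aware Assembly and Characterization of Gastropod Hemocyanins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing and characterizing paralogous multi-domain
    hemocyanin coding sequences from short-read data. Implements an iterative
    reference-guided, paralog-separating mapping assembler with stringent
    overlap/identity acceptance rules, a three-part verification protocol
    against chimeric ("hybrid") assemblies of internally repetitive paralogs,
    protein-level characterization (ORF translation, average molecular mass,
    functional-unit annotation, detection of histidine/aspartate-rich
    hydrophilic insertions, Kyte-Doolittle hydropathy, cysteine census),
    distance-based phylogenetics (neighbor joining with bootstrap support) for
    orthology assessment, and mass/oxygen-binding-site accounting for decameric
    oligomers. Includes a synthetic-data generator that emulates paralogous
    eight-functional-unit hemocyanin genes with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    tibble,
    dplyr,
    generics,
    ggplot2,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
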