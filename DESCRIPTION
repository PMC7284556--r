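Package: proxydb
Title: Proxy Protein Search Databases for Proteomics of Unsequenced Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates proxy protein search databases for tandem
    mass spectrometry (MS/MS) proteomics of organisms that lack a curated
    proteome. Constructs databases from genomic and transcriptomic sequence
    by six-frame translation (with genome chunking), open reading frame
    extraction, exact deduplication, contaminant appending and
    residue-equalized sizing; evaluates them at the peptide level through
    in-silico tryptic digestion, spectral-count identification filters,
    parsimony protein inference, detection of single amino acid variants and
    of terminal fragment peptides, and assembly quality metrics (N50,
    contiguity coverage). Includes read-processing utilities (sliding-window
    quality trimming, kmer-coverage normalization with an aberrant-read
    filter) and a fully seeded synthetic-data generator so the complete
    workflow runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
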