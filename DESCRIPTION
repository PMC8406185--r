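Package: clonalkit
Title: Clonal Genome Evolution Analysis for Isolated Bacterial Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying clonal, recombination-poor evolution in
    closely related bacterial genomes: a forward simulator of clonal genome
    evolution with homologous-recombination imports, indels and
    pseudogenization; single-copy ortholog identification and core-genome
    alignment; pangenome singleton statistics and fragment-based average
    nucleotide identity; neighbor-joining genealogies with ancestral state
    reconstruction; a per-branch two-state hidden Markov model estimating
    the recombination parameters R/theta, delta and nu and the derived r/m
    ratio; Nei-Gojobori counting dN/dS per branch; pseudogene detection by
    length-loss and premature stops; pairwise SNP/indel diversity and
    laboratory-generation null models; and the associated statistical tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
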