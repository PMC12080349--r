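Package: ecrmech
Title: Mechanisms Suppressing Extraneous CRISPR RNA in Type II-C CRISPR-Cas
    Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico screen for the candidate mechanisms by which type II-C
    CRISPR-Cas systems suppress the extraneous CRISPR RNA (ecrRNA) derived
    from the spacer-less extra repeat: rescue of mutated repeats hidden in
    the upstream intergenic region via empirical e-values over
    dinucleotide-shuffled nulls, per-repeat mutation profiling against the
    array consensus, a shuffle-null enrichment statistic for RNA helices
    pairing the putative ecrRNA guide, heuristic Rho-independent terminator
    calling with an observed-versus-expected intergenic enrichment ratio,
    nearest-neighbour repeat:tracrRNA duplex-energy comparison, and a
    per-locus mechanism classifier.  Includes a synthetic-locus generator
    with planted ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    BiocGenerics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
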