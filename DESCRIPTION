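Package: gsurvey
Title: Whole-Genome Survey Statistics from Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for low-cost whole-genome survey analysis of non-model
    organisms. Estimates genome size, sequencing error rate, heterozygosity
    and repeat content from the canonical k-mer spectrum of short reads;
    mines perfect and compound microsatellites (SSRs) with MISA-style
    thresholds and census statistics; computes assembly metrics (N50/N90,
    GC content, scaffold-to-contig decomposition, GC-depth tables); takes a
    census of circular mitochondrial genome annotations including start and
    stop codon classification under the vertebrate mitochondrial code; and
    parses and rescales PSMC output into effective-population-size
    trajectories with bootstrap envelopes. Includes a synthetic diploid
    genome and read simulator so every estimator ships with a
    parameter-recovery test against known truth.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
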