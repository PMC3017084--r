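Package: poolpop
Title: Population Genetics of Pooled Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of population genetic parameters from pooled
    next-generation sequencing (Pool-seq) data. Implements pool- and
    truncation-corrected estimators of Watterson's theta and nucleotide
    diversity (theta pi) under a binomial model of read sampling from a
    pool of chromosomes, a Tajima's D adapted to the truncated allele
    frequency spectrum induced by minor-allele-count filtering, quality
    trimming of reads with a modified Mott algorithm, SNP calling from
    SAMtools pileup files, sliding-window genome scans with GTF-based
    region restriction or masking, between-species divergence (dxy) from
    pairwise genome alignments, and a neutral coalescent simulation
    harness for validating estimator accuracy under sequencing error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    grDevices,
    graphics,
    Biostrings,
    IRanges,
    optparse
Suggests: testthat (>= 3.0.0), jsonlite, ggplot2
Config/testthat/edition: 3
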