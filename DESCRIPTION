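Package: haplosnp
Title: Haplotype-Aware Two-Round SNP Calling for Low-Coverage Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A progressive, haplotype-aware single-nucleotide polymorphism
    (SNP) caller for low-coverage long-read (nanopore-style) sequencing.
    A first-round genotyper applies a bidirectional LSTM to strand-split
    pileup count images at candidate sites; high-quality heterozygous
    calls are phased (exact/greedy minimum-error-correction) and used to
    haplotag reads; a second-round genotyper combines short-range pileup
    and long-range haplotype feature images over four alignment subsets
    (original, haplotype 1, haplotype 2, unphased); the two rounds are
    merged under a quality threshold into a final SNP-only VCF. A
    synthetic diploid read simulator with truth VCF/BAM/BED output makes
    every stage trainable and testable at desk scale. The recurrent
    networks, their training (Adam with optional lookahead, label
    smoothing) and exact backpropagation are implemented in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    Rsamtools,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
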