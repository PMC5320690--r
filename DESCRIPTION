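Package: polysites
Title: Streaming Extraction of Polymorphic Sites from Multi-FASTA Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and extracts single nucleotide polymorphisms (SNPs) from
    whole-genome multiple sequence alignments in multi-FASTA format, plain or
    gzip-compressed. A two-pass streaming algorithm builds a per-column
    consensus on the first pass and extracts the variant columns on the
    second, so peak memory is bounded by max(p*s, 2*g) characters for s
    samples, g alignment columns and p variant sites, and total input I/O is
    exactly two reads of the file. Gaps and unknown bases (n/N/?/-) are
    treated as non-variant. Variant columns are written as unwrapped
    multi-FASTA (default), relaxed sequential PHYLIP, or VCF 4.1 with haploid
    genotypes. Includes a planted-SNP alignment simulator and a scaling
    harness for benchmarking, plus a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    seqinr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
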