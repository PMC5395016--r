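Package: refgrade
Title: Reference-Assembly Error Detection and Validation from Re-Sequencing
    Reads and Optical Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to grade and correct a finished reference genome assembly
    with whole-genome re-sequencing data and an optical (restriction) map.
    Short reads from two re-sequenced individuals are quality-trimmed,
    adapter-clipped, uniquely mapped and piled up; every well-covered site is
    classified by base-frequency thresholds into reference type, sequencing
    error, allele within an individual, allelic difference between
    individuals, or low depth, and 1-4 bp indel errors are called from gapped
    alignments. Long reads detect large (>=100 bp) reference indels through
    split local alignments. In-silico restriction digestion and fragment-map
    alignment validate the assembly against an optical map and classify
    map-sequence discordances. A synthetic-data generator with full ground
    truth, an effect annotator for allelic SNPs, assembly correction with
    coordinate liftover, and gap/genome-size accounting complete the
    pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
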