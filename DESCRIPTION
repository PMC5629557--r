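Package: strscan
Title: Targeted Profiling of Short Tandem Repeats in Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies user-defined short tandem repeat (STR) loci in
    FASTA/FASTQ sequencing reads and reports per-locus repeat copy numbers
    with supporting reads. Each locus is described as a pattern of flanking
    sequences, one or more repetitive units with reference copy numbers,
    and intermediate spacers. Reads are matched by exact k-mer seeds built
    from tandem repetitions of the units, and seeds are extended in both
    directions by a greedy fitting-alignment procedure under a banded
    edit-distance model until both flanks are anchored or an edit-distance
    budget is exhausted. Includes a panel/read simulator with planted
    alleles, substitution and indel noise, and ground-truth tables, plus a
    command-line interface for profiling and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
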