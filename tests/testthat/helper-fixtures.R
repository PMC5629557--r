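# Shared fixtures: tiny hand-built patterns with boundary-distinct flanks.

fix_flank_L <- "CCATGAGTAACTGGAAGTAGAATCTTGAGT"  # 30 bp
fix_flank_R <- "GCTCGGCCTTTCCATATCTCGTGAACCACA"  # 30 bp

# single-unit ATCC x 8 locus
fix_pattern1 <- function(copies = 8L) {
    build_pattern("FIX1", left_flank = fix_flank_L, units = "ATCC",
                  copies = copies, right_flank = fix_flank_R)
}

# two-unit locus (compound marker): AAGG x 11, spacer, AAGG x 14
fix_pattern2 <- function() {
    build_pattern("DYS385", left_flank = fix_flank_L,
                  units = c("AAGG", "AAGG"), copies = c(11L, 14L),
                  spacers = c("TCCTGT", ""), right_flank = fix_flank_R,
                  chrom = "chrY", ref_start = 20801599L, ref_end = 20801642L)
}

# exact read rendering a pattern with padding on both sides
fix_read <- function(pattern, copies = NULL,
                     pad_l = "TGTGTGAGACCTA", pad_r = "CATGGAACCTTGA") {
    paste0(pad_l, render_locus(pattern, copies), pad_r)
}

revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# unbanded reference edit distance, independent of the package DP
lev <- function(a, b) as.integer(utils::adist(a, b))

# random DNA string helper for property tests
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
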