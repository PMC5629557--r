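test_that("read_sequences auto-detects FASTA/FASTQ and gzip", {
    fa <- tempfile(fileext = ".fa")
    writeLines(c(">a desc", "ACGT", ">b", "", ">c", "GGGG"), fa)
    x <- read_sequences(fa)
    expect_length(x, 3L)
    expect_equal(as.character(x[[2]]), "")   # empty record allowed

    fq <- tempfile(fileext = ".fq.gz")
    con <- gzfile(fq, "wt")
    writeLines(unlist(lapply(1:10, function(i)
        c(paste0("@r", i), "ACGTACGTAC", "+", "IIIIIIIIII"))), con)
    close(con)
    y <- read_sequences(fq)
    expect_length(y, 10L)
    expect_equal(unname(as.character(y[1])), "ACGTACGTAC")

    # paired files stream sequentially
    z <- read_sequences(c(fa, fq))
    expect_length(z, 13L)

    bad <- tempfile()
    writeLines("not a sequence file", bad)
    expect_error(read_sequences(bad), "format")
    expect_error(read_sequences("/nonexistent/reads.fq"), "cannot open")
})

test_that("scan_read calls planted loci and spans multiple loci per read", {
    params <- scan_params()
    panel <- make_panel(4, seed = 101)
    idx <- index_patterns(panel, params)

    read <- fix_read(panel[[1]])
    calls <- scan_read("r1", read, idx, params)
    expect_length(calls, 1L)
    expect_equal(calls[[1]]$marker, panel[[1]]$marker)
    expect_equal(calls[[1]]$copies, panel[[1]]$copies)
    expect_equal(calls[[1]]$read_id, "r1")

    # a read concatenating two loci supports both markers
    read2 <- paste0(fix_read(panel[[1]]), fix_read(panel[[2]]))
    calls2 <- scan_read("r2", read2, idx, params)
    expect_setequal(vapply(calls2, `[[`, character(1), "marker"),
                    c(panel[[1]]$marker, panel[[2]]$marker))

    expect_length(scan_read("r3", strrep("GATC", 40), idx, params), 0L)
})

test_that("profile_reads aggregates alleles and flags multi-allelic loci", {
    params <- scan_params()
    panel <- make_panel(3, seed = 102, two_unit_frac = 0)
    p <- panel[[1]]

    # haploid: 10 reads of one allele
    reads <- setNames(
        vapply(1:10, function(i) fix_read(p, copies = p$copies + 2L),
               character(1)),
        paste0("r", 1:10))
    prof <- profile_reads(reads, panel, params)
    pr <- prof$profiles[[p$marker]]
    expect_equal(nrow(pr$alleles), 1L)
    expect_equal(pr$alleles$count, 10L)
    expect_false(pr$multi_allelic)
    # loci with zero support are present with empty allele tables
    expect_equal(nrow(prof$profiles[[panel[[2]]$marker]]$alleles), 0L)

    # heterozygous: two alleles, multi-allelic
    reads2 <- setNames(
        c(vapply(1:4, function(i) fix_read(p, copies = 11L), character(1)),
          vapply(1:6, function(i) fix_read(p, copies = 14L), character(1))),
        paste0("r", 1:10))
    prof2 <- profile_reads(reads2, panel, params)
    pr2 <- prof2$profiles[[p$marker]]
    expect_equal(nrow(pr2$alleles), 2L)
    expect_true(pr2$multi_allelic)
    expect_setequal(pr2$alleles$count, c(4L, 6L))

    # empty read stream: every locus present, no alleles anywhere
    prof0 <- profile_reads(setNames(character(0), character(0)), panel, params)
    expect_length(prof0$profiles, 3L)
    expect_true(all(vapply(prof0$profiles, function(x)
        nrow(x$alleles) == 0L, logical(1))))
})

test_that("profile invariants hold and counts are read-order invariant", {
    params <- scan_params()
    panel <- make_panel(4, seed = 103)
    am <- list(list(panel[[1]]$copies, panel[[1]]$copies + 3L))
    names(am) <- panel[[1]]$marker
    sim <- simulate_reads(panel, allele_model = am, read_length = 600,
                          n_reads_per_locus = 6, seed = 104)
    prof <- profile_reads(sim$reads, panel, params)
    for (pr in prof$profiles) {
        expect_lte(sum(pr$alleles$count), length(sim$reads))
        expect_identical(pr$multi_allelic, nrow(pr$alleles) >= 2L)
    }
    # shuffling input reads changes no allele count
    set.seed(105)
    shuf <- sim$reads[sample(length(sim$reads))]
    prof_s <- profile_reads(shuf, panel, params)
    for (mk in names(prof$profiles)) {
        a <- prof$profiles[[mk]]$alleles
        b <- prof_s$profiles[[mk]]$alleles
        expect_equal(a[order(a$signature), ], b[order(b$signature), ],
                     ignore_attr = TRUE)
    }
})

test_that("reports are byte-stable and parse back to the same alleles", {
    params <- scan_params()
    panel <- make_panel(2, seed = 106, two_unit_frac = 0)
    p <- panel[[1]]
    reads <- setNames(
        c(vapply(1:6, function(i) fix_read(p, copies = 14L), character(1)),
          vapply(1:4, function(i) fix_read(p, copies = 11L), character(1))),
        paste0("r", 1:10))
    prof <- profile_reads(reads, panel, params)
    pre <- tempfile()
    write_report(prof, pre, per_read_calls = TRUE)
    expect_true(file.exists(paste0(pre, ".profile.tsv")))
    expect_true(file.exists(paste0(pre, ".calls.tsv")))

    tab <- read.delim(paste0(pre, ".profile.tsv"), comment.char = "#")
    expect_equal(tab$marker, vapply(panel, `[[`, character(1), "marker"))
    cell <- tab$alleles[1]
    expect_equal(cell, "14(6),11(4)")   # descending support order
    # reference reader: parse the allele cell back to a multiset
    parts <- regmatches(cell, gregexpr("[0-9/]+\\([0-9]+\\)", cell))[[1]]
    sig <- sub("\\(.*", "", parts)
    cnt <- as.integer(sub(".*\\((\\d+)\\)", "\\1", parts))
    got <- prof$profiles[[p$marker]]$alleles
    expect_setequal(paste(sig, cnt), paste(got$signature, got$count))

    # byte-stable on rerun
    pre2 <- tempfile()
    write_report(profile_reads(reads, panel, params), pre2,
                 per_read_calls = TRUE)
    expect_identical(readLines(paste0(pre, ".profile.tsv")),
                     readLines(paste0(pre2, ".profile.tsv")))
    expect_identical(readLines(paste0(pre, ".calls.tsv")),
                     readLines(paste0(pre2, ".calls.tsv")))
})
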