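seed_for <- function(read, pattern, params = scan_params()) {
    idx <- index_patterns(list(pattern), params)
    hits <- find_seeds(read, idx, params)
    hits <- hits[hits$strand == "+", , drop = FALSE]
    as.list(hits[1, ])
}

test_that("truncated seed copies are completed gap-free", {
    p <- fix_pattern1()
    params <- scan_params(k = 18)
    # seed ATCCATCCATCCATCCAT (k=18) followed in the read by CC
    read <- fix_read(p)
    sd <- seed_for(read, p, params)
    st <- complete_truncated_unit(sd, read, p)
    expect_equal(st$D, 0L)
    expect_equal(st$m[1], 5L)
    expect_equal(st$end - sd$end, 2L)   # cursor advanced over the completion

    # same seed followed by CG: one positional mismatch
    run_at <- sd$start
    read2 <- read
    substr(read2, sd$end + 2L, sd$end + 2L) <- "G"
    st2 <- complete_truncated_unit(sd, read2, p)
    expect_equal(st2$D, 1L)
    expect_equal(st2$m[1], 5L)

    # seed ending exactly on a copy boundary: no truncation, no distance
    params20 <- scan_params(k = 20)
    sd20 <- seed_for(read, p, params20)
    st20 <- complete_truncated_unit(sd20, read, p)
    expect_equal(st20$D, 0L)
    expect_equal(st20$m[1], 5L)
    expect_equal(st20$end, sd20$end)
})

test_that("3' steps pick the minimum-distance candidate", {
    p <- fix_pattern1()
    params <- scan_params(k = 20)
    read <- fix_read(p)
    sd <- seed_for(read, p, params)
    st <- complete_truncated_unit(sd, read, p)

    # inside the run: one more exact copy at distance 0
    st1 <- extend_3prime_step(st, read, p, params)
    expect_equal(st1$m[1], 6L)
    expect_equal(st1$D, 0L)
    expect_false(st1$reached_s_R)

    # at the end of the run the flank fits at 0 and is chosen
    st_end <- st
    while (!st_end$reached_s_R && !st_end$stopped3)
        st_end <- extend_3prime_step(st_end, read, p, params)
    expect_true(st_end$reached_s_R)
    expect_equal(st_end$m[1], 8L)
    expect_equal(st_end$D, 0L)
    expect_equal(st_end$anchor_R, nchar(fix_flank_R))

    # a flank that fits at 0 beats a next copy that would cost 1: pattern
    # whose right flank starts one substitution away from the unit
    tricky <- build_pattern("TRICKY", fix_flank_L, "ATCC", 8L,
                            right_flank = paste0("ATGC", fix_flank_R))
    read3 <- fix_read(tricky)
    sd3 <- seed_for(read3, tricky, params)
    st3 <- complete_truncated_unit(sd3, read3, tricky)
    while (!st3$reached_s_R && !st3$stopped3)
        st3 <- extend_3prime_step(st3, read3, tricky, params)
    expect_true(st3$reached_s_R)
    expect_equal(st3$D, 0L)
    expect_equal(st3$m[1], 8L)   # the 1-mismatch pseudo-copy was not taken
})

test_that("5' extension mirrors the 3' side and stops at the read start", {
    p <- fix_pattern1()
    params <- scan_params(k = 20)
    read <- fix_read(p)
    sd <- seed_for(read, p, params)
    st <- complete_truncated_unit(sd, read, p)
    while (!st$reached_s_L && !st$stopped5)
        st <- extend_5prime_step(st, read, p, params)
    expect_true(st$reached_s_L)
    expect_equal(st$D, 0L)
    expect_equal(st$anchor_L, nchar(fix_flank_L))

    # 5' context exhausted before the flank anchor: stop without the flank
    bare <- paste0(substr(fix_flank_L, nchar(fix_flank_L) - 2L, nchar(fix_flank_L)),
                   strrep("ATCC", 8), fix_flank_R)   # only 3 flank bases
    sd2 <- seed_for(bare, p, params)
    st2 <- complete_truncated_unit(sd2, bare, p)
    while (!st2$reached_s_L && !st2$stopped5)
        st2 <- extend_5prime_step(st2, bare, p, params)
    expect_false(st2$reached_s_L)
    expect_true(st2$stopped5)
})

test_that("extend_alignment accepts exactly contained loci and applies the copy slack", {
    p <- fix_pattern1()      # reference 8 copies
    params <- scan_params(k = 20, epsilon = 2)
    read10 <- fix_read(p, copies = 10L)
    sd <- seed_for(read10, p, params)
    call <- extend_alignment(sd, read10, p, params)
    expect_s3_class(call, "str_call")
    expect_equal(call$copies, 10L)
    expect_equal(call$distance, 0L)
    expect_gte(call$distance, brute_force_distance(
        substr(read10, call$start, call$end), p, epsilon = 2))

    # with epsilon = 1 the 10-copy run cannot be traversed cleanly
    params1 <- scan_params(k = 20, epsilon = 1)
    call1 <- extend_alignment(sd, read10, p, params1)
    expect_true(is.null(call1) || call1$distance > 0L)

    # a read starting mid-run (left flank missing) is rejected
    noflank <- paste0(strrep("ATCC", 8), fix_flank_R)
    sd2 <- seed_for(noflank, p, params)
    expect_null(extend_alignment(sd2, noflank, p, params))
})

test_that("count_copies reports whole copies per unit in pattern order", {
    p2 <- fix_pattern2()
    params <- scan_params(k = 18)
    read <- fix_read(p2)
    sd <- seed_for(read, p2, params)
    call <- extend_alignment(sd, read, p2, params)
    cc <- count_copies(call)
    expect_equal(cc$unit, c("AAGG", "AAGG"))
    expect_equal(cc$copies, c(11L, 14L))
    expect_equal(call$distance, 0L)
})

test_that("error-free fully contained loci are always recovered exactly", {
    params <- scan_params()
    panel <- make_panel(8, seed = 301)
    for (p in panel) {
        for (extra in c(-2L, 0L, 3L)) {
            m <- pmax(p$copies + extra,
                      ceiling(params$k / nchar(p$units)))  # keep run seedable
            read <- fix_read(p, copies = m)
            idx <- index_patterns(list(p), params)
            calls <- scan_read("r", read, idx, params)
            expect_length(calls, 1L)
            expect_equal(calls[[1]]$copies, as.integer(m))
            expect_equal(calls[[1]]$distance, 0L)
        }
    }
})

test_that("calls are strand symmetric and deterministic", {
    params <- scan_params()
    panel <- make_panel(5, seed = 302)
    idx <- index_patterns(panel, params)
    for (p in panel) {
        read <- fix_read(p)
        fwd <- scan_read("r", read, idx, params)
        rev <- scan_read("r", revcomp(read), idx, params)
        expect_equal(length(fwd), length(rev))
        pick <- function(cs) lapply(cs, function(x)
            list(x$marker, x$copies, x$distance))
        expect_equal(pick(fwd), pick(rev))
        # determinism: identical inputs give identical calls
        expect_identical(fwd, scan_read("r", read, idx, params))
    }
})

test_that("greedy distance never undercuts the exact partition distance", {
    params <- scan_params(epsilon = 3)
    set.seed(303)
    checked <- 0L
    for (case in 1:40) {
        panel <- make_panel(1, unit_lengths = 3:5, copy_range = c(7, 10),
                            flank_length = 20, two_unit_frac = 0,
                            seed = 500 + case)
        p <- panel[[1]]
        q <- render_locus(p)
        n_sub <- sample(0:2, 1)
        if (n_sub > 0) {
            ch <- strsplit(q, "")[[1]]
            for (x in sample(nchar(q), n_sub))
                ch[x] <- sample(setdiff(c("A", "C", "G", "T"), ch[x]), 1)
            q <- paste(ch, collapse = "")
        }
        idx <- index_patterns(panel, params)
        calls <- scan_read("q", q, idx, params)
        if (length(calls) == 0L) next
        exact <- brute_force_distance(q, p, epsilon = 3)
        expect_gte(calls[[1]]$distance, exact)
        if (n_sub == 0L) expect_equal(calls[[1]]$distance, 0L)
        checked <- checked + 1L
    }
    expect_gte(checked, 30L)
})
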