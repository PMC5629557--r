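# Synthetic panels and reads with planted STR alleles and noise, plus
# ground-truth tables, so the whole pipeline is testable without external
# data. All generators are deterministic given `seed`.

.with_seed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(seed)
    force(code)
}

.rand_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.is_periodic <- function(unit) {
    L <- nchar(unit)
    if (L == 1L) return(FALSE)
    for (d in seq_len(L - 1L)) {
        if (L %% d == 0L && strrep(substr(unit, 1L, d), L %/% d) == unit)
            return(TRUE)
    }
    FALSE
}

# sample one/several values from a vector (avoiding sample()'s scalar
# interpretation when the vector has length one)
.sample_from <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]

# boundary screen: the |unit| bases of context adjacent to a tandem run
# must differ from the unit in >= 2 positions (>= 1 for single-base units),
# so that the greedy choice between "one more copy" and "leave the run" is
# never ambiguous at zero error (see the methods vignette).
.boundary_ok <- function(unit, context_after) {
    L <- nchar(unit)
    if (nchar(context_after) < L) return(FALSE)
    .substr_mismatches(substr(context_after, 1L, L), unit) >= min(2L, L)
}

#' Generate a random STR panel
#'
#' Draws `n_loci` random patterns: aperiodic units with lengths from
#' `unit_lengths`, reference copy numbers uniform in `copy_range`, random
#' flanks of `flank_length` bases, and a fraction `two_unit_frac` of loci
#' with two unit runs separated by a spacer (as in compound Y-STR markers).
#' Flanks and spacers are resampled until the context adjacent to each
#' tandem run differs from the run's unit in at least 2 of its first bases,
#' so that run boundaries are unambiguous in error-free sequence.
#'
#' @param n_loci Number of loci.
#' @param unit_lengths Integer vector of admissible unit lengths (1--6).
#' @param copy_range Length-2 integer vector, inclusive range of reference
#'   copy numbers.
#' @param flank_length Flank length in bases.
#' @param two_unit_frac Fraction of loci given a second unit run.
#' @param spacer_range Length-2 range of spacer lengths for two-unit loci.
#' @param seed RNG seed; identical seeds give identical panels.
#' @return List of `str_pattern` objects named `SYN001`, `SYN002`, ...
#' @export
make_panel <- function(n_loci, unit_lengths = 3:6, copy_range = c(8L, 30L),
                       flank_length = 30L, two_unit_frac = 0.15,
                       spacer_range = c(4L, 8L), seed = NULL) {
    stopifnot(n_loci >= 1L, length(unit_lengths) >= 1L,
              all(unit_lengths >= 1L & unit_lengths <= 6L),
              copy_range[1] >= 1L, copy_range[2] >= copy_range[1],
              flank_length >= 1L)
    .with_seed(seed, {
        lapply(seq_len(n_loci), function(i) {
            n_units <- 1L + as.integer(stats::runif(1) < two_unit_frac)
            units <- character(n_units)
            for (u in seq_len(n_units)) {
                repeat {
                    cand <- .rand_dna(.sample_from(unit_lengths))
                    if (!.is_periodic(cand)) { units[u] <- cand; break }
                }
            }
            copies <- .sample_from(seq(copy_range[1], copy_range[2]), n_units)
            spacers <- character(n_units)
            if (n_units == 2L) {
                repeat {
                    sp <- .rand_dna(.sample_from(seq(spacer_range[1], spacer_range[2])))
                    # context after run 1 is spacer+unit2..., before run 2 ends with spacer
                    if (.boundary_ok(units[1], paste0(sp, units[2])) &&
                        .boundary_ok(.str_reverse(units[2]),
                                     .str_reverse(paste0(units[1], sp)))) {
                        spacers[1] <- sp
                        break
                    }
                }
            }
            repeat {
                lf <- .rand_dna(flank_length)
                if (.boundary_ok(.str_reverse(units[1]), .str_reverse(lf)))
                    break
            }
            repeat {
                rf <- .rand_dna(flank_length)
                if (.boundary_ok(units[n_units], rf)) break
            }
            build_pattern(sprintf("SYN%03d", i), left_flank = lf,
                          units = units, copies = copies, spacers = spacers,
                          right_flank = rf, chrom = "chrS",
                          ref_start = 1000L * i,
                          ref_end = 1000L * i + sum(copies * nchar(units)))
        })
    })
}

#' Render a locus sequence
#'
#' Concatenates left flank, unit runs (at reference copies or at
#' `copies` overrides) with their spacers, and right flank.
#'
#' @param pattern An `str_pattern`.
#' @param copies Optional integer vector of per-unit copy numbers.
#' @return DNA string of the rendered locus.
#' @export
render_locus <- function(pattern, copies = NULL) {
    stopifnot(inherits(pattern, "str_pattern"))
    if (is.null(copies)) copies <- pattern$copies
    stopifnot(length(copies) == pattern$n, all(copies >= 0L))
    runs <- paste0(vapply(seq_len(pattern$n), function(i)
        paste0(strrep(pattern$units[i], copies[i]), pattern$spacers[i]),
        character(1)), collapse = "")
    paste0(pattern$left_flank, runs, pattern$right_flank)
}

.apply_substitutions <- function(seq, positions) {
    if (length(positions) == 0L) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (p in positions) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    paste(chars, collapse = "")
}

# padding screened so no seed k-mer appears outside the planted locus
.screened_read <- function(locus_seq, read_length, offset, index, max_tries = 20L) {
    span <- nchar(locus_seq)
    left_n <- offset
    right_n <- read_length - span - offset
    for (try in seq_len(max_tries)) {
        read <- paste0(.rand_dna(left_n), locus_seq, .rand_dna(right_n))
        hits <- .raw_hits(read, index)
        ok_lo <- left_n + 1L
        ok_hi <- left_n + span - index$k + 1L
        if (nrow(hits) == 0L ||
            all(hits$pos >= ok_lo & hits$pos <= ok_hi))
            return(read)
    }
    read       # accept last draw; spurious seeds are astronomically unlikely
}

#' Simulate reads with planted STR alleles
#'
#' Each read carries one locus rendered at a planted allele, embedded in
#' random padding screened to contain no panel seed k-mer outside the
#' locus. When the read is long enough the locus is fully contained at a
#' random offset; otherwise the read is a window centred at a random
#' position inside the locus (partial containment). Substitution errors are
#' planted i.i.d. per base at `error_rate` (optionally single-base indels
#' at `indel_rate`), and about half the reads are reverse-complemented.
#'
#' @param patterns List of `str_pattern` objects.
#' @param allele_model Named list, one entry per marker: an integer vector
#'   of per-unit copies (haploid) or a list of such vectors (each read
#'   draws one uniformly, e.g. two vectors for a heterozygous locus).
#'   Missing markers use reference copies.
#' @param read_length Read length in bases.
#' @param n_reads_per_locus Reads simulated per locus.
#' @param error_rate Per-base substitution probability.
#' @param indel_rate Per-read probability of one random single-base indel
#'   inside the locus (default 0, keeping truth copy numbers exact).
#' @param revcomp_frac Fraction of reads reverse-complemented.
#' @param params [scan_params()], used only for the padding screen (k).
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id`, `marker`, `copies` (`/`-joined), `n_errors`,
#'   `error_pos` (`;`-joined, pre-strand coordinates), `strand`,
#'   `locus_start`, `locus_end` (forward-read coordinates),
#'   `fully_contained`).
#' @export
simulate_reads <- function(patterns, allele_model = NULL, read_length = 1000L,
                           n_reads_per_locus = 10L, error_rate = 0,
                           indel_rate = 0, revcomp_frac = 0.5,
                           params = scan_params(), seed = NULL) {
    stopifnot(read_length >= 1L, n_reads_per_locus >= 1L,
              error_rate >= 0, error_rate <= 1)
    index <- index_patterns(patterns, params)
    .with_seed(seed, {
        reads <- character(0)
        truth <- list()
        rid <- 0L
        for (p in patterns) {
            alleles <- allele_model[[p$marker]]
            if (is.null(alleles)) alleles <- list(p$copies)
            if (!is.list(alleles)) alleles <- list(as.integer(alleles))
            for (r in seq_len(n_reads_per_locus)) {
                rid <- rid + 1L
                copies <- as.integer(alleles[[sample.int(length(alleles), 1L)]])
                locus_seq <- render_locus(p, copies)
                span <- nchar(locus_seq)
                if (span <= read_length) {
                    offset <- sample.int(read_length - span + 1L, 1L) - 1L
                    read <- .screened_read(locus_seq, read_length, offset, index)
                    locus_start <- offset + 1L
                    locus_end <- offset + span
                    contained <- TRUE
                } else {
                    centre <- sample.int(span, 1L)
                    win_start <- max(1L, min(centre - read_length %/% 2L,
                                             span - read_length + 1L))
                    read <- substr(locus_seq, win_start,
                                   win_start + read_length - 1L)
                    locus_start <- 1L
                    locus_end <- nchar(read)
                    contained <- FALSE
                }
                err_pos <- which(stats::runif(nchar(read)) < error_rate)
                read <- .apply_substitutions(read, err_pos)
                n_indel <- 0L
                if (indel_rate > 0 && stats::runif(1) < indel_rate) {
                    pos <- sample.int(nchar(read), 1L)
                    if (stats::runif(1) < 0.5) {
                        read <- paste0(substr(read, 1L, pos - 1L),
                                       substr(read, pos + 1L, nchar(read)))
                    } else {
                        read <- paste0(substr(read, 1L, pos),
                                       .rand_dna(1L),
                                       substr(read, pos + 1L, nchar(read)))
                    }
                    n_indel <- 1L
                }
                strand <- if (stats::runif(1) < revcomp_frac) "-" else "+"
                Lr <- nchar(read)
                if (strand == "-") {
                    read <- .revcomp(read)
                    ls <- Lr - locus_end + 1L
                    le <- Lr - locus_start + 1L
                    locus_start <- ls; locus_end <- le
                }
                id <- sprintf("r%05d_%s", rid, p$marker)
                reads[id] <- read
                truth[[rid]] <- data.frame(
                    read_id = id, marker = p$marker,
                    copies = paste(copies, collapse = "/"),
                    n_errors = length(err_pos) + n_indel,
                    error_pos = paste(err_pos, collapse = ";"),
                    strand = strand,
                    locus_start = locus_start, locus_end = locus_end,
                    fully_contained = contained,
                    stringsAsFactors = FALSE)
            }
        }
        list(reads = reads, truth = do.call(rbind, truth))
    })
}

#' Write simulated reads as FASTQ
#'
#' @param reads Named character vector of sequences.
#' @param path Output path (`.gz` suffix enables compression via
#'   [Biostrings::writeXStringSet()]).
#' @export
write_reads_fastq <- function(reads, path) {
    x <- Biostrings::DNAStringSet(reads)
    Biostrings::writeXStringSet(
        x, path, format = "fastq",
        compress = grepl("\\.gz$", path),
        qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(x))))
    invisible(path)
}

#' Compare profiling calls with simulation truth
#'
#' For every truth record, checks whether the pipeline produced a call for
#' that read and marker and whether the called copy numbers equal the
#' planted ones. Recovery statistics are reported over the reads whose
#' locus was fully contained (partial reads cannot satisfy the both-flank
#' rule by construction).
#'
#' @param profiles `str_profiles` from [profile_reads()].
#' @param truth Truth data.frame from [simulate_reads()].
#' @return List with `n_eligible` (fully contained truth reads), `n_called`,
#'   `n_correct` (called with the planted copies), `recall`,
#'   `copy_accuracy` (fraction of calls with planted copies), and the
#'   per-read merge table `detail`.
#' @export
evaluate_against_truth <- function(profiles, truth) {
    cdf <- .calls_df(profiles$calls)
    key <- paste(cdf$read_id, cdf$marker)
    eligible <- truth[truth$fully_contained, , drop = FALSE]
    idx <- match(paste(eligible$read_id, eligible$marker), key)
    called <- !is.na(idx)
    correct <- called & cdf$copies[idx] == eligible$copies
    detail <- data.frame(eligible,
                         called = called,
                         called_copies = ifelse(called, cdf$copies[idx], NA),
                         correct = correct,
                         stringsAsFactors = FALSE)
    list(n_eligible = nrow(eligible),
         n_called = sum(called),
         n_correct = sum(correct),
         recall = if (nrow(eligible)) mean(called) else NA_real_,
         copy_accuracy = if (any(called)) sum(correct) / sum(called) else NA_real_,
         detail = detail)
}
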