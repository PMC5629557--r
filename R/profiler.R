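# End-to-end pipeline: read streaming, per-read scanning, per-locus
# aggregation into allele profiles, and TSV reports.

#' Read sequences from FASTA or FASTQ
#'
#' The format is auto-detected from the first record character (`>` FASTA,
#' `@` FASTQ); gzip compression is handled transparently. FASTQ qualities
#' are read and discarded. When two paths are given (paired files) they are
#' streamed sequentially: mates are independent reads to the scanner.
#'
#' @param path Character vector of one or two file paths.
#' @return A named [Biostrings::DNAStringSet] in file order.
#' @export
read_sequences <- function(path) {
    one <- function(p) {
        if (!file.exists(p)) stop("cannot open reads file: ", p)
        con <- gzfile(p, "rt")
        on.exit(close(con))
        first <- ""
        while (!nzchar(first)) {
            ln <- readLines(con, n = 1L)
            if (length(ln) == 0L) break
            first <- trimws(ln)
        }
        fmt <- if (startsWith(first, ">")) "fasta"
               else if (startsWith(first, "@")) "fastq"
               else stop("cannot detect FASTA/FASTQ format of ", p)
        Biostrings::readDNAStringSet(p, format = fmt)
    }
    sets <- lapply(path, one)
    if (length(sets) == 1L) sets[[1L]] else do.call(c, sets)
}

#' Scan one read against the panel
#'
#' Finds collapsed seed matches ([find_seeds()]) and extends each
#' ([extend_alignment()]) on the read in pattern orientation (minus-strand
#' seeds are extended on the reverse complement and mapped back). Among
#' multiple accepted calls for the same marker, the one with minimal
#' distance is kept (ties: most total copies, then leftmost on the forward
#' read); a read may still support several distinct markers.
#'
#' @param read_id Read identifier attached to the returned calls.
#' @param read DNA string.
#' @param index `seed_index` from [index_patterns()].
#' @param params The [scan_params()] used to build the index.
#' @return List of `str_call` objects with forward-read coordinates.
#' @export
scan_read <- function(read_id, read, index, params = scan_params()) {
    read <- .clean_read(read)
    seeds <- find_seeds(read, index, params)
    if (nrow(seeds) == 0L) return(list())
    L <- nchar(read)
    rc <- if (any(seeds$strand == "-")) .revcomp(read) else NULL

    calls <- list()
    for (s in seq_len(nrow(seeds))) {
        row <- seeds[s, , drop = FALSE]
        pattern <- index$patterns[[row$pattern]]
        if (row$strand == "+") {
            oriented <- read
            oseed <- list(pattern = row$pattern, unit = row$unit,
                          start = row$start, end = row$end,
                          phase = row$phase, strand = "+")
        } else {
            oriented <- rc
            oseed <- list(pattern = row$pattern, unit = row$unit,
                          start = L - row$end + 1L, end = L - row$start + 1L,
                          phase = row$phase, strand = "-")
        }
        call <- extend_alignment(oseed, oriented, pattern, params)
        if (is.null(call)) next
        if (row$strand == "-") {
            os <- call$start; oe <- call$end
            call$start <- L - oe + 1L
            call$end <- L - os + 1L
        }
        call$read_id <- read_id
        calls[[length(calls) + 1L]] <- call
    }
    if (length(calls) <= 1L) return(calls)

    # best call per marker: min distance, then most copies, then leftmost
    markers <- vapply(calls, `[[`, character(1), "marker")
    keep <- lapply(split(seq_along(calls), markers), function(ix) {
        cs <- calls[ix]
        d <- vapply(cs, `[[`, integer(1), "distance")
        tot <- vapply(cs, function(x) sum(x$copies), integer(1))
        st <- vapply(cs, `[[`, integer(1), "start")
        ix[order(d, -tot, st)][1L]
    })
    calls[sort(unlist(keep, use.names = FALSE))]
}

.signature <- function(copies) paste(copies, collapse = "/")

#' Profile a set of reads against an STR panel
#'
#' Builds the seed index, scans every read, and aggregates accepted calls
#' per locus into allele profiles: each supporting read contributes its
#' per-unit copy-number signature to exactly one allele of a marker. A
#' locus with two or more distinct signatures among its supporting reads is
#' classified as multi-allelic.
#'
#' @param reads A named [Biostrings::DNAStringSet], named character vector,
#'   or path(s) to FASTA/FASTQ file(s).
#' @param patterns List of `str_pattern` objects (or a panel TSV path).
#' @param params A [scan_params()].
#' @return An `str_profiles` object: list with `profiles` (one entry per
#'   marker: `alleles` data.frame of `signature`/`count`, `read_ids`,
#'   `multi_allelic`), `calls` (all accepted `str_call`s in input order),
#'   `patterns` and `params`.
#' @examples
#' p <- build_pattern("EX1", strrep("ACGTC", 4), "ATCC", 8, NULL,
#'                    strrep("GGTCA", 4))
#' read <- paste0(strrep("ACGTC", 4), strrep("ATCC", 8), strrep("GGTCA", 4))
#' pr <- profile_reads(c(r1 = read), list(p))
#' as.data.frame(pr)
#' @export
profile_reads <- function(reads, patterns, params = scan_params()) {
    if (is.character(patterns) && length(patterns) == 1L &&
        file.exists(patterns))
        patterns <- read_panel(patterns)
    if (is.character(reads) && !is.null(names(reads))) {
        seqs <- reads
    } else if (is.character(reads)) {
        seqs <- as.character(read_sequences(reads))
    } else {
        seqs <- as.character(reads)
    }
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
    ids <- sub("\\s.*$", "", ids)        # first token of FASTA/FASTQ header

    index <- index_patterns(patterns, params)
    all_calls <- list()
    for (ri in seq_along(seqs)) {
        cs <- scan_read(ids[ri], seqs[[ri]], index, params)
        all_calls <- c(all_calls, cs)
    }

    profiles <- lapply(patterns, function(p) {
        list(marker = p$marker, alleles = data.frame(
                 signature = character(0), count = integer(0),
                 stringsAsFactors = FALSE),
             read_ids = list(), multi_allelic = FALSE)
    })
    names(profiles) <- vapply(patterns, `[[`, character(1), "marker")
    for (call in all_calls) {
        sig <- .signature(call$copies)
        pr <- profiles[[call$marker]]
        j <- match(sig, pr$alleles$signature)
        if (is.na(j)) {
            pr$alleles <- rbind(pr$alleles, data.frame(
                signature = sig, count = 1L, stringsAsFactors = FALSE))
            pr$read_ids[[sig]] <- call$read_id
        } else {
            pr$alleles$count[j] <- pr$alleles$count[j] + 1L
            pr$read_ids[[sig]] <- c(pr$read_ids[[sig]], call$read_id)
        }
        pr$multi_allelic <- nrow(pr$alleles) >= 2L
        profiles[[call$marker]] <- pr
    }

    structure(list(profiles = profiles, calls = all_calls,
                   patterns = patterns, params = params),
              class = "str_profiles")
}

#' @export
print.str_profiles <- function(x, ...) {
    df <- as.data.frame(x)
    cat("str_profiles over ", length(x$profiles), " loci, ",
        length(x$calls), " supporting calls\n", sep = "")
    print(df[, c("marker", "ref_copies", "n_supporting", "alleles",
                 "multi_allelic")])
    invisible(x)
}

.allele_cell <- function(alleles) {
    if (nrow(alleles) == 0L) return("")
    ord <- order(-alleles$count, alleles$signature)
    paste0(alleles$signature[ord], "(", alleles$count[ord], ")",
           collapse = ",")
}

#' @export
as.data.frame.str_profiles <- function(x, ...) {
    rows <- lapply(seq_along(x$patterns), function(i) {
        p <- x$patterns[[i]]
        pr <- x$profiles[[p$marker]]
        data.frame(marker = p$marker,
                   chrom = ifelse(is.na(p$chrom), ".", p$chrom),
                   start = p$ref_start, end = p$ref_end,
                   ref_copies = paste(p$copies, collapse = "/"),
                   n_supporting = sum(pr$alleles$count),
                   alleles = .allele_cell(pr$alleles),
                   multi_allelic = pr$multi_allelic,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

.calls_df <- function(calls) {
    if (length(calls) == 0L)
        return(data.frame(read_id = character(0), marker = character(0),
                          strand = character(0), start = integer(0),
                          end = integer(0), copies = character(0),
                          distance = integer(0), stringsAsFactors = FALSE))
    do.call(rbind, lapply(calls, function(x) data.frame(
        read_id = x$read_id, marker = x$marker, strand = x$strand,
        start = x$start, end = x$end, copies = .signature(x$copies),
        distance = x$distance, stringsAsFactors = FALSE)))
}

#' Write profiling reports
#'
#' Writes a locus-level TSV (`<prefix>.profile.tsv`): marker, coordinates,
#' reference copies, observed alleles as `signature(count)` entries joined
#' by commas in descending support order (multi-unit signatures join their
#' per-unit copies with `/`), and the multi-allelic flag. With
#' `per_read_calls = TRUE` a second TSV (`<prefix>.calls.tsv`) lists every
#' accepted call. Both files start with `#` comment lines echoing the scan
#' parameters.
#'
#' @param x An `str_profiles` object from [profile_reads()].
#' @param prefix Output path prefix.
#' @param per_read_calls Also write the per-read calls table.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, prefix, per_read_calls = FALSE) {
    stopifnot(inherits(x, "str_profiles"))
    hdr <- paste0("# strscan profile; k=", x$params$k,
                  " delta=", x$params$delta, " epsilon=", x$params$epsilon,
                  " band=", x$params$band,
                  " min_flank_anchor=", x$params$min_flank_anchor,
                  " both_strands=", x$params$both_strands)
    prof_path <- paste0(prefix, ".profile.tsv")
    df <- as.data.frame(x)
    con <- file(prof_path, "wt")
    writeLines(hdr, con)
    writeLines(paste(colnames(df), collapse = "\t"), con)
    if (nrow(df) > 0L)
        writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con)
    close(con)
    paths <- prof_path
    if (per_read_calls) {
        calls_path <- paste0(prefix, ".calls.tsv")
        cdf <- .calls_df(x$calls)
        con <- file(calls_path, "wt")
        writeLines(hdr, con)
        writeLines(paste(colnames(cdf), collapse = "\t"), con)
        if (nrow(cdf) > 0L)
            writeLines(do.call(paste, c(lapply(cdf, as.character), sep = "\t")),
                       con)
        close(con)
        paths <- c(paths, calls_path)
    }
    invisible(paths)
}
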