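# k-mer seeds of tandem repeats: seed construction, panel indexing, and
# exact seed search in reads (both strands), with collapsing of the many
# overlapping hits a long tandem run produces.

#' Build the length-k seed of a repetitive unit
#'
#' The seed is the first `k` bases of the infinite tandem repetition of
#' `unit`: whole copies followed by a truncated last copy when `k` is not a
#' multiple of the unit length.
#'
#' @param unit Repetitive unit (DNA string).
#' @param k Seed length; must be at least the unit length so the seed
#'   contains one full copy.
#' @return A DNA string of length `k`.
#' @examples
#' build_seed("ATCC", 18)  # "ATCCATCCATCCATCCAT"
#' @export
build_seed <- function(unit, k) {
    stopifnot(length(unit) == 1L, nzchar(unit))
    k <- as.integer(k)
    if (k < nchar(unit))
        stop("seed length k (", k, ") is shorter than the unit (",
             nchar(unit), "): the seed cannot contain one full copy")
    substr(strrep(unit, ceiling(k / nchar(unit))), 1L, k)
}

.rotations <- function(unit) {
    L <- nchar(unit)
    vapply(seq_len(L) - 1L, function(p)
        paste0(substr(unit, p + 1L, L), substr(unit, 1L, p)), character(1))
}

#' All phase seeds of a unit
#'
#' A read may enter a tandem run at any phase of the unit, so one seed per
#' distinct rotation of the unit is generated (a periodic unit such as
#' `"ATAT"` has fewer distinct rotations than its length).
#'
#' @inheritParams build_seed
#' @return Character vector of distinct length-`k` seeds, one per distinct
#'   rotation, in phase order.
#' @export
seed_phases <- function(unit, k) {
    seeds <- vapply(.rotations(unit), build_seed, character(1), k = k,
                    USE.NAMES = FALSE)
    seeds[!duplicated(seeds)]
}

#' Index a panel of STR patterns by tandem-repeat k-mer seeds
#'
#' For every pattern and unit, every distinct phase seed (see
#' [seed_phases()]) is entered into an exact-match k-mer index. Units whose
#' maximum admissible tandem run `(c_i + epsilon) * |s_i|` is shorter than
#' `k` can never contain a length-`k` seed and are skipped with a warning.
#'
#' @param patterns List of `str_pattern` objects with unique marker names.
#' @param params A [scan_params()] object.
#' @return A `seed_index` object used by [find_seeds()].
#' @export
index_patterns <- function(patterns, params = scan_params()) {
    stopifnot(inherits(params, "scan_params"))
    if (length(patterns) == 0L) stop("empty panel: nothing to index")
    stopifnot(all(vapply(patterns, inherits, logical(1), "str_pattern")))
    markers <- vapply(patterns, `[[`, character(1), "marker")
    if (anyDuplicated(markers))
        stop("duplicate marker names in panel: ",
             paste(unique(markers[duplicated(markers)]), collapse = ", "))

    k <- params$k
    entries <- new.env(parent = emptyenv())
    for (pi in seq_along(patterns)) {
        p <- patterns[[pi]]
        for (ui in seq_len(p$n)) {
            unit <- p$units[ui]
            if ((p$copies[ui] + params$epsilon) * nchar(unit) < k) {
                warning("marker ", p$marker, " unit ", ui, " (", unit, " x",
                        p$copies[ui], "): maximum tandem run shorter than k=",
                        k, "; unit not indexed")
                next
            }
            rots <- .rotations(unit)
            seen <- character(0)
            for (phase in seq_along(rots) - 1L) {
                seed <- build_seed(rots[phase + 1L], k)
                key_id <- paste0(seed, "\r", pi, "\r", ui)
                # periodic units: phases that yield the same seed are
                # equivalent modulo the period; keep the smallest phase
                if (key_id %in% seen) next
                seen <- c(seen, key_id)
                rec <- data.frame(pattern = pi, marker = p$marker, unit = ui,
                                  phase = phase, stringsAsFactors = FALSE)
                prev <- if (!is.null(entries[[seed]])) entries[[seed]] else NULL
                if (is.null(prev)) entries[[seed]] <- rec
                else if (!any(prev$pattern == pi & prev$unit == ui))
                    entries[[seed]] <- rbind(prev, rec)
            }
        }
    }
    keys <- ls(entries)
    if (length(keys) == 0L)
        stop("no unit in the panel is indexable at k=", k)
    entry_list <- mget(keys, envir = entries)
    flat <- do.call(rbind, entry_list)
    flat$key_idx <- rep.int(seq_along(keys), vapply(entry_list, nrow, integer(1)))
    lens <- vapply(seq_len(nrow(flat)), function(r)
        nchar(patterns[[flat$pattern[r]]]$units[flat$unit[r]]), integer(1))
    flat$len <- lens
    flat$lead <- (lens - flat$phase) %% lens
    flat$m0 <- (k - flat$lead) %/% lens
    structure(
        list(k = k,
             keys = keys,
             entries = entry_list,
             flat = flat,
             rows_by_key = unname(split(
                 seq_len(nrow(flat)),
                 factor(flat$key_idx, levels = seq_along(keys)))),
             pdict = Biostrings::PDict(Biostrings::DNAStringSet(keys)),
             patterns = patterns),
        class = "seed_index"
    )
}

#' @export
print.seed_index <- function(x, ...) {
    cat("seed_index: ", length(x$keys), " seeds (k=", x$k, ") over ",
        length(x$patterns), " patterns\n", sep = "")
    invisible(x)
}

.revcomp <- function(x) {
    chartr("ACGTN", "TGCAN", intToUtf8(rev(utf8ToInt(x))))
}

.clean_read <- function(read) {
    read <- toupper(read)
    gsub("[^ACGT]", "N", read)
}

# All exact hits of the index in a single oriented sequence.
# Returns data.frame(key_idx, pos) with 1-based start positions.
.raw_hits <- function(seq, index) {
    subject <- Biostrings::DNAString(seq)
    m <- Biostrings::matchPDict(index$pdict, subject)
    starts <- IRanges::start(m)
    nhit <- lengths(starts)
    data.frame(key_idx = rep.int(seq_along(nhit), nhit),
               pos = unlist(starts, use.names = FALSE))
}

#' Find collapsed seed matches in a read
#'
#' Searches all k-mers of the read (and, when `params$both_strands`, of its
#' reverse complement) against the seed index. Overlapping hits of the same
#' (pattern, unit, strand) tandem run are collapsed to the single hit whose
#' seed covers the most whole unit copies (ties: leftmost). Coordinates are
#' reported on the forward read, 1-based inclusive; minus-strand hits carry
#' the phase observed on the reverse complement (pattern orientation).
#'
#' @param read DNA string; reads shorter than `k` yield no matches, and
#'   non-ACGT characters never match a seed.
#' @param index A `seed_index` from [index_patterns()].
#' @param params The [scan_params()] the index was built with.
#' @return A data.frame with columns `marker`, `pattern`, `unit`, `start`,
#'   `end`, `phase`, `strand`, `m0` (whole copies covered by the seed).
#' @export
find_seeds <- function(read, index, params = scan_params()) {
    stopifnot(inherits(index, "seed_index"))
    k <- index$k
    empty <- data.frame(marker = character(0), pattern = integer(0),
                        unit = integer(0), start = integer(0), end = integer(0),
                        phase = integer(0), strand = character(0),
                        m0 = integer(0), stringsAsFactors = FALSE)
    read <- .clean_read(read)
    L <- nchar(read)
    if (L < k) return(empty)

    strands <- if (isTRUE(params$both_strands)) c("+", "-") else "+"
    out <- list()
    for (strand in strands) {
        seq <- if (strand == "+") read else .revcomp(read)
        hits <- .raw_hits(seq, index)
        if (nrow(hits) == 0L) next
        rows <- index$rows_by_key[hits$key_idx]
        ridx <- unlist(rows, use.names = FALSE)
        pos <- rep.int(hits$pos, lengths(rows))
        raw <- index$flat[ridx, c("marker", "pattern", "unit", "phase",
                                  "lead", "m0"), drop = FALSE]
        raw$ostart <- pos
        raw$strand <- strand
        out[[length(out) + 1L]] <- raw
    }
    if (length(out) == 0L) return(empty)
    raw <- do.call(rbind, out)
    raw$oend <- raw$ostart + k - 1L

    # collapse overlapping hits per (pattern, unit, strand) tandem run
    collapsed <- list()
    for (grp in split(raw, paste(raw$pattern, raw$unit, raw$strand))) {
        grp <- grp[order(grp$ostart), , drop = FALSE]
        run_id <- cumsum(c(1L, as.integer(
            grp$ostart[-1L] > grp$oend[-nrow(grp)] + 1L)))
        for (run in split(grp, run_id)) {
            # most whole copies; then copy-boundary-aligned (smallest leading
            # partial, so gap-free completion stays inside the run); then
            # leftmost
            best <- run[order(-run$m0, run$lead, run$ostart), ,
                        drop = FALSE][1L, , drop = FALSE]
            collapsed[[length(collapsed) + 1L]] <- best
        }
    }
    res <- do.call(rbind, collapsed)
    # map minus-strand intervals back to forward-read coordinates
    fwd_start <- ifelse(res$strand == "+", res$ostart, L - res$oend + 1L)
    fwd_end <- ifelse(res$strand == "+", res$oend, L - res$ostart + 1L)
    res <- data.frame(marker = res$marker, pattern = res$pattern,
                      unit = res$unit, start = as.integer(fwd_start),
                      end = as.integer(fwd_end), phase = res$phase,
                      strand = res$strand, m0 = res$m0,
                      stringsAsFactors = FALSE)
    res <- res[order(res$pattern, res$unit, res$strand, res$start), ,
               drop = FALSE]
    rownames(res) <- NULL
    res
}
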