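# STR locus patterns: construction, validation, panel TSV I/O.
#
# A locus is s_L (s_1)_{c_1} t_1 ... (s_n)_{c_n} s_R: left flank, n
# repetitive units with reference copy numbers, n spacers (the last one
# always empty), right flank. Coordinates in the panel file are 1-based
# inclusive and informational only; no reference genome is consulted.

.valid_dna <- function(x) grepl("^[ACGT]+$", x)

.check_dna <- function(x, field, allow_empty = FALSE) {
    if (length(x) != 1L || is.na(x)) stop("'", field, "' must be a single string")
    x <- toupper(x)
    if (nzchar(x)) {
        if (!.valid_dna(x))
            stop("'", field, "' contains non-ACGT characters: ", x)
    } else if (!allow_empty) {
        stop("'", field, "' must be a non-empty DNA string")
    }
    x
}

#' Build and validate an STR locus pattern
#'
#' @param marker_name Label for the locus (e.g. `"DYS385"`).
#' @param left_flank,right_flank Unique DNA sequence immediately upstream /
#'   downstream of the locus. Both must be non-empty: flanks anchor the
#'   termination of seed extension, so a locus without them cannot be called.
#' @param units Repetitive units, either a character vector or a list of
#'   `(unit, copies)` pairs. Each unit is a DNA string of length 1--6.
#' @param copies Integer vector of reference copy numbers, one per unit
#'   (ignored when `units` is a list of pairs).
#' @param spacers Character vector of intermediate sequences between
#'   consecutive repeat runs. Must have one entry per unit with the last
#'   entry empty, or one fewer entry than units, or be omitted for a
#'   single-unit locus.
#' @param chrom,ref_start,ref_end Optional reference coordinates (1-based
#'   inclusive), carried through to reports but never used in scanning.
#'
#' @return An object of class `str_pattern` with fields `marker`, `chrom`,
#'   `ref_start`, `ref_end`, `left_flank`, `units`, `copies`, `spacers`,
#'   `right_flank` and `n` (number of units).
#' @examples
#' build_pattern("X", left_flank = "ACGTACGTAC", units = "AT", copies = 3,
#'               right_flank = "GGCCGGCCGG")
#' @export
build_pattern <- function(marker_name, left_flank, units, copies = NULL,
                          spacers = NULL, right_flank,
                          chrom = NA_character_, ref_start = NA_integer_,
                          ref_end = NA_integer_) {
    if (length(marker_name) != 1L || is.na(marker_name) || !nzchar(marker_name))
        stop("'marker_name' must be a non-empty string")
    if (is.list(units)) {
        copies <- vapply(units, function(u) as.integer(u[[2]]), integer(1))
        units <- vapply(units, function(u) as.character(u[[1]]), character(1))
    }
    units <- as.character(units)
    copies <- as.integer(copies)
    n <- length(units)
    if (n < 1L) stop("a pattern needs at least one repetitive unit")
    if (length(copies) != n)
        stop("'copies' must have one entry per unit")
    if (anyNA(copies) || any(copies < 1L))
        stop("'copies' must be positive integers")
    units <- vapply(seq_len(n), function(i)
        .check_dna(units[[i]], paste0("units[", i, "]")), character(1))
    if (any(nchar(units) > 6L))
        stop("repetitive units must be at most 6 bases long")

    if (is.null(spacers)) spacers <- character(0)
    spacers <- as.character(spacers)
    if (length(spacers) == n - 1L) spacers <- c(spacers, "")
    if (length(spacers) != n)
        stop("'spacers' must have one entry per unit (last empty) or one fewer")
    spacers[is.na(spacers)] <- ""
    if (nzchar(spacers[n]))
        stop("the spacer after the last unit must be empty")
    spacers <- vapply(seq_len(n), function(i)
        .check_dna(spacers[[i]], paste0("spacers[", i, "]"), allow_empty = TRUE),
        character(1))

    left_flank <- .check_dna(left_flank, "left_flank")
    right_flank <- .check_dna(right_flank, "right_flank")

    chrom <- as.character(chrom)
    if (length(chrom) != 1L || is.na(chrom) || chrom %in% c("", ".", "NA"))
        chrom <- NA_character_

    structure(
        list(marker = as.character(marker_name),
             chrom = chrom,
             ref_start = suppressWarnings(as.integer(ref_start)),
             ref_end = suppressWarnings(as.integer(ref_end)),
             left_flank = left_flank,
             units = units,
             copies = copies,
             spacers = spacers,
             right_flank = right_flank,
             n = n),
        class = "str_pattern"
    )
}

#' @export
print.str_pattern <- function(x, ...) {
    runs <- paste0("(", x$units, ")", x$copies,
                   ifelse(nzchar(x$spacers), paste0(" ", x$spacers, " "), ""),
                   collapse = "")
    cat("str_pattern ", x$marker,
        if (!is.na(x$chrom)) paste0(" [", x$chrom, ":", x$ref_start, "-", x$ref_end, "]"),
        "\n  ", x$left_flank, " | ", runs, " | ", x$right_flank, "\n", sep = "")
    invisible(x)
}

.panel_columns <- c("marker", "chrom", "start", "end", "left_flank",
                    "units", "copies", "spacers", "right_flank")

.split_semi <- function(x, n) {
    out <- strsplit(x, ";", fixed = TRUE)[[1]]
    length(out) <- n          # pad with NA -> "" below
    out[is.na(out)] <- ""
    out
}

#' Read an STR panel file
#'
#' Parses the tab-separated panel format: one row per locus with columns
#' `marker`, `chrom`, `start`, `end`, `left_flank`, `units`, `copies`,
#' `spacers`, `right_flank`. Multi-unit loci join their per-unit fields
#' with `';'` (the trailing empty spacer may be omitted). Lines starting
#' with `#` are comments. Coordinates are 1-based inclusive.
#'
#' @param source Path to a panel TSV, or a connection.
#' @return A list of [build_pattern()] objects, in file order.
#' @export
read_panel <- function(source) {
    lines <- if (inherits(source, "connection")) readLines(source) else readLines(source)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    if (length(keep) == 0L) stop("panel file has no header line")
    header <- strsplit(lines[keep[1]], "\t", fixed = TRUE)[[1]]
    if (!identical(header, .panel_columns))
        stop("panel header must be: ", paste(.panel_columns, collapse = "\t"))
    rows <- keep[-1]
    out <- vector("list", length(rows))
    for (idx in seq_along(rows)) {
        lineno <- rows[idx]
        fields <- strsplit(lines[lineno], "\t", fixed = TRUE)[[1]]
        if (length(fields) != length(.panel_columns))
            stop("line ", lineno, ": expected ", length(.panel_columns),
                 " tab-separated columns, found ", length(fields))
        units <- strsplit(fields[6], ";", fixed = TRUE)[[1]]
        n <- length(units)
        if (n == 0L) stop("line ", lineno, ": empty 'units' field")
        copies_raw <- strsplit(fields[7], ";", fixed = TRUE)[[1]]
        if (length(copies_raw) != n)
            stop("line ", lineno, ": 'copies' must list one integer per unit")
        copies <- suppressWarnings(as.integer(copies_raw))
        if (anyNA(copies))
            stop("line ", lineno, ": 'copies' must list one integer per unit")
        spacers_raw <- strsplit(fields[8], ";", fixed = TRUE)[[1]]
        if (!(length(spacers_raw) %in% c(n, n - 1L)))
            stop("line ", lineno, ": 'spacers' must list one entry per unit ",
                 "(trailing empty entry may be omitted)")
        spacers <- .split_semi(fields[8], n)
        out[[idx]] <- tryCatch(
            build_pattern(fields[1], left_flank = fields[5], units = units,
                          copies = copies, spacers = spacers,
                          right_flank = fields[9], chrom = fields[2],
                          ref_start = fields[3], ref_end = fields[4]),
            error = function(e) stop("line ", lineno, ": ", conditionMessage(e),
                                     call. = FALSE)
        )
    }
    out
}

#' Write an STR panel file
#'
#' Inverse of [read_panel()]: `read_panel()` on the written file reproduces
#' the pattern list field for field.
#'
#' @param patterns List of `str_pattern` objects.
#' @param sink Output path or connection.
#' @export
write_panel <- function(patterns, sink) {
    stopifnot(all(vapply(patterns, inherits, logical(1), "str_pattern")))
    rows <- vapply(patterns, function(p) {
        paste(p$marker,
              ifelse(is.na(p$chrom), ".", p$chrom),
              ifelse(is.na(p$ref_start), ".", p$ref_start),
              ifelse(is.na(p$ref_end), ".", p$ref_end),
              p$left_flank,
              paste(p$units, collapse = ";"),
              paste(p$copies, collapse = ";"),
              paste(p$spacers, collapse = ";"),
              p$right_flank,
              sep = "\t")
    }, character(1))
    writeLines(c(paste(.panel_columns, collapse = "\t"), rows), sink)
    invisible(NULL)
}
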