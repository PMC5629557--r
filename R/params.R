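#' Scan parameters
#'
#' Bundles the tuning parameters of the seed-and-extend scan.
#'
#' @param k Seed length in bases. Every seed is an exact `k`-mer taken from
#'   the tandem repetition of a repetitive unit, so `k` must be at least as
#'   long as the longest unit you want to detect (units whose maximum
#'   admissible run is shorter than `k` are skipped at indexing time).
#' @param delta Maximum total edit distance for an accepted occurrence of a
#'   locus in a read. An extension that would exceed `delta` stops.
#' @param epsilon Maximum deviation of an observed per-unit copy number from
#'   its reference value. The default is deliberately large so that copy
#'   number is effectively unconstrained upward; lower it to restrict calls
#'   to near-reference alleles.
#' @param band Maximum number of indels allowed in the alignment of any
#'   single pattern component (unit copy, spacer+unit, flank); implemented
#'   as the diagonal band of the component dynamic program.
#' @param min_flank_anchor Minimum number of flank bases that must align at
#'   each end of an accepted occurrence. Reads that stop inside a flank are
#'   accepted with a clipped anchor as long as at least this many flank
#'   bases align.
#' @param both_strands Scan the reverse complement of each read as well and
#'   report calls in pattern orientation.
#'
#' @return An object of class `scan_params`.
#' @examples
#' scan_params(k = 18, delta = 4)
#' @export
scan_params <- function(k = 18L, delta = 4L, epsilon = 30L, band = 3L,
                        min_flank_anchor = 8L, both_strands = TRUE) {
    k <- as.integer(k)
    delta <- as.integer(delta)
    epsilon <- as.integer(epsilon)
    band <- as.integer(band)
    min_flank_anchor <- as.integer(min_flank_anchor)
    stopifnot(length(k) == 1L, length(delta) == 1L, length(epsilon) == 1L,
              length(band) == 1L, length(min_flank_anchor) == 1L,
              is.logical(both_strands), length(both_strands) == 1L)
    if (is.na(k) || k < 1L) stop("'k' must be a positive integer")
    if (is.na(delta) || delta < 0L) stop("'delta' must be >= 0")
    if (is.na(epsilon) || epsilon < 0L) stop("'epsilon' must be >= 0")
    if (is.na(band) || band < 0L) stop("'band' must be >= 0")
    if (is.na(min_flank_anchor) || min_flank_anchor < 1L)
        stop("'min_flank_anchor' must be >= 1")
    structure(
        list(k = k, delta = delta, epsilon = epsilon, band = band,
             min_flank_anchor = min_flank_anchor,
             both_strands = isTRUE(both_strands)),
        class = "scan_params"
    )
}

#' @export
print.scan_params <- function(x, ...) {
    cat("scan_params: k=", x$k, " delta=", x$delta, " epsilon=", x$epsilon,
        " band=", x$band, " min_flank_anchor=", x$min_flank_anchor,
        " both_strands=", x$both_strands, "\n", sep = "")
    invisible(x)
}
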