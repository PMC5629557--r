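# Edit-distance machinery. The banded dynamic programs live in src/align.cpp;
# these wrappers add the budget/NONE semantics used by the extension engine
# and an exact partition-distance oracle for testing.

#' Banded global edit distance
#'
#' Unit-cost Levenshtein distance restricted to alignments whose total
#' number of indels is at most `band` (equivalently, the dynamic program is
#' confined to the diagonal band `|i - j| <= band`). When the length
#' difference of the two strings already exceeds `band`, no such alignment
#' exists and `Inf` is returned.
#'
#' @param a,b DNA strings (any character strings are accepted; comparison is
#'   by exact character identity).
#' @param band Maximum total number of indels (non-negative integer).
#' @return The banded edit distance, or `Inf` when infeasible.
#' @examples
#' banded_edit_distance("ACGT", "ACGGT", band = 1)  # 1
#' banded_edit_distance("ACGT", "ACGGT", band = 0)  # Inf
#' @export
banded_edit_distance <- function(a, b, band) {
    stopifnot(length(a) == 1L, length(b) == 1L)
    d <- .C_banded_edit_distance(a, b, as.integer(band))
    if (d < 0) Inf else d
}

#' Fit a component against a prefix (or suffix) of a read segment
#'
#' `fit_prefix()` aligns the whole string `s` against the best prefix of
#' `t`: among all prefixes `p` of `t` with `||p| - |s|| <= band`, it returns
#' the one minimizing the banded edit distance. Ties prefer the longer
#' prefix (consuming the full component length). `fit_suffix()` is the
#' mirror image on reversed strings: `s` is aligned against the best suffix
#' of `t`, and `consumed` counts bases from the right end of `t`.
#'
#' Both return `NULL` ("no admissible fit") when the best distance exceeds
#' `budget` or no prefix lies within the band, so callers can treat an
#' over-budget branch and an infeasible branch uniformly.
#'
#' @param s Component string to fit in full.
#' @param t Read segment supplying the prefix/suffix.
#' @param band Maximum indels in this component alignment.
#' @param budget Remaining edit-distance budget; fits with distance above it
#'   are rejected.
#' @return A list with `distance` and `consumed` (number of bases of `t`
#'   used), or `NULL`.
#' @examples
#' fit_prefix("ATCC", "ATTCGGGG", band = 2, budget = 5)  # distance 1, consumed 4
#' @export
fit_prefix <- function(s, t, band, budget = Inf) {
    r <- .C_fit_prefix(s, t, as.integer(band))
    if (r[1] < 0 || r[1] > budget) return(NULL)
    list(distance = r[1], consumed = r[2])
}

.str_reverse <- function(x) {
    vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                collapse = ""), character(1), USE.NAMES = FALSE)
}

#' @rdname fit_prefix
#' @export
fit_suffix <- function(s, t, band, budget = Inf) {
    fit_prefix(.str_reverse(s), .str_reverse(t), band, budget)
}

#' Exact partition distance between a string and an STR pattern (oracle)
#'
#' Computes the exact minimum, over all partitions of `Q` into
#' `(q_L, q_1, p_1, ..., q_n, p_n, q_R)` and all per-unit copy numbers `m_i`
#' with `|m_i - c_i| <= epsilon`, of
#' `D(q_L, s_L) + sum_i [D(q_i, s_i^{m_i}) + D(p_i, t_i)] + D(q_R, s_R)`
#' under unit-cost edit distance. Because edit distance decomposes over
#' concatenation, this equals the minimum over admissible `m` of the plain
#' edit distance between `Q` and the rendered locus
#' `s_L s_1^{m_1} t_1 ... s_n^{m_n} s_R`, which is how it is evaluated
#' (via `utils::adist`, independent of the banded DP and of the greedy
#' engine). The result is the exact, unbanded distance and therefore a
#' lower bound on what any banded greedy extension can achieve.
#'
#' This is a test oracle: it enumerates copy-number vectors exhaustively and
#' is guarded to small inputs (`nchar(Q) <= 300`, at most 3 units).
#'
#' @param Q Query DNA string.
#' @param P An `str_pattern`.
#' @param epsilon Maximum per-unit copy-number deviation.
#' @param band Accepted for interface symmetry with the greedy engine; the
#'   oracle itself is unbanded (see above).
#' @return Non-negative integer distance.
#' @export
brute_force_distance <- function(Q, P, epsilon, band = NULL) {
    stopifnot(inherits(P, "str_pattern"))
    if (nchar(Q) > 300L) stop("oracle guard: nchar(Q) must be <= 300")
    if (P$n > 3L) stop("oracle guard: patterns with more than 3 units not supported")
    epsilon <- as.integer(epsilon)
    ranges <- lapply(seq_len(P$n), function(i) {
        lo <- max(0L, P$copies[i] - epsilon)
        hi <- min(P$copies[i] + epsilon,
                  nchar(Q) %/% nchar(P$units[i]) + 2L)
        if (hi < lo) hi <- lo
        lo:hi
    })
    grid_size <- prod(lengths(ranges))
    if (grid_size > 2e5) stop("oracle guard: copy-number grid too large (",
                              grid_size, " combinations)")
    grid <- expand.grid(ranges, KEEP.OUT.ATTRS = FALSE)
    best <- Inf
    for (r in seq_len(nrow(grid))) {
        m <- as.integer(grid[r, ])
        ren <- render_locus(P, copies = m)
        d <- as.integer(utils::adist(Q, ren))
        if (d < best) best <- d
        if (best == 0L) break
    }
    as.integer(best)
}
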