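# Greedy bidirectional seed extension. Starting from an exact seed inside a
# tandem run, the 3' end repeatedly applies the cheapest of three fitting
# alignments -- one more unit copy, spacer plus next unit, or the right
# flank -- and the 5' end does the mirror image, until both flanks are
# anchored or the edit-distance budget delta is exhausted. Ties are broken
# by read progress (see .pick_candidate), then by the candidate order
# copy > spacer+unit > flank, deterministically.

.substr_mismatches <- function(a, b) {
    # positional mismatch count of two equal-length strings
    if (!nzchar(a)) return(0L)
    sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Initialize an extension state from a seed, completing truncated copies
#'
#' A seed whose k-mer starts or ends mid-copy is first completed by gap-free
#' extension: the remaining bases of the partial copy are compared position
#' by position against the read, each mismatch adding 1 to the distance, and
#' the completed partial counts as a whole copy. If the read ends before the
#' copy can be completed, the partial is discarded and the cursor reverts to
#' the last whole-copy boundary.
#'
#' @param seed One row of [find_seeds()] output (a list or one-row
#'   data.frame with `unit`, `start`, `end`, `phase`). Coordinates must be
#'   on the oriented read passed as `read`.
#' @param read The oriented read (pattern orientation) as a DNA string.
#' @param pattern The `str_pattern` the seed belongs to.
#' @return An `extension_state` list: unit cursors `i3`/`i5`, per-unit
#'   copies `m`, aligned interval `start`/`end`, cumulative distance `D`,
#'   flank flags and anchors.
#' @export
complete_truncated_unit <- function(seed, read, pattern) {
    unit <- pattern$units[seed$unit]
    len <- nchar(unit)
    k <- seed$end - seed$start + 1L
    phase <- seed$phase
    lead <- (len - phase) %% len          # partial leading copy inside seed
    body <- k - lead
    m_i <- body %/% len                   # whole copies inside the seed
    tp <- body %% len                     # partial trailing copy inside seed
    start <- seed$start
    end <- seed$end
    D <- 0L
    L <- nchar(read)

    if (tp > 0L) {                        # complete trailing partial at 3'
        need <- len - tp
        if (end + need <= L) {
            D <- D + .substr_mismatches(substr(read, end + 1L, end + need),
                                        substr(unit, tp + 1L, len))
            end <- end + need
            m_i <- m_i + 1L
        } else {
            end <- end - tp               # discard partial, revert to boundary
        }
    }
    if (lead > 0L) {                      # complete leading partial at 5'
        need <- phase                     # bases of the copy before the seed
        if (start - need >= 1L) {
            D <- D + .substr_mismatches(substr(read, start - need, start - 1L),
                                        substr(unit, 1L, need))
            start <- start - need
            m_i <- m_i + 1L
        } else {
            start <- start + lead
        }
    }

    m <- integer(pattern$n)
    m[seed$unit] <- m_i
    structure(
        list(pattern_id = seed$pattern %||% NA_integer_,
             unit0 = seed$unit, i3 = seed$unit, i5 = seed$unit,
             m = m, start = as.integer(start), end = as.integer(end),
             D = as.integer(D),
             reached_s_R = FALSE, reached_s_L = FALSE,
             anchor_R = 0L, anchor_L = 0L,
             stopped3 = FALSE, stopped5 = FALSE),
        class = "extension_state"
    )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# candidate choice: minimum fitting distance; ties prefer the candidate
# consuming the most read bases (a corrupt boundary can let a unit copy
# absorb an indel and tie the true spacer/flank step at a fraction of the
# progress -- preferring progress keeps the greedy walk from re-entering
# the run); remaining ties keep the listed order copy > spacer > flank.
.pick_candidate <- function(cands) {
    dists <- vapply(cands, `[[`, numeric(1), "distance")
    progress <- vapply(cands, function(x)
        (x$consumed_read %||% x$consumed), numeric(1))
    names(cands)[order(dists, -progress)[1L]]
}

# Fit a flank whose available read context may be shorter than the flank
# itself. Returns list(distance, consumed_read, anchor) or NULL.
# full flank available: fit the whole flank to a prefix/suffix of the
# context; clipped: the whole remaining context is aligned against a
# prefix (right flank) / suffix (left flank) of the flank, and the anchor
# is the number of flank bases covered.
.fit_flank <- function(flank, context, band, budget, min_anchor, side) {
    avail <- nchar(context)
    if (avail <= 0L) return(NULL)
    fit_fun <- if (side == "R") fit_prefix else fit_suffix
    if (avail >= nchar(flank)) {
        r <- fit_fun(flank, context, band, budget)
        if (is.null(r)) return(NULL)
        list(distance = r$distance, consumed_read = r$consumed,
             anchor = nchar(flank))
    } else {
        r <- fit_fun(context, flank, band, budget)
        if (is.null(r)) return(NULL)
        if (r$consumed < min_anchor) return(NULL)
        list(distance = r$distance, consumed_read = avail, anchor = r$consumed)
    }
}

#' One greedy extension step at the 3' end
#'
#' Evaluates the admissible candidates with the remaining budget
#' `delta - D`: (a) one more copy of the current unit (admissible while
#' `m_i < c_i + epsilon`), (b) the spacer plus the next unit (admissible
#' while not at the last unit; counts one copy of the next unit), and
#' (c) the right flank (admissible at the last unit; clipped to the read end
#' with the distance computed over the overlapping anchor only). The
#' candidate with the minimum fitting distance is applied; ties prefer the
#' candidate consuming the most read bases, then the order (a), (b), (c).
#' When no candidate is admissible within the budget the state is marked
#' stopped.
#'
#' @param state An `extension_state`.
#' @param read Oriented read.
#' @param pattern The `str_pattern`.
#' @param params A [scan_params()].
#' @return The updated `extension_state` (fields `stopped3`/`reached_s_R`
#'   signal termination).
#' @export
extend_3prime_step <- function(state, read, pattern, params) {
    if (state$reached_s_R || state$stopped3) return(state)
    i <- state$i3
    budget <- params$delta - state$D
    if (budget < 0L) { state$stopped3 <- TRUE; return(state) }
    L <- nchar(read)
    cands <- list()

    if (state$m[i] < pattern$copies[i] + params$epsilon) {
        comp <- pattern$units[i]
        win <- substr(read, state$end + 1L,
                      min(L, state$end + nchar(comp) + params$band))
        r <- fit_prefix(comp, win, params$band, budget)
        if (!is.null(r)) cands$copy <- r
    }
    if (i < pattern$n) {
        comp <- paste0(pattern$spacers[i], pattern$units[i + 1L])
        win <- substr(read, state$end + 1L,
                      min(L, state$end + nchar(comp) + params$band))
        r <- fit_prefix(comp, win, params$band, budget)
        if (!is.null(r)) cands$spacer <- r
    }
    if (i == pattern$n) {
        context <- substr(read, state$end + 1L,
                          min(L, state$end + nchar(pattern$right_flank) + params$band))
        r <- .fit_flank(pattern$right_flank, context, params$band, budget,
                        params$min_flank_anchor, side = "R")
        if (!is.null(r)) cands$flank <- r
    }

    if (length(cands) == 0L) { state$stopped3 <- TRUE; return(state) }
    pick <- .pick_candidate(cands)
    ch <- cands[[pick]]
    state$D <- state$D + as.integer(ch$distance)
    if (pick == "copy") {
        state$end <- state$end + ch$consumed
        state$m[i] <- state$m[i] + 1L
    } else if (pick == "spacer") {
        state$end <- state$end + ch$consumed
        state$i3 <- i + 1L
        state$m[i + 1L] <- state$m[i + 1L] + 1L
    } else {
        state$end <- state$end + ch$consumed_read
        state$reached_s_R <- TRUE
        state$anchor_R <- ch$anchor
    }
    state
}

#' One greedy extension step at the 5' end
#'
#' Mirror image of [extend_3prime_step()]: candidates are one more copy of
#' the current unit (fitted against the suffix of the left context), the
#' previous unit plus its spacer, and the left flank.
#'
#' @inheritParams extend_3prime_step
#' @return The updated `extension_state` (fields `stopped5`/`reached_s_L`).
#' @export
extend_5prime_step <- function(state, read, pattern, params) {
    if (state$reached_s_L || state$stopped5) return(state)
    i <- state$i5
    budget <- params$delta - state$D
    if (budget < 0L) { state$stopped5 <- TRUE; return(state) }
    cands <- list()

    if (state$m[i] < pattern$copies[i] + params$epsilon) {
        comp <- pattern$units[i]
        win <- substr(read, max(1L, state$start - nchar(comp) - params$band),
                      state$start - 1L)
        r <- fit_suffix(comp, win, params$band, budget)
        if (!is.null(r)) cands$copy <- r
    }
    if (i > 1L) {
        comp <- paste0(pattern$units[i - 1L], pattern$spacers[i - 1L])
        win <- substr(read, max(1L, state$start - nchar(comp) - params$band),
                      state$start - 1L)
        r <- fit_suffix(comp, win, params$band, budget)
        if (!is.null(r)) cands$spacer <- r
    }
    if (i == 1L) {
        context <- substr(read,
                          max(1L, state$start - nchar(pattern$left_flank) - params$band),
                          state$start - 1L)
        r <- .fit_flank(pattern$left_flank, context, params$band, budget,
                        params$min_flank_anchor, side = "L")
        if (!is.null(r)) cands$flank <- r
    }

    if (length(cands) == 0L) { state$stopped5 <- TRUE; return(state) }
    pick <- .pick_candidate(cands)
    ch <- cands[[pick]]
    state$D <- state$D + as.integer(ch$distance)
    if (pick == "copy") {
        state$start <- state$start - ch$consumed
        state$m[i] <- state$m[i] + 1L
    } else if (pick == "spacer") {
        state$start <- state$start - ch$consumed
        state$i5 <- i - 1L
        state$m[i - 1L] <- state$m[i - 1L] + 1L
    } else {
        state$start <- state$start - ch$consumed_read
        state$reached_s_L <- TRUE
        state$anchor_L <- ch$anchor
    }
    state
}

#' Extend a seed into a full locus call
#'
#' Runs [complete_truncated_unit()], then alternates 3' and 5' steps
#' (starting 3'; a side that has reached its flank is skipped) until both
#' flanks are anchored, either side stops without its flank, or the budget
#' `delta` is exhausted. An accepted call requires both flanks anchored with
#' at least `min_flank_anchor` aligned bases, total distance `<= delta`, and
#' every per-unit copy number within `epsilon` of its reference.
#'
#' @inheritParams complete_truncated_unit
#' @param params A [scan_params()].
#' @return An `str_call` (list with `marker`, `units`, `copies`, `distance`,
#'   `start`, `end`, `anchor_L`, `anchor_R`), or `NULL` when the seed does
#'   not extend to an acceptable occurrence. Coordinates are on the oriented
#'   read given; [scan_read()] maps them back to the forward read.
#' @export
extend_alignment <- function(seed, read, pattern, params = scan_params()) {
    state <- complete_truncated_unit(seed, read, pattern)
    if (state$D > params$delta) return(NULL)
    repeat {
        done3 <- state$reached_s_R || state$stopped3
        done5 <- state$reached_s_L || state$stopped5
        if (done3 && done5) break
        if (!done3) state <- extend_3prime_step(state, read, pattern, params)
        if (!done5) state <- extend_5prime_step(state, read, pattern, params)
    }
    if (!state$reached_s_R || !state$reached_s_L) return(NULL)
    if (state$D > params$delta) return(NULL)
    if (state$anchor_R < params$min_flank_anchor ||
        state$anchor_L < params$min_flank_anchor) return(NULL)
    if (any(abs(state$m - pattern$copies) > params$epsilon)) return(NULL)
    structure(
        list(marker = pattern$marker,
             units = pattern$units,
             copies = state$m,
             distance = state$D,
             start = state$start, end = state$end,
             anchor_L = state$anchor_L, anchor_R = state$anchor_R,
             strand = seed$strand %||% "+",
             read_id = NA_character_),
        class = "str_call"
    )
}

#' Per-unit copy numbers of an accepted call
#'
#' @param call An `str_call` from [extend_alignment()] or [scan_read()].
#' @return A data.frame with columns `unit` and `copies`, in pattern order.
#'   Copy numbers are whole copies only; partial trailing copies are never
#'   counted.
#' @export
count_copies <- function(call) {
    stopifnot(inherits(call, "str_call"))
    data.frame(unit = call$units, copies = call$copies,
               stringsAsFactors = FALSE)
}

#' @export
print.str_call <- function(x, ...) {
    cat("str_call ", x$marker, " [", x$start, "-", x$end, "] strand ",
        x$strand, " copies ", paste(x$copies, collapse = "/"),
        " distance ", x$distance, "\n", sep = "")
    invisible(x)
}
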