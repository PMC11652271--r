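#' Canonicalize a HOR unit under rotation and reversal
#'
#' HOR occurrences that start at a shifted phase, or that were read on the
#' opposite strand, describe the same repeat.  The canonical form of a unit
#' is the lexicographically minimal tuple over all rotations of the unit and
#' all rotations of its reversal, so e.g. 1-2-3-4, 4-1-2-3, 3-4-1-2, 2-3-4-1
#' and 4-3-2-1 all canonicalize identically.
#'
#' @param unit integer (or integer-like character) vector of monomer ids.
#' @return integer vector: the canonical tuple.
#' @examples
#' canonicalizePattern(c(4, 1, 2, 3))  # 1 2 3 4
#' @export
canonicalizePattern <- function(unit) {
    if (!length(unit)) stop("unit must be non-empty")
    unit <- as.integer(unit)
    L <- length(unit)
    if (L == 1L) return(unit)
    rots <- function(x) lapply(seq_len(L) - 1L, function(r)
        if (r == 0L) x else c(x[(r + 1L):L], x[seq_len(r)]))
    cand <- c(rots(unit), rots(rev(unit)))
    m <- do.call(rbind, cand)
    m[do.call(order, as.data.frame(m))[1L], ]
}

.canonKey <- function(unit) paste(canonicalizePattern(unit), collapse = "-")

#' Expand a compressed monomer pattern
#'
#' Expands compressed notation for locally nested HOR subunits, e.g.
#' \code{(1-2)x4-5-6-4-3}, into a flat monomer tuple and reports the total
#' monomer length.  Input may be the string notation or a list mixing plain
#' ids with \code{list(sub = , count = )} compressed symbols.
#'
#' @param compressed character scalar in dash/\code{(..)xN} notation, or a
#'   list of ids and \code{list(sub, count)} elements.
#' @return list with \code{expanded} (integer vector) and
#'   \code{monomerLength}.
#' @examples
#' expandPattern("(1-2)x4-5-6-4-3")$monomerLength       # 12
#' expandPattern("3-5-6-8-1-2-3-4-(3-5-6-7)x2")$monomerLength  # 16
#' @export
expandPattern <- function(compressed) {
    if (is.character(compressed) && length(compressed) == 1L)
        compressed <- .parsePatternNotation(compressed)
    if (!is.list(compressed)) compressed <- as.list(compressed)
    out <- integer(0)
    for (el in compressed) {
        if (is.list(el)) {
            cnt <- as.integer(el$count)
            if (is.na(cnt) || cnt < 1L)
                stop("argument error: compressed count must be >= 1")
            out <- c(out, rep(as.integer(el$sub), cnt))
        } else {
            out <- c(out, as.integer(el))
        }
    }
    list(expanded = out, monomerLength = length(out))
}

# parse "(1-2)x4-5-6-4-3" into a mixed list of ids and list(sub, count)
.parsePatternNotation <- function(x) {
    x <- gsub("\\s", "", x)
    out <- list()
    i <- 1L; n <- nchar(x)
    while (i <= n) {
        ch <- substr(x, i, i)
        if (ch == "-") { i <- i + 1L; next }
        if (ch == "(") {
            close <- i + regexpr(")", substr(x, i, n), fixed = TRUE) - 1L
            if (close < i) stop("parse error: unmatched '(' in ", x)
            sub <- as.integer(strsplit(substr(x, i + 1L, close - 1L),
                                       "-", fixed = TRUE)[[1]])
            if (substr(x, close + 1L, close + 1L) != "x")
                stop("parse error: expected 'x<count>' after ')' in ", x)
            mm <- regexpr("^[0-9]+", substr(x, close + 2L, n))
            cnt <- as.integer(substr(x, close + 2L,
                                     close + 1L + attr(mm, "match.length")))
            out <- c(out, list(list(sub = sub, count = cnt)))
            i <- close + 2L + attr(mm, "match.length")
        } else {
            mm <- regexpr("^[0-9]+", substr(x, i, n))
            if (mm < 0) stop("parse error: unexpected character '", ch, "'")
            out <- c(out, as.integer(substr(x, i,
                                            i + attr(mm, "match.length") - 1L)))
            i <- i + attr(mm, "match.length")
        }
    }
    out
}

#' Find maximal tandem runs in a monomer token sequence
#'
#' Reports every maximal run in which a unit of length \code{u} in
#' \code{[1, maxUnit]} repeats at least twice consecutively.  A run at
#' period \code{u} is maximal when it can be extended in neither direction;
#' partial trailing repeats do not extend the count.  \code{"unknown"}
#' tokens never match anything (including other unknowns) and therefore
#' terminate runs.
#'
#' @param tokens character vector of monomer tokens (or a
#'   \code{\linkS4class{MonomerSequence}}).
#' @param maxUnit largest unit length considered (default 40, covering the
#'   largest human HOR units).
#' @return data.frame with columns \code{start} (1-based token index),
#'   \code{unitLength}, \code{count} and \code{unit} (dash-separated).
#' @examples
#' findTandemRuns(c("1", "2", "1", "2", "1", "2"))
#' @export
findTandemRuns <- function(tokens, maxUnit = 40L) {
    if (is(tokens, "MonomerSequence")) tokens <- tokens(tokens)
    tokens <- as.character(tokens)
    if (maxUnit < 1L) stop("maxUnit must be >= 1")
    keys <- tokens
    keys[keys == "unknown"] <- NA_character_
    res <- lapply(seq_len(min(maxUnit, max(0L, length(tokens) %/% 2L))),
                  function(u) .runsAtPeriod(keys, u))
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(start = integer(0), unitLength = integer(0),
                          count = integer(0), unit = character(0))
    rownames(out) <- NULL
    out[order(out$start, out$unitLength), , drop = FALSE]
}

# maximal runs at one period: maximal TRUE segments of the lag-u equality
.runsAtPeriod <- function(keys, u) {
    n <- length(keys)
    if (n < 2L * u) return(NULL)
    eq <- keys[seq_len(n - u)] == keys[seq_len(n - u) + u]
    eq[is.na(eq)] <- FALSE
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= u
    if (!any(keep)) return(NULL)
    st <- starts[keep]
    cnt <- r$lengths[keep] %/% u + 1L
    data.frame(start = st, unitLength = u, count = cnt,
               unit = vapply(st, function(s)
                   paste(keys[s:(s + u - 1L)], collapse = "-"), ""),
               stringsAsFactors = FALSE)
}

#' Hierarchical tandem repeat mining of a monomer sequence
#'
#' Recursively detects and compresses local tandem repeats in a monomer
#' token sequence to reveal (possibly nested) HOR structure.  The shortest
#' repeating unit is compressed first; compressed runs become single symbols
#' and the reduced sequence is re-mined until no run remains.  Two symbols
#' match during run detection when they compress the same subpattern,
#' regardless of their repeat counts, so units carrying different levels of
#' local expansion (e.g. 10-mor vs 12-mor variants of one HOR) are annotated
#' as occurrences of the same pattern with different expanded monomer
#' lengths.  Patterns are grouped under shift/reverse canonicalization
#' (\code{\link{canonicalizePattern}}).
#'
#' @param tokens character vector of monomer tokens, or a
#'   \code{\linkS4class{MonomerSequence}}.
#' @param maxUnit largest unit length mined (default 40).
#' @param source source id recorded in the annotation (taken from a
#'   \code{MonomerSequence} input when available).
#' @return a \code{\linkS4class{HORAnnotation}}: \code{horPatterns()} holds
#'   every mined pattern (all nesting levels) with its total repeat count;
#'   \code{horUnits()} holds the non-overlapping top-level unit occurrences
#'   in token coordinates with their expanded monomer lengths.
#' @examples
#' ann <- htrmMine(rep(c("1", "1", "2", "3", "4", "5"), 10))
#' horPatterns(ann)
#' @export
htrmMine <- function(tokens, maxUnit = 40L, source = "seq") {
    if (is(tokens, "MonomerSequence")) {
        source <- tokens@source
        tokens <- tokens(tokens)
    }
    tokens <- as.character(tokens)
    if (!length(tokens)) stop("tokens must be non-empty")
    elems <- lapply(seq_along(tokens), function(i) {
        if (tokens[i] == "unknown")
            list(type = "u", key = NA_character_, span = c(i, i),
                 base = integer(0), expLen = 0L, children = NULL,
                 eventId = NA_integer_)
        else
            list(type = "m", key = tokens[i], span = c(i, i),
                 base = as.integer(tokens[i]), expLen = 1L, children = NULL,
                 eventId = NA_integer_)
    })
    events <- list()       # per compression event: key, occ rows, swallowed
    swallowed <- integer(0)
    nextId <- 1L
    repeat {
        keys <- vapply(elems, `[[`, "", "key")
        found <- NULL
        for (u in seq_len(min(maxUnit, length(elems) %/% 2L))) {
            runs <- .runsAtPeriod(keys, u)
            if (!is.null(runs)) { found <- runs; break }
        }
        if (is.null(found)) break
        # among overlapping candidates prefer maximal token coverage, then
        # leftmost start
        found$cover <- found$count * found$unitLength
        found <- found[order(-found$cover, found$start), , drop = FALSE]
        chosen <- logical(0); sel <- list(); occupied <- integer(0)
        for (i in seq_len(nrow(found))) {
            u <- found$unitLength[i]
            span <- found$start[i]:(found$start[i] + found$count[i] * u - 1L)
            if (!any(span %in% occupied)) {
                sel[[length(sel) + 1L]] <- found[i, ]
                occupied <- c(occupied, span)
            }
        }
        sel <- do.call(rbind, sel)
        sel <- sel[order(sel$start), , drop = FALSE]
        # compress selected runs right-to-left so element indices stay valid
        for (i in rev(seq_len(nrow(sel)))) {
            st <- sel$start[i]; u <- sel$unitLength[i]; cnt <- sel$count[i]
            members <- elems[st:(st + cnt * u - 1L)]
            unitElems <- members[seq_len(u)]
            unitFlat <- unlist(lapply(unitElems, `[[`, "base"))
            key <- .canonKey(unitFlat)
            nestedSubs <- vapply(
                unitElems[vapply(unitElems, `[[`, "", "type") == "s"],
                function(e) paste(e$base, collapse = "-"), "")
            occ <- do.call(rbind, lapply(seq_len(cnt), function(r) {
                re <- members[((r - 1L) * u + 1L):(r * u)]
                data.frame(start = re[[1L]]$span[1L],
                           end = re[[u]]$span[2L],
                           expandedLength = sum(vapply(re, `[[`, 0L,
                                                       "expLen")))
            }))
            occ$canonical <- key
            # inner symbols are swallowed by this event
            swallowed <- c(swallowed, stats::na.omit(
                vapply(members, `[[`, NA_integer_, "eventId")))
            events[[nextId]] <- list(id = nextId, key = key,
                unit = unitFlat, L = length(unitFlat),
                nested = paste(unique(nestedSubs), collapse = ","),
                occ = occ)
            # the symbol's match key is structural (member keys, counts
            # ignored), so differently nested blocks of the same flat
            # pattern never fuse into a spurious outer run
            newElem <- list(type = "s",
                key = paste0("(", paste(vapply(unitElems, `[[`, "",
                                               "key"), collapse = ","),
                             ")"),
                span = c(members[[1L]]$span[1L],
                         members[[cnt * u]]$span[2L]),
                base = unitFlat,
                expLen = sum(vapply(members, `[[`, 0L, "expLen")),
                children = members, eventId = nextId)
            elems <- c(elems[seq_len(st - 1L)], list(newElem),
                       if (st + cnt * u <= length(elems))
                           elems[(st + cnt * u):length(elems)])
            nextId <- nextId + 1L
        }
    }
    .htrmCollect(events, swallowed, elems, source)
}

.htrmCollect <- function(events, swallowed, elems, source) {
    if (!length(events)) {
        return(new("HORAnnotation",
            patterns = data.frame(canonical = character(0), L = integer(0),
                                  nested = character(0), count = integer(0),
                                  stringsAsFactors = FALSE),
            units = data.frame(source = character(0), start = integer(0),
                               end = integer(0), canonical = character(0),
                               expandedLength = integer(0),
                               stringsAsFactors = FALSE)))
    }
    allocc <- do.call(rbind, lapply(events, function(e)
        cbind(e$occ, L = e$L, nested = e$nested)))
    pat <- do.call(rbind, lapply(split(allocc, allocc$canonical), function(d)
        data.frame(canonical = d$canonical[1L], L = d$L[1L],
                   nested = paste(setdiff(unique(unlist(
                       strsplit(d$nested, ",", fixed = TRUE))), ""),
                       collapse = ","),
                   count = nrow(d), stringsAsFactors = FALSE)))
    rownames(pat) <- NULL
    topIds <- setdiff(vapply(events, `[[`, 0L, "id"), swallowed)
    units <- do.call(rbind, lapply(events[topIds], `[[`, "occ"))
    units <- data.frame(source = source, start = units$start,
                        end = units$end, canonical = units$canonical,
                        expandedLength = units$expandedLength,
                        stringsAsFactors = FALSE)
    units <- units[order(units$start), , drop = FALSE]
    rownames(units) <- NULL
    new("HORAnnotation", patterns = pat, units = units)
}

#' Token coverage of a HOR annotation
#'
#' Fraction of tokens inside an annotated top-level HOR unit, labeled
#' unknown, or left unassigned; the three fractions sum to 1.
#'
#' @param annotation a \code{\linkS4class{HORAnnotation}}.
#' @param tokens the token vector (or \code{MonomerSequence}) that was
#'   mined.
#' @return named numeric vector \code{c(inUnit, unknown, unassigned)}.
#' @export
tokenCoverage <- function(annotation, tokens) {
    if (is(tokens, "MonomerSequence")) tokens <- tokens(tokens)
    n <- length(tokens)
    u <- horUnits(annotation)
    covered <- rep(FALSE, n)
    for (i in seq_len(nrow(u))) covered[u$start[i]:u$end[i]] <- TRUE
    unk <- tokens == "unknown" & !covered
    c(inUnit = sum(covered) / n, unknown = sum(unk) / n,
      unassigned = sum(!covered & !unk) / n)
}

#' Name HOR patterns by repeat rank and unit length
#'
#' Patterns are sorted by total repeat count (descending) and named
#' \code{"R<rank>L<length>"} within one sample or \code{"M<rank>L<length>"}
#' after cross-sample aggregation.  Ties are broken by smaller unit length,
#' then by canonical tuple order.  A chromosome prefix (e.g. \code{"5_"})
#' can be applied for reporting.
#'
#' @param patterns data.frame with at least \code{canonical}, \code{L} and
#'   \code{count} columns (e.g. \code{horPatterns()} of a mining result).
#' @param scope \code{"per_sample"} (R names) or \code{"aggregated"}
#'   (M names).
#' @param chromPrefix optional chromosome label prepended as
#'   \code{"<prefix>_"}.
#' @return the input data.frame with \code{rank} and \code{name} columns,
#'   sorted by rank.
#' @examples
#' p <- data.frame(canonical = c("1-2-3-4-5", "1"), L = c(5L, 1L),
#'                 count = c(20L, 4L))
#' nameHors(p)$name  # "R1L5" "R2L1"
#' @export
nameHors <- function(patterns, scope = c("per_sample", "aggregated"),
                     chromPrefix = NULL) {
    scope <- match.arg(scope)
    prefix <- if (scope == "per_sample") "R" else "M"
    ord <- order(-patterns$count, patterns$L, patterns$canonical)
    patterns <- patterns[ord, , drop = FALSE]
    patterns$rank <- seq_len(nrow(patterns))
    patterns$name <- paste0(prefix, patterns$rank, "L", patterns$L)
    if (!is.null(chromPrefix))
        patterns$name <- paste0(chromPrefix, "_", patterns$name)
    rownames(patterns) <- NULL
    patterns
}
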