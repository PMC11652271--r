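#' Scan an assembly for alpha-satellite template hits
#'
#' Internal seed-and-extend scanner: exact seed k-mers sampled along the
#' template (and its reverse complement) are matched against each
#' chromosome; every candidate window is then scored by edit-distance
#' identity against the template and kept when it reaches
#' \code{identityFloor}.  The floor default (0.70) admits divergent
#' monomers, which share 50--90\% identity, while rejecting random
#' sequence.  Externally produced hit tables can be supplied instead via
#' \code{\link{readHitTable}}.
#'
#' @param assembly \code{DNAStringSet} of chromosomes.
#' @param template the ~171-bp alpha-satellite template.
#' @param identityFloor minimum identity for a reported hit (default 0.7).
#' @param seedLength exact seed length (default 12).
#' @param seedStep spacing of seeds along the template (default 10).
#' @return \code{GRanges} of hits in assembly coordinates, with strand and
#'   an \code{identity} metadata column, sorted; empty for an empty
#'   assembly.
#' @export
scanTemplateHits <- function(assembly, template, identityFloor = 0.7,
                             seedLength = 12L, seedStep = 10L) {
    if (!is(assembly, "DNAStringSet"))
        assembly <- Biostrings::DNAStringSet(assembly)
    if (is.null(names(assembly)))
        names(assembly) <- paste0("chr", seq_along(assembly))
    tpl <- as.character(template)
    L <- nchar(tpl)
    bound <- as.integer(ceiling((1 - identityFloor) * L)) + 2L
    out <- list()
    for (strand in c("+", "-")) {
        t <- if (strand == "+") tpl else revComp(tpl)
        offs <- seq(1L, L - seedLength + 1L, by = seedStep)
        seeds <- Biostrings::DNAStringSet(substring(t, offs,
                                                    offs + seedLength - 1L))
        pd <- Biostrings::PDict(seeds)
        for (ch in names(assembly)) {
            subject <- assembly[[ch]]
            mm <- Biostrings::matchPDict(pd, subject)
            cand <- unlist(lapply(seq_along(mm), function(i)
                BiocGenerics::start(mm[[i]]) - (offs[i] - 1L)))
            cand <- sort(unique(pmax(1L, cand)))
            cand <- cand[cand + L - 1L <= length(subject)]
            if (!length(cand)) next
            win <- as.character(Biostrings::extractAt(subject,
                IRanges::IRanges(cand, width = L)))
            d <- cpp_edit_distance(win, t, bound)
            idv <- 1 - d / L
            keep <- idv >= identityFloor
            if (!any(keep)) next
            out[[length(out) + 1L]] <- GenomicRanges::GRanges(ch,
                IRanges::IRanges(cand[keep], width = L), strand = strand,
                identity = idv[keep])
        }
    }
    if (!length(out))
        return(GenomicRanges::GRanges(identity = numeric(0)))
    GenomicRanges::sort(do.call(c, out), ignore.strand = TRUE)
}

#' Read an externally produced template-hit table
#'
#' Generic tab format adapter: a TSV with columns \code{chrom},
#' \code{start}, \code{end} (1-based closed), \code{strand} and optionally
#' \code{identity}.
#'
#' @param path path to the TSV.
#' @return \code{GRanges} of hits.
#' @export
readHitTable <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
        strand = d$strand,
        identity = if ("identity" %in% names(d)) d$identity else
            rep(NA_real_, nrow(d)))
}

#' Merge template hits into satellite regions
#'
#' Hits mapped less than \code{maxGap} (default 5 kb) from each other are
#' merged into one region; merged regions with total length below
#' \code{minRegion} (default 10 kb) are discarded.  The 10-kb floor is
#' applied per merged region.  Each region's strand is the length-weighted
#' majority strand of its hits (ties resolve to \code{"+"}); merging is
#' idempotent.
#'
#' @param hits \code{GRanges} from \code{\link{scanTemplateHits}}.
#' @param maxGap merge hits whose gap is strictly less than this (bp).
#' @param minRegion discard merged regions shorter than this (bp).
#' @return \code{GRanges} of satellite regions.
#' @export
mergeHits <- function(hits, maxGap = 5000L, minRegion = 10000L) {
    if (!length(hits)) return(hits[, NULL])
    merged <- GenomicRanges::reduce(hits, min.gapwidth = maxGap,
                                    ignore.strand = TRUE)
    ov <- GenomicRanges::findOverlaps(merged, hits, ignore.strand = TRUE)
    str <- vapply(seq_along(merged), function(i) {
        h <- hits[S4Vectors::subjectHits(ov)[
            S4Vectors::queryHits(ov) == i]]
        w <- tapply(GenomicRanges::width(h),
                    as.character(GenomicRanges::strand(h)), sum)
        plus <- if ("+" %in% names(w)) w[["+"]] else 0
        minus <- if ("-" %in% names(w)) w[["-"]] else 0
        if (minus > plus) "-" else "+"
    }, "")
    GenomicRanges::strand(merged) <- str
    merged[GenomicRanges::width(merged) >= minRegion]
}

#' Build the satellite array of one chromosome
#'
#' Concatenates the chromosome's satellite regions in coordinate order into
#' one array, reverse-complementing minus-strand regions so the array is
#' uniformly plus-oriented, and records the junction offsets and the
#' back-mapping to assembly coordinates.
#'
#' @param assembly \code{DNAStringSet} of chromosomes.
#' @param regions \code{GRanges} of merged satellite regions (see
#'   \code{\link{mergeHits}}).
#' @param chrom chromosome to build (default: the single chromosome present
#'   in \code{regions}).
#' @return a \code{\linkS4class{SatelliteArray}}.
#' @export
buildSatelliteArray <- function(assembly, regions, chrom = NULL) {
    if (is.null(chrom)) {
        chrom <- unique(as.character(GenomicRanges::seqnames(regions)))
        if (length(chrom) != 1L)
            stop("regions span several chromosomes; supply 'chrom'")
    }
    gr <- regions[as.character(GenomicRanges::seqnames(regions)) == chrom]
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    if (!length(gr)) stop("no regions on ", chrom)
    if (!chrom %in% names(assembly)) stop(chrom, " not in assembly")
    clen <- length(assembly[[chrom]])
    if (any(GenomicRanges::end(gr) > clen) ||
        any(GenomicRanges::start(gr) < 1L))
        stop("consistency error: region exceeds chromosome bounds")
    pieces <- vapply(seq_along(gr), function(i) {
        s <- Biostrings::subseq(assembly[[chrom]],
                                GenomicRanges::start(gr)[i],
                                GenomicRanges::end(gr)[i])
        if (as.character(GenomicRanges::strand(gr))[i] == "-")
            s <- Biostrings::reverseComplement(s)
        as.character(s)
    }, "")
    w <- GenomicRanges::width(gr)
    new("SatelliteArray", chrom = chrom,
        sequence = Biostrings::DNAString(paste(pieces, collapse = "")),
        regions = gr,
        junctions = if (length(gr) > 1L) cumsum(w)[-length(w)] else
            integer(0))
}

#' Map between array and assembly coordinates
#'
#' \code{arrayToAssembly} maps 1-based offsets in the concatenated array
#' back to assembly coordinates (accounting for reverse-complemented
#' regions); \code{assemblyToArray} is its inverse for positions inside a
#' region.
#'
#' @param x a \code{\linkS4class{SatelliteArray}}.
#' @param pos integer vector of positions (array offsets, or assembly
#'   positions).
#' @return \code{arrayToAssembly}: data.frame with \code{chrom},
#'   \code{pos}, \code{strand}; \code{assemblyToArray}: integer array
#'   offsets (\code{NA} outside all regions).
#' @export
arrayToAssembly <- function(x, pos) {
    w <- GenomicRanges::width(x@regions)
    cum <- c(0L, cumsum(w))
    if (any(pos < 1L | pos > sum(w))) stop("position outside array")
    reg <- findInterval(pos - 1L, cum, rightmost.closed = FALSE)
    off <- pos - cum[reg]
    st <- GenomicRanges::start(x@regions)[reg]
    en <- GenomicRanges::end(x@regions)[reg]
    strand <- as.character(GenomicRanges::strand(x@regions))[reg]
    data.frame(chrom = x@chrom,
               pos = as.integer(ifelse(strand == "-", en - off + 1L,
                                       st + off - 1L)),
               strand = strand, stringsAsFactors = FALSE)
}

#' @rdname arrayToAssembly
#' @export
assemblyToArray <- function(x, pos) {
    w <- GenomicRanges::width(x@regions)
    cum <- c(0L, cumsum(w))
    st <- GenomicRanges::start(x@regions)
    en <- GenomicRanges::end(x@regions)
    strand <- as.character(GenomicRanges::strand(x@regions))
    out <- rep(NA_integer_, length(pos))
    for (i in seq_along(pos)) {
        reg <- which(pos[i] >= st & pos[i] <= en)
        if (length(reg) == 1L) {
            off <- if (strand[reg] == "-") en[reg] - pos[i] + 1L
                   else pos[i] - st[reg] + 1L
            out[i] <- as.integer(cum[reg] + off)
        }
    }
    out
}
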