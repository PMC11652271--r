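#' Accessors for SatelliteArray
#'
#' @param x a \code{\linkS4class{SatelliteArray}}.
#' @return \code{arrayChrom} the chromosome name; \code{arraySeq} the
#'   concatenated \code{DNAString}; \code{arrayRegions} the source regions as
#'   a \code{GRanges}; \code{junctions} integer junction offsets in array
#'   coordinates; \code{length} the array length in bases.
#' @name SatelliteArray-accessors
#' @aliases arrayChrom arraySeq arrayRegions junctions
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1, 100), width = c(20, 30)))
#' asm <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 50),
#'     collapse = "")))
#' arr <- buildSatelliteArray(asm, gr, chrom = "chr1")
#' arrayChrom(arr); junctions(arr); length(arr)
NULL

#' @rdname SatelliteArray-accessors
#' @export
setMethod("arrayChrom", "SatelliteArray", function(x) x@chrom)

#' @rdname SatelliteArray-accessors
#' @export
setMethod("arraySeq", "SatelliteArray", function(x) x@sequence)

#' @rdname SatelliteArray-accessors
#' @export
setMethod("arrayRegions", "SatelliteArray", function(x) x@regions)

#' @rdname SatelliteArray-accessors
#' @export
setMethod("junctions", "SatelliteArray", function(x) x@junctions)

#' @rdname SatelliteArray-accessors
#' @export
setMethod("length", "SatelliteArray", function(x) length(x@sequence))

setMethod("show", "SatelliteArray", function(object) {
    cat("SatelliteArray on", object@chrom, "|",
        length(object@sequence), "bp in", length(object@regions),
        "region(s),", length(object@junctions), "junction(s)\n")
})

#' Accessors for MonomerSequence
#'
#' @param x a \code{\linkS4class{MonomerSequence}}.
#' @return \code{tokens} the character vector of monomer ids (with
#'   \code{"unknown"}); \code{identities} per-block best identities;
#'   \code{blockRanges} the block intervals as an \code{IRanges};
#'   \code{length} the token count.
#' @name MonomerSequence-accessors
#' @aliases tokens identities blockRanges
NULL

#' @rdname MonomerSequence-accessors
#' @export
setMethod("tokens", "MonomerSequence", function(x) x@tokens)

#' @rdname MonomerSequence-accessors
#' @export
setMethod("identities", "MonomerSequence", function(x) x@identities)

#' @rdname MonomerSequence-accessors
#' @export
setMethod("blockRanges", "MonomerSequence", function(x) x@ranges)

#' @rdname MonomerSequence-accessors
#' @export
setMethod("length", "MonomerSequence", function(x) length(x@tokens))

setMethod("show", "MonomerSequence", function(object) {
    n <- length(object@tokens)
    unk <- sum(object@tokens == "unknown")
    cat("MonomerSequence from", object@source, "|", n, "tokens (",
        length(unique(object@tokens[object@tokens != "unknown"])),
        "distinct monomers,", unk, "unknown )\n")
    if (n) cat(" head:", paste(head(object@tokens, 12L), collapse = "-"),
               if (n > 12L) "..." else "", "\n")
})

#' Accessors for HORAnnotation
#'
#' @param x a \code{\linkS4class{HORAnnotation}}.
#' @return \code{horPatterns} the pattern table (one row per canonical HOR);
#'   \code{horUnits} the per-unit occurrence table.
#' @name HORAnnotation-accessors
#' @aliases horPatterns horUnits
NULL

#' @rdname HORAnnotation-accessors
#' @export
setMethod("horPatterns", "HORAnnotation", function(x) x@patterns)

#' @rdname HORAnnotation-accessors
#' @export
setMethod("horUnits", "HORAnnotation", function(x) x@units)

setMethod("show", "HORAnnotation", function(object) {
    cat("HORAnnotation |", nrow(object@patterns), "pattern(s),",
        nrow(object@units), "annotated unit(s)\n")
    if (nrow(object@patterns)) {
        p <- object@patterns[order(-object@patterns$count), , drop = FALSE]
        print(head(p, 5L), row.names = FALSE)
        if (nrow(p) > 5L) cat(" ...\n")
    }
})

setMethod("show", "KmerClassifier", function(object) {
    cat("KmerClassifier stage:", object@stage, "|", object@nComp,
        "components (", sprintf("%.1f%%", 100 * object@varExplained),
        "variance ) |", length(object@labels), "classes\n")
})
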