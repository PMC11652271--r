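#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges IRanges
NULL

#' SatelliteArray: concatenated alpha-satellite regions of one chromosome
#'
#' Holds the concatenated plus-oriented sequence of all alpha-satellite
#' regions of one chromosome, the assembly coordinates of those regions, and
#' the junction ("break") offsets where discontiguous regions were joined.
#' Minus-strand regions are reverse-complemented into the array so that the
#' concatenated sequence is uniformly plus-oriented; the original orientation
#' is kept in \code{regions()} strand for back-mapping.
#'
#' @slot chrom chromosome name.
#' @slot sequence concatenated array sequence (\code{DNAString}).
#' @slot regions \code{GRanges} of the source regions in assembly
#'   coordinates, sorted and non-overlapping.
#' @slot junctions integer offsets in array coordinates (1-based position of
#'   the last base before each junction); one fewer than the region count.
#'
#' @seealso \code{\link{buildSatelliteArray}}, \code{\link{arrayToAssembly}}
#' @export
setClass("SatelliteArray",
    representation(chrom = "character", sequence = "DNAString",
                   regions = "GRanges", junctions = "integer"))

setValidity("SatelliteArray", function(object) {
    msg <- NULL
    w <- GenomicRanges::width(object@regions)
    if (length(object@chrom) != 1L)
        msg <- c(msg, "'chrom' must be a single string")
    if (sum(w) != length(object@sequence))
        msg <- c(msg, "sum of region widths must equal sequence length")
    if (length(object@regions) > 1L) {
        st <- GenomicRanges::start(object@regions)
        en <- GenomicRanges::end(object@regions)
        if (is.unsorted(st, strictly = TRUE) ||
            any(st[-1L] <= en[-length(en)]))
            msg <- c(msg, "regions must be sorted and non-overlapping")
    }
    if (length(object@junctions) != max(0L, length(object@regions) - 1L))
        msg <- c(msg, "junction count must be region count - 1")
    if (length(object@junctions) &&
        !identical(object@junctions, cumsum(w)[-length(w)]))
        msg <- c(msg, "junctions must be cumulative region widths")
    if (is.null(msg)) TRUE else msg
})

#' MonomerSequence: monomer tokens decoded from a block decomposition
#'
#' Ordered monomer identifiers (as character tokens, \code{"unknown"} for
#' blocks below the identity cutoff) together with the block intervals they
#' were decoded from and the per-block best identity.
#'
#' @slot source identifier of the read or array the blocks tile.
#' @slot ranges \code{IRanges} of block intervals on the source (1-based).
#' @slot tokens character vector of monomer ids or \code{"unknown"}.
#' @slot identities numeric best identity per block, in [0, 1].
#'
#' @seealso \code{\link{labelMonomers}}, \code{\link{htrmMine}}
#' @export
setClass("MonomerSequence",
    representation(source = "character", ranges = "IRanges",
                   tokens = "character", identities = "numeric"))

setValidity("MonomerSequence", function(object) {
    msg <- NULL
    n <- length(object@tokens)
    if (length(object@ranges) != n)
        msg <- c(msg, "token count must equal block count")
    if (length(object@identities) != n)
        msg <- c(msg, "one identity per token required")
    if (n && (min(object@identities) < 0 || max(object@identities) > 1))
        msg <- c(msg, "identities must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' HORAnnotation: mined HOR patterns and their located occurrences
#'
#' @slot patterns data.frame with one row per canonical HOR pattern:
#'   \code{canonical} (dash-separated monomer ids), \code{L} (unit monomer
#'   length counting each nested subunit once), \code{nested} (compressed
#'   notation or \code{""}), \code{count} (number of annotated units) and,
#'   after \code{\link{nameHors}}, \code{name}.
#' @slot units data.frame with one row per annotated HOR unit:
#'   \code{source}, \code{start}, \code{end} (token coordinates, 1-based
#'   closed), \code{canonical} and \code{expandedLength} (monomer count after
#'   expanding nested subunits).
#'
#' @seealso \code{\link{htrmMine}}, \code{\link{nameHors}}
#' @export
setClass("HORAnnotation",
    representation(patterns = "data.frame", units = "data.frame"))

setValidity("HORAnnotation", function(object) {
    msg <- NULL
    need <- c("canonical", "L", "nested", "count")
    if (!all(need %in% names(object@patterns)))
        msg <- c(msg, paste("patterns must have columns:",
                            paste(need, collapse = ", ")))
    needu <- c("source", "start", "end", "canonical", "expandedLength")
    if (!all(needu %in% names(object@units)))
        msg <- c(msg, paste("units must have columns:",
                            paste(needu, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' KmerClassifier: one stage of the two-step alpha-satellite read classifier
#'
#' A PCA projection retaining the smallest number of components whose
#' explained variance exceeds the configured threshold, followed by a
#' maximum-margin (SVM) decision rule on the projected 512-dimensional
#' canonical 5-mer frequencies.
#'
#' @slot stage \code{"alpha_vs_non"} or \code{"chromosome"}.
#' @slot labels class labels the decision rule can emit.
#' @slot center per-feature centering vector of the PCA.
#' @slot rotation loading matrix (512 x nComp).
#' @slot nComp number of retained components.
#' @slot varExplained cumulative variance explained by the retained
#'   components (> the training threshold, default 0.95).
#' @slot model fitted decision rule (an \code{e1071::svm} object).
#'
#' @seealso \code{\link{trainTwoStage}}, \code{\link{classifyReads}}
#' @export
setClass("KmerClassifier",
    representation(stage = "character", labels = "character",
                   center = "numeric", rotation = "matrix",
                   nComp = "integer", varExplained = "numeric",
                   model = "ANY"))

setValidity("KmerClassifier", function(object) {
    msg <- NULL
    if (!object@stage %in% c("alpha_vs_non", "chromosome"))
        msg <- c(msg, "stage must be 'alpha_vs_non' or 'chromosome'")
    if (!length(object@labels))
        msg <- c(msg, "labels must be non-empty")
    if (is.null(msg)) TRUE else msg
})
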