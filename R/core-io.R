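#' Read sequences from FASTA or FASTQ
#'
#' Reads a FASTA or FASTQ file (dialect auto-detected from the first record
#' marker) into a \code{DNAStringSet}.  Lowercase bases are normalized to
#' uppercase; any character outside \code{A,C,G,T,N} (e.g., IUPAC ambiguity
#' codes) is mapped to \code{N} and the total replacement count is reported
#' with a message.  FASTQ qualities are attached as an integer-score list in
#' \code{mcols(x)$quality}.
#'
#' @param path path to an (uncompressed or gzipped) FASTA/FASTQ file.
#' @return a \code{DNAStringSet}, in file order, with \code{names} from the
#'   record headers; for FASTQ input, \code{mcols()$quality} holds a
#'   \code{PhredQuality} per read.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    con <- gzfile(path, "r")
    first <- ""
    repeat {
        ln <- readLines(con, n = 1L)
        if (!length(ln)) break
        if (nzchar(trimws(ln))) { first <- trimws(ln); break }
    }
    close(con)
    fastq <- startsWith(first, "@")
    if (!fastq && !startsWith(first, ">"))
        stop("parse error at line 1: not FASTA ('>') or FASTQ ('@'): ",
             substr(first, 1, 30))
    if (fastq) {
        raw <- Biostrings::readDNAStringSet(path, format = "fastq",
                                            with.qualities = TRUE)
        qual <- S4Vectors::mcols(raw)$qualities
    } else {
        raw <- Biostrings::readBStringSet(path, format = "fasta")
        qual <- NULL
    }
    if (any(Biostrings::width(raw) == 0L))
        stop("parse error: record without sequence: ",
             names(raw)[which(Biostrings::width(raw) == 0L)[1L]])
    chr <- toupper(as.character(raw))
    nbad <- sum(nchar(gsub("[ACGTN]", "", chr)))
    if (nbad > 0) {
        chr <- gsub("[^ACGTN]", "N", chr)
        message("readFasta: mapped ", nbad, " non-ACGTN base(s) to N")
    }
    out <- Biostrings::DNAStringSet(chr)
    names(out) <- names(raw)
    if (!is.null(qual))
        S4Vectors::mcols(out)$quality <- Biostrings::PhredQuality(qual)
    out
}

#' Write sequences to FASTA
#'
#' @param x a \code{DNAStringSet} (or named character vector).
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeFasta <- function(x, path) {
    if (is.character(x)) x <- Biostrings::DNAStringSet(x)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

.checkAlphabet <- function(x) {
    bad <- grepl("[^ACGTN]", x)
    if (any(bad))
        stop("alphabet error: sequence contains characters outside ACGTN")
    invisible(TRUE)
}

#' Reverse complement
#'
#' Strict \code{A,C,G,T,N} reverse complement (\code{N} maps to \code{N});
#' an involution that preserves length.
#'
#' @param x character vector, \code{DNAString} or \code{DNAStringSet}.
#' @return same type as the input.
#' @examples
#' revComp("AAAC")  # "GTTT"
#' @export
revComp <- function(x) {
    if (is(x, "DNAString") || is(x, "DNAStringSet")) {
        .checkAlphabet(as.character(x))
        return(Biostrings::reverseComplement(x))
    }
    .checkAlphabet(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Levenshtein edit distance
#'
#' Unit-cost edit distance (substitution, insertion, deletion all cost 1),
#' vectorized with recycling over the longer argument.  Characters are
#' compared literally, so \code{N} mismatches every other base (and matches
#' \code{N}).
#'
#' @param a,b character vectors (or XStringSet objects) of non-empty
#'   sequences.
#' @param cutoff optional non-negative integer; when the true distance
#'   exceeds it, \code{cutoff + 1} is returned instead (early abandon).
#'   Default \code{-1} disables the bound.
#' @return integer vector of distances.
#' @examples
#' editDistance("AAAA", "AAAT")  # 1
#' @export
editDistance <- function(a, b, cutoff = -1L) {
    a <- as.character(a); b <- as.character(b)
    if (!length(a) || !length(b) || any(!nchar(a)) || any(!nchar(b)))
        stop("argument error: sequences must be non-empty")
    cpp_edit_distance(a, b, as.integer(cutoff))
}

#' Pairwise edit-distance matrix
#'
#' @param x,y character vectors or XStringSet objects; with \code{y} missing
#'   the symmetric self-distance matrix of \code{x} is returned.
#' @param cutoff as in \code{\link{editDistance}}.
#' @return integer matrix of distances.
#' @export
editDistanceMatrix <- function(x, y, cutoff = -1L) {
    x <- as.character(x)
    if (missing(y)) return(cpp_self_edit_distance(x, as.integer(cutoff)))
    cpp_edit_distance_matrix(x, as.character(y), as.integer(cutoff))
}

#' Sequence identity between a block and a monomer template
#'
#' Identity is \code{1 - ed(a, b) / max(nchar(a), nchar(b))}: the edit
#' distance normalized by the longer sequence, subtracted from one so that
#' identical sequences score 1 and the annotation cutoff ("label only when
#' the best identity reaches 0.9") reads naturally.
#'
#' @param a,b character vectors of sequences (recycled).
#' @param cutoff optional early-abandon bound on the underlying edit
#'   distance; identities whose distance exceeds it are reported as upper
#'   bounds.
#' @return numeric vector of identities in [0, 1].
#' @export
seqIdentity <- function(a, b, cutoff = -1L) {
    a <- as.character(a); b <- as.character(b)
    d <- editDistance(a, b, cutoff)
    n <- pmax(nchar(a), nchar(b))
    1 - d / n
}

#' Write labeled intervals to BED
#'
#' Writes a six-column BED file (0-based half-open on disk) whose name column
#' carries the monomer/HOR label and whose strand column is populated.
#' In-memory coordinates follow the Bioconductor convention (1-based closed);
#' conversion is handled by the BED writer.
#'
#' @param gr a \code{GRanges}; \code{mcols(gr)$name} supplies the name
#'   column (\code{"."} when absent).
#' @param path output file path.
#' @param sort if \code{TRUE}, sort by chromosome and start before writing.
#' @return invisibly, \code{path}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr5", IRanges::IRanges(1, 171), "+",
#'     name = "mon1")
#' tf <- tempfile(fileext = ".bed")
#' writeBed(gr, tf)
#' readLines(tf)
#' @export
writeBed <- function(gr, path, sort = FALSE) {
    if (!is(gr, "GRanges")) stop("'gr' must be a GRanges")
    if (sort) gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    if (is.null(S4Vectors::mcols(gr)$name))
        S4Vectors::mcols(gr)$name <- rep(".", length(gr))
    if (is.null(S4Vectors::mcols(gr)$score))
        S4Vectors::mcols(gr)$score <- rep(0L, length(gr))
    rtracklayer::export.bed(gr, path)
    invisible(path)
}

#' Read a BED file into a GRanges
#'
#' @param path path to a BED file.
#' @return a \code{GRanges} with 1-based closed coordinates and \code{name} /
#'   \code{score} metadata columns when present.
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    rtracklayer::import.bed(path)
}
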