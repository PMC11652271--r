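#' Decompose a sequence into template-sized blocks
#'
#' Tiles a read or satellite array into consecutive blocks by a
#' dynamic-programming parse in which every block is scored as a full global
#' alignment of the alpha-satellite template and the block boundaries
#' minimize the total edit cost (the StringDecomposer contract).  Block
#' lengths stay near the template length, drifting with indels.
#'
#' @param sequence a \code{DNAString}, character scalar, or
#'   \code{\linkS4class{SatelliteArray}}.
#' @param template the ~171-bp alpha-satellite template (character or
#'   \code{DNAString}).
#' @return data.frame with \code{start}, \code{end} (1-based closed) and
#'   \code{sequence} per block, tiling the input without gap or overlap.
#'   A sequence shorter than one template length yields a single block with
#'   a warning.
#' @examples
#' tpl <- paste(rep("ACGTT", 6), collapse = "")
#' decomposeBlocks(strrep(tpl, 5), tpl)
#' @export
decomposeBlocks <- function(sequence, template) {
    if (is(sequence, "SatelliteArray")) sequence <- arraySeq(sequence)
    s <- as.character(sequence)
    t <- as.character(template)
    if (!nchar(s) || !nchar(t)) stop("argument error: empty sequence")
    if (nchar(s) < nchar(t))
        warning("sequence shorter than template; returning a single block")
    dp <- cpp_decompose(s, t)
    data.frame(start = dp$start, end = dp$end,
               sequence = substring(s, dp$start, dp$end),
               stringsAsFactors = FALSE)
}

#' Label blocks with monomer template ids
#'
#' For each block the identity against every monomer template is computed as
#' \code{1 - ed(block, monomer) / max(len(block), len(monomer))} and the
#' block is labeled with the arg-max template id (ties broken by lowest id).
#' Blocks whose best identity falls below \code{cutoff} (default 0.9) are
#' labeled \code{"unknown"} -- such blocks may be transposable elements or
#' other sequence interjected into the HOR.
#'
#' @param blocks data.frame from \code{\link{decomposeBlocks}} (columns
#'   \code{start}, \code{end}, \code{sequence}).
#' @param templates \code{DNAStringSet} (or character vector) of monomer
#'   templates; names are used as ids, else \code{1..k}.
#' @param cutoff minimum identity for a monomer label (default 0.9).
#' @param source source id stored in the result.
#' @return a \code{\linkS4class{MonomerSequence}}.
#' @export
labelMonomers <- function(blocks, templates, cutoff = 0.9,
                          source = "seq") {
    tpl <- as.character(templates)
    if (!length(tpl)) stop("templates must be non-empty")
    ids <- names(tpl)
    if (is.null(ids)) ids <- as.character(seq_along(tpl))
    maxlen <- max(nchar(tpl), nchar(blocks$sequence))
    bound <- as.integer(ceiling((1 - cutoff) * maxlen)) + 2L
    d <- cpp_edit_distance_matrix(blocks$sequence, tpl, bound)
    denom <- outer(nchar(blocks$sequence), nchar(tpl), pmax)
    idm <- 1 - d / denom
    best <- apply(idm, 1L, which.max)        # ties: lowest template id
    bestId <- idm[cbind(seq_len(nrow(idm)), best)]
    tok <- ids[best]
    tok[bestId < cutoff] <- "unknown"
    new("MonomerSequence", source = source,
        ranges = IRanges::IRanges(blocks$start, blocks$end),
        tokens = tok, identities = pmax(0, bestId))
}

#' Infer monomer templates from a satellite array by community detection
#'
#' Blocks of the array are clustered on a similarity graph whose edges
#' connect block pairs above an identity threshold (weighted by identity);
#' communities are found by modularity maximization (Louvain).  For each
#' community the representative is the member minimizing the summed edit
#' distance to all other members; a community of one monomer is its own
#' representative.  Representatives are numbered in order of first
#' appearance along the array, matching monomer-pattern notation 1-2-3-...
#'
#' @param array a \code{\linkS4class{SatelliteArray}}, \code{DNAString} or
#'   character scalar.
#' @param template the alpha-satellite template used for block
#'   decomposition.
#' @param seed integer seed for the community detection.
#' @param edgeThreshold minimum identity for a graph edge (default 0.9).
#' @param maxBlocks blocks are subsampled (deterministically, evenly spaced)
#'   to at most this many before the quadratic pairwise stage (default 400).
#' @return \code{DNAStringSet} of monomer templates named \code{1..k}.
#' @export
inferMonomerTemplates <- function(array, template, seed = 1L,
                                  edgeThreshold = 0.9, maxBlocks = 400L) {
    blocks <- decomposeBlocks(array, template)
    if (nrow(blocks) == 1L)
        return(Biostrings::DNAStringSet(setNames(blocks$sequence, "1")))
    if (nrow(blocks) > maxBlocks) {
        keep <- unique(as.integer(round(seq(1L, nrow(blocks),
                                            length.out = maxBlocks))))
        blocks <- blocks[keep, , drop = FALSE]
    }
    seqs <- blocks$sequence
    L <- max(nchar(seqs))
    d <- cpp_self_edit_distance(seqs, as.integer(ceiling(
        (1 - edgeThreshold) * L)) + 2L)
    idm <- 1 - d / outer(nchar(seqs), nchar(seqs), pmax)
    adj <- idm * (idm >= edgeThreshold)
    diag(adj) <- 0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    set.seed(seed)
    comm <- igraph::membership(igraph::cluster_louvain(g))
    reps <- vapply(sort(unique(comm)), function(cm) {
        idx <- which(comm == cm)
        if (length(idx) == 1L) return(idx)
        dd <- d[idx, idx, drop = FALSE]
        idx[which.min(rowSums(dd))]
    }, 0L)
    # number communities by first appearance along the array
    firsts <- vapply(sort(unique(comm)), function(cm) min(which(comm == cm)),
                     0L)
    reps <- reps[order(firsts)]
    Biostrings::DNAStringSet(setNames(seqs[reps],
                                      as.character(seq_along(reps))))
}

#' Decompose, label and mine a sequence in one call
#'
#' Convenience wrapper chaining \code{\link{decomposeBlocks}},
#' \code{\link{labelMonomers}} and \code{\link{htrmMine}}.
#'
#' @param sequence a \code{DNAString}, character scalar or
#'   \code{\linkS4class{SatelliteArray}}.
#' @param template the alpha-satellite template.
#' @param monomerTemplates monomer template set (see
#'   \code{\link{labelMonomers}}).
#' @param source source id for the outputs.
#' @param cutoff identity cutoff for monomer labels.
#' @param maxUnit largest HOR unit length mined.
#' @return list with \code{monomers} (a
#'   \code{\linkS4class{MonomerSequence}}) and \code{annotation} (a
#'   \code{\linkS4class{HORAnnotation}}).
#' @export
annotateSequence <- function(sequence, template, monomerTemplates,
                             source = "seq", cutoff = 0.9, maxUnit = 40L) {
    blocks <- decomposeBlocks(sequence, template)
    ms <- labelMonomers(blocks, monomerTemplates, cutoff = cutoff,
                        source = source)
    list(monomers = ms,
         annotation = htrmMine(ms, maxUnit = maxUnit, source = source))
}
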