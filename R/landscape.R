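# center-star consensus: align everything to the medoid (the member with
# minimal summed edit distance), then take the majority character at every
# medoid position; gap majorities are dropped.
.consensusSeq <- function(seqs, medoidSample = 30L) {
    seqs <- as.character(seqs)
    if (length(seqs) == 1L) return(seqs)
    idx <- if (length(seqs) > medoidSample)
        unique(as.integer(round(seq(1L, length(seqs),
                                    length.out = medoidSample))))
    else seq_along(seqs)
    # distances only rank candidate medoids among near-identical units, so
    # a tight clip suffices (far pairs tie above it)
    bound <- as.integer(ceiling(0.05 * max(nchar(seqs)))) + 2L
    d <- cpp_self_edit_distance(seqs[idx], bound)
    medoid <- seqs[idx[which.min(rowSums(d))]]
    cols <- .projectOnRef(seqs, medoid)
    m <- do.call(rbind, strsplit(cols, ""))
    cons <- apply(m, 2L, function(col) {
        tb <- sort(table(col), decreasing = TRUE)
        names(tb)[1L]
    })
    paste(cons[cons != "-"], collapse = "")
}

# project each sequence onto the reference coordinates of one global
# alignment pass: for every reference position, the aligned character of
# the sequence ("-" on deletion); insertions fall between reference
# columns and are dropped
.projectOnRef <- function(seqs, ref) {
    out <- seqs
    todo <- which(seqs != ref)
    if (!length(todo)) return(out)
    # equal-length, low-divergence pairs align column to column under unit
    # costs, so the projection is the sequence itself
    refraw <- charToRaw(ref)
    direct <- vapply(todo, function(i) {
        nchar(seqs[i]) == length(refraw) &&
            sum(charToRaw(seqs[i]) != refraw) <=
                max(3L, length(refraw) %/% 20L)
    }, TRUE)
    todo <- todo[!direct]
    if (!length(todo)) return(out)
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(seqs[todo]), ref, type = "global")
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")
    q <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")
    out[todo] <- vapply(seq_along(todo), function(i)
        paste(p[[i]][q[[i]] != "-"], collapse = ""), "")
    out
}

# 0-1 difference matrix of units against the consensus: one column per
# consensus position, 1 on mismatch or deletion (gap columns in the unit
# count as difference; insertions in the unit fall between consensus
# columns and are not encoded).
.zeroOneMatrix <- function(units, consensus) {
    proj <- .projectOnRef(units, consensus)
    ref <- strsplit(consensus, "")[[1]]
    t(vapply(strsplit(proj, ""), function(ch) as.integer(ch != ref),
             integer(nchar(consensus))))
}

.zeroOneVector <- function(unit, consensus)
    .zeroOneMatrix(unit, consensus)[1L, ]

#' Cluster HOR unit sequences across landscapes
#'
#' The DNA sequences of the target HOR's units (the largest monomer pattern
#' shared by the landscapes' primary HORs) are encoded as 0-1 difference
#' vectors against their consensus (most common base at every position of a
#' center-star alignment) and clustered by k-means.  With \code{k = "auto"}
#' the smallest k in \code{kRange} whose cluster-landscape association
#' (Cramer's V of the cluster x landscape table) exceeds
#' \code{assocThreshold} is chosen (or the best-associating k when none
#' passes).
#'
#' @param units \code{DNAStringSet} or character vector of HOR unit DNA
#'   sequences.
#' @param landscape factor/character: the landscape each unit came from.
#' @param k integer cluster count, or \code{"auto"}.
#' @param kRange candidate k values for auto selection (default 2:6).
#' @param assocThreshold Cramer's V threshold for auto selection (default
#'   0.3).
#' @param seed integer seed for k-means.
#' @return list with \code{k}, \code{assignment} (cluster labels R0, R1,
#'   ... ordered by cluster size), \code{consensus} (overall consensus),
#'   \code{clusterConsensus} (per-cluster consensus sequences),
#'   \code{vectors} (the 0-1 matrix), \code{composition} (landscape x
#'   cluster table) and \code{association} (Cramer's V per tried k).
#' @export
clusterUnitsCrossLandscape <- function(units, landscape, k = "auto",
                                       kRange = 2:6,
                                       assocThreshold = 0.3, seed = 1L) {
    seqs <- as.character(units)
    stopifnot(length(seqs) == length(landscape))
    if (length(unique(seqs)) == 1L)
        stop("degenerate: all units identical; clustering refused")
    cons <- .consensusSeq(seqs)
    V <- .zeroOneMatrix(seqs, cons)
    kmFit <- function(kk) {
        if (length(seqs) < kk)
            stop("argument error: fewer units than clusters")
        set.seed(seed)
        kmeans(V, centers = kk, nstart = 10L, iter.max = 50L)
    }
    cramerV <- function(cl) {
        tab <- table(cl, landscape)
        if (min(dim(tab)) < 2L) return(0)
        chi <- suppressWarnings(chisq.test(tab)$statistic)
        sqrt(chi / (sum(tab) * (min(dim(tab)) - 1L)))
    }
    assoc <- NULL
    if (identical(k, "auto")) {
        kRange <- kRange[kRange <= length(unique(seqs))]
        assoc <- vapply(kRange, function(kk) cramerV(kmFit(kk)$cluster), 0)
        names(assoc) <- kRange
        pass <- which(assoc > assocThreshold)
        k <- if (length(pass)) kRange[pass[1L]] else
            kRange[which.max(assoc)]
    }
    km <- kmFit(k)
    sizes <- table(km$cluster)
    ord <- order(-sizes, as.integer(names(sizes)))
    lab <- paste0("R", match(km$cluster, as.integer(names(sizes))[ord]) -
                  1L)
    names(lab) <- if (!is.null(names(units))) names(units) else
        paste0("unit", seq_along(seqs))
    clCons <- vapply(paste0("R", seq_len(k) - 1L), function(cl)
        .consensusSeq(seqs[lab == cl]), "")
    list(k = k, assignment = lab, consensus = cons,
         clusterConsensus = clCons, vectors = V,
         composition = table(landscape, cluster = lab),
         association = assoc)
}

# cut an unrooted distance tree into g leaf groups by removing the g-1
# longest edges
.cutTreeGroups <- function(tree, g) {
    ed <- tree$edge
    len <- tree$edge.length
    ntip <- length(tree$tip.label)
    if (g > ntip) stop("more groups than tips")
    drop <- order(-len)[seq_len(g - 1L)]
    gph <- igraph::graph_from_edgelist(apply(ed[-drop, , drop = FALSE],
                                             2L, as.character),
                                       directed = FALSE)
    miss <- setdiff(as.character(seq_len(ntip + tree$Nnode)),
                    igraph::V(gph)$name)
    gph <- igraph::add_vertices(gph, length(miss), name = miss)
    comp <- igraph::components(gph)$membership
    grp <- comp[as.character(seq_len(ntip))]
    setNames(match(grp, unique(grp)), tree$tip.label)
}

#' Reconstruct an ancestral HOR from outgroup monomers
#'
#' Outgroup monomers (from another chromosome of the same suprachromosomal
#' family) are grouped by cutting a neighbor-joining tree of their edit
#' distances into the stated number of groups; each group's consensus is an
#' ancestral monomer.  A joint tree of target monomer consensuses and
#' ancestral monomers yields the target-ancestral correspondence (nearest
#' ancestral monomer by tree distance; ties are flagged, not silently
#' assigned), and the ancestral HOR sequence is assembled by substituting
#' each target monomer in the target HOR with its corresponding ancestral
#' monomer.
#'
#' @param targetMonomers \code{DNAStringSet} of per-monomer consensus
#'   sequences of the target HOR, named by monomer id.
#' @param outgroupMonomers \code{DNAStringSet} of outgroup monomer
#'   sequences.
#' @param nGroups number of ancestral monomer groups (from the
#'   suprachromosomal family's ancestral HOR).
#' @param targetPattern integer vector: the target HOR monomer pattern (ids
#'   indexing \code{targetMonomers} names); default all target monomers in
#'   order.
#' @param clusterConsensus optional \code{DNAStringSet}/character of HOR
#'   cluster consensus sequences to include in the identity matrix.
#' @return list with \code{groups} (outgroup monomer group per sequence),
#'   \code{ancestralMonomers} (\code{DNAStringSet}), \code{tree} (outgroup
#'   NJ tree), \code{jointTree}, \code{correspondence} (named map, NA where
#'   ambiguous), \code{ambiguous} (flagged target monomers),
#'   \code{ancestralHor} (character) and \code{identity} (identity matrix
#'   of ancestral HOR vs cluster consensuses).
#' @export
reconstructAncestralHor <- function(targetMonomers, outgroupMonomers,
                                    nGroups,
                                    targetPattern = NULL,
                                    clusterConsensus = NULL) {
    og <- as.character(outgroupMonomers)
    if (is.null(names(og))) names(og) <- paste0("og", seq_along(og))
    tg <- as.character(targetMonomers)
    if (is.null(names(tg))) names(tg) <- as.character(seq_along(tg))
    if (is.null(targetPattern)) targetPattern <- names(tg)
    targetPattern <- as.character(targetPattern)
    D <- cpp_self_edit_distance(og)
    dimnames(D) <- list(names(og), names(og))
    tree <- ape::nj(as.dist(D))
    grp <- .cutTreeGroups(tree, nGroups)[names(og)]
    anc <- vapply(seq_len(nGroups), function(g)
        .consensusSeq(og[grp == g]), "")
    names(anc) <- paste0("anc", seq_len(nGroups))
    joint <- c(tg, anc)
    DJ <- cpp_self_edit_distance(joint)
    dimnames(DJ) <- list(names(joint), names(joint))
    jointTree <- ape::nj(as.dist(DJ))
    coph <- ape::cophenetic.phylo(jointTree)
    corr <- setNames(rep(NA_character_, length(tg)), names(tg))
    ambiguous <- character(0)
    for (t in names(tg)) {
        dd <- coph[t, names(anc)]
        best <- which(abs(dd - min(dd)) < 1e-9)
        if (length(best) > 1L) ambiguous <- c(ambiguous, t)
        else corr[t] <- names(anc)[best]
    }
    ancHor <- if (length(ambiguous)) NA_character_ else
        paste(anc[corr[targetPattern]], collapse = "")
    idm <- NULL
    if (!is.na(ancHor)) {
        members <- c(ancestral = ancHor)
        if (!is.null(clusterConsensus)) {
            cc <- as.character(clusterConsensus)
            if (is.null(names(cc))) names(cc) <- paste0("R",
                                                        seq_along(cc) - 1L)
            members <- c(members, cc)
        }
        dmx <- cpp_self_edit_distance(members)
        idm <- 1 - dmx / outer(nchar(members), nchar(members), pmax)
        diag(idm) <- 1
        dimnames(idm) <- list(names(members), names(members))
    }
    list(groups = grp, ancestralMonomers =
             Biostrings::DNAStringSet(anc), tree = tree,
         jointTree = jointTree, correspondence = corr,
         ambiguous = ambiguous, ancestralHor = ancHor, identity = idm)
}

#' Recent-expansion sliding-window track
#'
#' For each window of \code{window} consecutive HOR units (sliding by
#' \code{slide}), counts the unit pairs whose DNA sequences match exactly
#' (the default), or the units having at least one exact twin in the
#' window (\code{mode = "units"}).
#'
#' @param units character vector or \code{DNAStringSet} of HOR unit DNA
#'   sequences in array order.
#' @param window window size in units (default 10).
#' @param slide slide in units (default 1).
#' @param mode \code{"pairs"} or \code{"units"}.
#' @return data.frame with \code{start} (1-based index of the window's
#'   first unit) and \code{count}; empty with a warning when fewer than
#'   \code{window} units are supplied.
#' @examples
#' recentExpansionTrack(rep("ACGT", 10))$count  # 45 = choose(10, 2)
#' @export
recentExpansionTrack <- function(units, window = 10L, slide = 1L,
                                 mode = c("pairs", "units")) {
    mode <- match.arg(mode)
    seqs <- as.character(units)
    if (length(seqs) < window) {
        warning("fewer than ", window, " units; empty track")
        return(data.frame(start = integer(0), count = integer(0)))
    }
    starts <- seq(1L, length(seqs) - window + 1L, by = slide)
    cnt <- vapply(starts, function(i) {
        tb <- table(seqs[i:(i + window - 1L)])
        if (mode == "pairs") sum(choose(tb, 2L)) else sum(tb[tb > 1L])
    }, 0)
    data.frame(start = starts, count = as.integer(cnt))
}

#' Monomer-length distribution of a HOR's units
#'
#' Histogram of per-unit expanded monomer lengths (the unit length after
#' expanding locally nested subunits, e.g. 10/12/16/20-mors), the modal
#' peak, and a per-sample ratio vector over tracked lengths for downstream
#' k-means grouping of samples.
#'
#' @param annotation a \code{\linkS4class{HORAnnotation}} (or a units
#'   data.frame with an \code{expandedLength} column).
#' @param canonical optional canonical pattern key to restrict to.
#' @param trackLengths optional integer vector of lengths to report ratios
#'   for (e.g. \code{c(12, 16, 20)}); ratios plus the remainder sum to 1.
#' @return list with \code{histogram} (table), \code{peak} (modal length,
#'   smallest on ties) and \code{ratios} (named vector over
#'   \code{trackLengths} plus \code{other}).
#' @export
mpLengthDistribution <- function(annotation, canonical = NULL,
                                 trackLengths = NULL) {
    u <- if (is(annotation, "HORAnnotation")) horUnits(annotation) else
        annotation
    if (!is.null(canonical)) u <- u[u$canonical == canonical, ,
                                    drop = FALSE]
    len <- u$expandedLength
    if (!length(len)) stop("no units to summarize")
    h <- table(len)
    peak <- as.integer(names(h)[which.max(h)])
    ratios <- NULL
    if (!is.null(trackLengths)) {
        r <- vapply(trackLengths, function(L) mean(len == L), 0)
        ratios <- c(setNames(r, trackLengths), other = 1 - sum(r))
    }
    list(histogram = h, peak = peak, ratios = ratios)
}
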