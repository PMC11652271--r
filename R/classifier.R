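#' Canonical 5-mer feature table
#'
#' Enumerates all k-mers collapsed with their reverse complements into one
#' feature each; at odd k no palindromes exist, so for k = 5 there are
#' exactly 1024 / 2 = 512 features.
#'
#' @param k k-mer size (default 5).
#' @return data.frame with \code{kmer}, \code{revcomp} and \code{canonical}
#'   (the lexicographic minimum of the pair) for all 4^k k-mers.
#' @examples
#' length(unique(canonicalKmers()$canonical))  # 512
#' @export
canonicalKmers <- function(k = 5L) {
    km <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(km)))
    data.frame(kmer = km, revcomp = rc, canonical = pmin(km, rc),
               stringsAsFactors = FALSE)
}

#' Canonical 5-mer frequency features for reads
#'
#' Counts every overlapping 5-mer window of each read (windows containing
#' \code{N} are skipped), collapses a 5-mer with its reverse complement into
#' one canonical feature (512 columns), and divides the counts by the read
#' length.  The feature vector of a read equals that of its reverse
#' complement exactly.
#'
#' @param reads \code{DNAStringSet} or character vector.
#' @param k k-mer size (default 5; the two-step classifier assumes 5).
#' @return numeric matrix, one row per read (named), 4^k / 2 columns named
#'   by canonical k-mer.  Reads shorter than k are dropped with a warning.
#' @examples
#' kmerFeatures(c(r1 = "AAAAAA"))[, "AAAAA"]  # 2/6
#' @export
kmerFeatures <- function(reads, k = 5L) {
    if (!is(reads, "DNAStringSet"))
        reads <- Biostrings::DNAStringSet(reads)
    if (is.null(names(reads)))
        names(reads) <- paste0("read", seq_along(reads))
    short <- Biostrings::width(reads) < k
    if (any(short)) {
        warning(sum(short), " read(s) shorter than ", k, " bp skipped")
        reads <- reads[!short]
    }
    of <- Biostrings::oligonucleotideFrequency(reads, width = k)
    ck <- canonicalKmers(k)
    canon <- sort(unique(ck$canonical))
    pairA <- match(canon, ck$kmer)
    pairB <- match(ck$revcomp[pairA], ck$kmer)
    m <- of[, pairA, drop = FALSE] + of[, pairB, drop = FALSE]
    colnames(m) <- canon
    rownames(m) <- names(reads)
    m / Biostrings::width(reads)
}

#' Simulate labeled training reads from an annotated reference
#'
#' Positive reads are sampled from the per-chromosome satellite arrays
#' (satellite regions concatenated), with lengths uniform in
#' \code{readRange}, equal counts per chromosome, half of the set
#' reverse-complemented, over \code{rounds} replicate rounds.  An equal
#' total number of negative reads is sampled outside the satellite regions;
#' candidates touching a satellite region are rejected and resampled.
#'
#' @param assembly \code{DNAStringSet} of reference chromosomes.
#' @param satellites \code{GRanges} of satellite-array intervals on the
#'   assembly.
#' @param seed integer seed.
#' @param readsPerChrom positive reads per chromosome per round.
#' @param rounds number of replicate simulation rounds (default 10).
#' @param readRange read length range in bp (default 10--25 kb).
#' @return list with \code{reads} (\code{DNAStringSet}) and \code{labels}
#'   (data.frame: read, stage1 "Alpha"/"Non-Alpha", chromosome, strand).
#'   Chromosomes whose satellite array is shorter than the minimum read
#'   length are skipped with a warning.
#' @export
simulateTrainingReads <- function(assembly, satellites, seed = 1L,
                                  readsPerChrom = 10L, rounds = 10L,
                                  readRange = c(10000L, 25000L)) {
    set.seed(seed)
    chroms <- intersect(names(assembly),
                        unique(as.character(GenomicRanges::seqnames(
                            satellites))))
    arrays <- lapply(chroms, function(ch) {
        gr <- satellites[GenomicRanges::seqnames(satellites) == ch]
        gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
        paste(vapply(seq_along(gr), function(i) as.character(
            Biostrings::subseq(assembly[[ch]], GenomicRanges::start(gr)[i],
                               GenomicRanges::end(gr)[i])), ""),
            collapse = "")
    })
    names(arrays) <- chroms
    ok <- nchar(unlist(arrays)) >= readRange[1]
    if (any(!ok))
        warning("satellite array shorter than minimum read length; ",
                "skipping: ", paste(chroms[!ok], collapse = ", "))
    chroms <- chroms[ok]; arrays <- arrays[ok]
    reads <- character(0); lab <- list()
    for (rd in seq_len(rounds)) {
        for (ch in chroms) {
            alen <- nchar(arrays[[ch]])
            for (i in seq_len(readsPerChrom)) {
                rl <- min(sample(readRange[1]:readRange[2], 1L), alen)
                st <- sample.int(alen - rl + 1L, 1L)
                reads <- c(reads, substr(arrays[[ch]], st, st + rl - 1L))
                lab[[length(reads)]] <- data.frame(stage1 = "Alpha",
                    chromosome = ch, stringsAsFactors = FALSE)
            }
        }
    }
    npos <- length(reads)
    # negatives anywhere outside the satellite regions, mirroring the
    # positive length model; boundary-touching candidates are resampled
    clens <- Biostrings::width(assembly)
    names(clens) <- names(assembly)
    nneg <- 0L
    while (nneg < npos) {
        ch <- sample(names(assembly), 1L, prob = clens)
        rl <- sample(readRange[1]:readRange[2], 1L)
        if (clens[ch] < rl) next
        st <- sample.int(clens[ch] - rl + 1L, 1L)
        cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(st,
                                                            st + rl - 1L))
        if (length(GenomicRanges::findOverlaps(cand, satellites)) > 0L)
            next
        reads <- c(reads, as.character(Biostrings::subseq(assembly[[ch]],
                                                          st, st + rl - 1L)))
        nneg <- nneg + 1L
        lab[[length(reads)]] <- data.frame(stage1 = "Non-Alpha",
            chromosome = NA_character_, stringsAsFactors = FALSE)
    }
    labels <- do.call(rbind, lab)
    labels$read <- paste0("sim", seq_len(nrow(labels)))
    labels$strand <- "+"
    # reverse-complement half of the positives (and, symmetrically, half of
    # the negatives)
    for (grp in c("Alpha", "Non-Alpha")) {
        idx <- which(labels$stage1 == grp)
        flip <- idx[sample(rep(c(TRUE, FALSE), length.out = length(idx)))]
        reads[flip] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(reads[flip])))
        labels$strand[flip] <- "-"
    }
    list(reads = Biostrings::DNAStringSet(setNames(reads, labels$read)),
         labels = labels[, c("read", "stage1", "chromosome", "strand")])
}

.trainStage <- function(features, y, stage, varThreshold, cost) {
    tab <- table(y)
    if (length(tab) < 2L)
        stop("training error: stage '", stage, "' needs >= 2 classes")
    if (any(tab < 2L))
        stop("training error: class with < 2 examples: ",
             paste(names(tab)[tab < 2L], collapse = ", "))
    pc <- prcomp(features, center = TRUE, scale. = FALSE)
    cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    ncomp <- which(cumvar > varThreshold)[1L]
    proj <- pc$x[, seq_len(ncomp), drop = FALSE]
    fit <- e1071::svm(proj, factor(y), kernel = "linear", cost = cost,
                      scale = FALSE)
    new("KmerClassifier", stage = stage, labels = names(tab),
        center = pc$center,
        rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
        nComp = as.integer(ncomp), varExplained = cumvar[ncomp],
        model = fit)
}

#' Train the two-step alpha-satellite read classifier
#'
#' Stage 1 separates alpha-satellite from non-alpha reads; stage 2 assigns
#' alpha reads to chromosomes.  Each stage projects the canonical 5-mer
#' features onto the principal components whose cumulative explained
#' variance exceeds \code{varThreshold} (default 0.95) and fits a linear
#' SVM (regularization constant \code{cost}; the kernel and cost are
#' configuration defaults of this package, fixed for reproducibility).
#'
#' @param reads training reads (\code{DNAStringSet}).
#' @param labels data.frame with \code{stage1} ("Alpha"/"Non-Alpha") and
#'   \code{chromosome} columns, row order matching \code{reads} (e.g. from
#'   \code{\link{simulateTrainingReads}}).
#' @param seed integer seed.
#' @param varThreshold minimum cumulative explained variance of the
#'   retained components.
#' @param cost SVM regularization constant (default 1).
#' @return list of two \code{\linkS4class{KmerClassifier}} objects
#'   (\code{stage1}, \code{stage2}).
#' @export
trainTwoStage <- function(reads, labels, seed = 1L, varThreshold = 0.95,
                          cost = 1) {
    set.seed(seed)
    features <- kmerFeatures(reads)
    stage1 <- .trainStage(features, labels$stage1, "alpha_vs_non",
                          varThreshold, cost)
    alpha <- labels$stage1 == "Alpha"
    stage2 <- .trainStage(features[alpha, , drop = FALSE],
                          labels$chromosome[alpha], "chromosome",
                          varThreshold, cost)
    list(stage1 = stage1, stage2 = stage2)
}

.predictStage <- function(model, features) {
    if (ncol(features) != nrow(model@rotation))
        stop("model error: feature dimension mismatch (",
             ncol(features), " vs ", nrow(model@rotation), ")")
    proj <- sweep(features, 2L, model@center) %*% model@rotation
    as.character(predict(model@model, proj))
}

#' Classify reads with a trained two-step model
#'
#' Every read receives \code{"Non-Alpha"} or a chromosome label; the
#' chromosome stage is applied only to stage-1 positives.  There is no
#' length gate at inference time: the 10--25 kb range constrains training
#' only.
#'
#' @param reads \code{DNAStringSet} or character vector.
#' @param models list of two \code{\linkS4class{KmerClassifier}} objects
#'   from \code{\link{trainTwoStage}}.
#' @return data.frame with \code{read}, \code{stage1} and
#'   \code{chromosome} (\code{NA} for non-alpha reads).
#' @export
classifyReads <- function(reads, models) {
    features <- kmerFeatures(reads)
    s1 <- .predictStage(models$stage1, features)
    chrom <- rep(NA_character_, nrow(features))
    alpha <- s1 == "Alpha"
    if (any(alpha))
        chrom[alpha] <- .predictStage(models$stage2,
                                      features[alpha, , drop = FALSE])
    data.frame(read = rownames(features), stage1 = s1, chromosome = chrom,
               stringsAsFactors = FALSE)
}
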