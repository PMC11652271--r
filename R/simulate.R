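#' Specification of a synthetic centromere simulation
#'
#' Collects the parameters of a synthetic alpha-satellite cohort.  Defaults
#' follow the biology the simulator emulates: ~171-bp monomers sharing
#' 50--90\% identity across a centromere (default cross-identity target
#' 0.7), HOR units sharing 95--100\% identity (default per-base mutation
#' rate 0.01, i.e. ~98\% unit identity), and HiFi-like reads of 10--25 kb.
#'
#' @param monomerCount number of distinct monomers.
#' @param monomerLength monomer length in bp (default 171).
#' @param crossIdentity target pairwise identity between monomers, in the
#'   50--90\% band (default 0.7).
#' @param pattern integer vector: the planted HOR monomer pattern (default
#'   \code{1..monomerCount}).
#' @param nUnits HOR units per array (default 100).
#' @param mutationRate per-base substitution rate applied to each unit copy
#'   (default 0.01).
#' @param indelRate per-base insertion/deletion rate (default 0; substitution
#'   -only keeps unit-length truth crisp).
#' @param nesting optional list of nesting events, each
#'   \code{list(sub = , count = , units = )}: in the given unit indices the
#'   first occurrence of \code{sub} within \code{pattern} is replaced by
#'   \code{count} tandem copies.
#' @param coverage sequencing fold-coverage for read simulation (default
#'   20).
#' @param readRange read length range in bp, within [1 kb, 100 kb] (default
#'   \code{c(10000, 25000)}).
#' @param flank length of uniform-random flanking DNA placed around arrays
#'   when an assembly is built (default 20000).
#' @param seed integer seed; all randomness in the generators derives from
#'   it.
#' @return a list of class \code{"SimSpec"}.
#' @export
simSpec <- function(monomerCount = 5L, monomerLength = 171L,
                    crossIdentity = 0.7, pattern = seq_len(monomerCount),
                    nUnits = 100L, mutationRate = 0.01, indelRate = 0,
                    nesting = NULL, coverage = 20, readRange = c(10000L,
                    25000L), flank = 20000L, seed = 1L) {
    stopifnot(monomerCount >= 1L, monomerLength >= 50L,
              crossIdentity > 0, crossIdentity < 1,
              mutationRate >= 0, mutationRate <= 1,
              indelRate >= 0, indelRate <= 1, coverage > 0,
              length(readRange) == 2L, readRange[1] <= readRange[2],
              readRange[1] >= 1000L, readRange[2] <= 100000L)
    if (!all(pattern %in% seq_len(monomerCount)))
        stop("pattern uses undefined monomer ids")
    structure(list(monomerCount = as.integer(monomerCount),
                   monomerLength = as.integer(monomerLength),
                   crossIdentity = crossIdentity,
                   pattern = as.integer(pattern),
                   nUnits = as.integer(nUnits),
                   mutationRate = mutationRate, indelRate = indelRate,
                   nesting = nesting, coverage = coverage,
                   readRange = as.integer(readRange),
                   flank = as.integer(flank), seed = as.integer(seed)),
              class = "SimSpec")
}

.randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

.mutateSubs <- function(s, pos) {
    if (!length(pos)) return(s)
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    paste(ch, collapse = "")
}

#' Generate a monomer set at a target cross-identity
#'
#' Each monomer is derived from a hidden base sequence by substituting a
#' fixed number of positions chosen so that the expected pairwise identity
#' between monomers matches the target (two independently mutated copies
#' differ at a position with probability \code{2p(1-p) + (2/3)p^2}, which is
#' solved for the per-monomer substitution fraction \code{p}).
#'
#' @param spec a \code{\link{simSpec}}.
#' @return list with \code{monomers} (\code{DNAStringSet} named
#'   \code{1..k}), \code{template} (the hidden base consensus, the
#'   synthetic analog of the alpha-satellite template sequence) and
#'   \code{pairwiseIdentity} (realized identity matrix).
#' @export
genMonomers <- function(spec) {
    set.seed(spec$seed)
    L <- spec$monomerLength
    k <- spec$monomerCount
    t <- spec$crossIdentity
    disc <- 1 - (4 / 3) * (1 - t)
    if (disc < 0)
        stop("unreachable identity target ", t, " for length ", L)
    p <- (1 - sqrt(disc)) * 3 / 4
    s <- round(p * L)
    base <- .randDna(L)
    mono <- vapply(seq_len(k), function(i)
        .mutateSubs(base, sample.int(L, s)), "")
    out <- Biostrings::DNAStringSet(setNames(mono, as.character(seq_len(k))))
    pid <- 1 - cpp_self_edit_distance(mono) / L
    dimnames(pid) <- list(names(out), names(out))
    list(monomers = out, template = Biostrings::DNAString(base),
         pairwiseIdentity = pid)
}

# monomer id layout of one unit, applying nesting events for unit i
.unitLayout <- function(spec, i) {
    ids <- spec$pattern
    for (ev in spec$nesting) {
        if (!is.null(ev$units) && !(i %in% ev$units)) next
        sub <- as.integer(ev$sub)
        hit <- .findSub(ids, sub)
        if (is.na(hit)) stop("nesting subpattern not found in pattern")
        ids <- c(ids[seq_len(hit - 1L)], rep(sub, ev$count),
                 if (hit + length(sub) <= length(ids))
                     ids[(hit + length(sub)):length(ids)])
    }
    ids
}

.findSub <- function(x, sub) {
    m <- length(sub)
    for (i in seq_len(length(x) - m + 1L))
        if (all(x[i:(i + m - 1L)] == sub)) return(i)
    NA_integer_
}

#' Generate a synthetic satellite array with planted truth
#'
#' Concatenates \code{nUnits} copies of the planted HOR pattern (with any
#' nesting events spliced in), applying per-base substitutions (and
#' optionally indels) to each copy.  The ground truth records every unit
#' interval, its monomer layout and expanded monomer length, and the planted
#' canonical pattern.
#'
#' @param spec a \code{\link{simSpec}}.
#' @param monomers monomer set from \code{\link{genMonomers}} (generated
#'   from \code{spec} when missing).
#' @return list with \code{sequence} (\code{DNAString}) and \code{truth}
#'   (list: \code{units} data.frame with bp intervals, \code{pattern},
#'   \code{canonical} key, \code{monomers}).
#' @export
genArray <- function(spec, monomers = NULL) {
    if (is.null(monomers)) monomers <- genMonomers(spec)$monomers
    set.seed(spec$seed + 1L)
    mono <- as.character(monomers)
    pieces <- character(spec$nUnits)
    units <- vector("list", spec$nUnits)
    pos <- 1L
    for (i in seq_len(spec$nUnits)) {
        ids <- .unitLayout(spec, i)
        s <- paste(mono[as.character(ids)], collapse = "")
        n <- nchar(s)
        nmut <- stats::rbinom(1L, n, spec$mutationRate)
        if (nmut > 0) s <- .mutateSubs(s, sample.int(n, nmut))
        if (spec$indelRate > 0) s <- .applyIndels(s, spec$indelRate)
        pieces[i] <- s
        units[[i]] <- data.frame(unit = i, start = pos,
                                 end = pos + nchar(s) - 1L,
                                 layout = paste(ids, collapse = "-"),
                                 expandedLength = length(ids))
        pos <- pos + nchar(s)
    }
    truthUnits <- do.call(rbind, units)
    truthUnits$canonical <- .canonKey(spec$pattern)
    list(sequence = Biostrings::DNAString(paste(pieces, collapse = "")),
         truth = list(units = truthUnits, pattern = spec$pattern,
                      canonical = .canonKey(spec$pattern),
                      monomers = monomers))
}

.applyIndels <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    ndel <- stats::rbinom(1L, n, rate / 2)
    nins <- stats::rbinom(1L, n, rate / 2)
    if (ndel > 0) ch <- ch[-sample.int(length(ch), ndel)]
    if (nins > 0) {
        at <- sort(sample.int(length(ch), nins, replace = TRUE))
        for (j in rev(seq_along(at)))
            ch <- append(ch, sample(c("A", "C", "G", "T"), 1L), after = at[j])
    }
    paste(ch, collapse = "")
}

#' Build a synthetic assembly around satellite arrays
#'
#' Wraps one array per chromosome in uniform-random flanking DNA so that
#' classifier training has non-satellite sequence to sample negatives from.
#'
#' @param arrays named list of array sequences (\code{DNAString} or
#'   character), one per chromosome.
#' @param flank flank length in bp on each side.
#' @param seed integer seed for the flank sequence.
#' @return list with \code{assembly} (\code{DNAStringSet}) and
#'   \code{satellites} (\code{GRanges} of the embedded arrays).
#' @export
genAssembly <- function(arrays, flank = 20000L, seed = 1L) {
    set.seed(seed + 2L)
    chroms <- names(arrays)
    if (is.null(chroms)) chroms <- paste0("chr", seq_along(arrays))
    seqs <- character(length(arrays))
    alen <- integer(length(arrays))
    for (i in seq_along(arrays)) {
        a <- as.character(arrays[[i]])
        alen[i] <- nchar(a)
        seqs[i] <- paste0(.randDna(flank), a, .randDna(flank))
    }
    list(assembly = Biostrings::DNAStringSet(setNames(seqs, chroms)),
         satellites = GenomicRanges::GRanges(chroms,
             IRanges::IRanges(flank + 1L, flank + alen)))
}

#' Sample long reads from arrays at a stated coverage
#'
#' Reads are drawn until the total base count reaches
#' \code{coverage * total array length}; lengths are uniform in
#' \code{readRange} (truncated to the source length when necessary), start
#' positions uniform, and exactly half of the reads are
#' reverse-complemented.
#'
#' @param arrays \code{DNAStringSet} (or named list / character vector) of
#'   source sequences.
#' @param spec a \code{\link{simSpec}} supplying \code{coverage},
#'   \code{readRange} and \code{seed}.
#' @return list with \code{reads} (\code{DNAStringSet}) and \code{truth}
#'   (data.frame: read, source, start, end, strand).
#' @export
genReads <- function(arrays, spec) {
    if (!is(arrays, "DNAStringSet"))
        arrays <- Biostrings::DNAStringSet(vapply(arrays, as.character, ""))
    if (is.null(names(arrays)))
        names(arrays) <- paste0("src", seq_along(arrays))
    set.seed(spec$seed + 3L)
    lens <- Biostrings::width(arrays)
    target <- spec$coverage * sum(lens)
    reads <- character(0); truth <- list(); total <- 0
    i <- 0L
    while (total < target) {
        i <- i + 1L
        src <- sample(seq_along(arrays), 1L, prob = lens)
        rl <- min(sample(spec$readRange[1]:spec$readRange[2], 1L), lens[src])
        st <- sample.int(lens[src] - rl + 1L, 1L)
        reads[i] <- as.character(Biostrings::subseq(arrays[[src]], st,
                                                    st + rl - 1L))
        truth[[i]] <- data.frame(read = paste0("read", i),
                                 source = names(arrays)[src],
                                 start = st, end = st + rl - 1L,
                                 strand = "+", stringsAsFactors = FALSE)
        total <- total + rl
    }
    truth <- do.call(rbind, truth)
    flip <- sample(rep(c(TRUE, FALSE), length.out = length(reads)))
    reads[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[flip])))
    truth$strand[flip] <- "-"
    out <- Biostrings::DNAStringSet(setNames(reads, truth$read))
    list(reads = out, truth = truth)
}

#' Simulate a diploid cohort with planted centromere genotypes
#'
#' Each sample carries two haplotypes chosen from two allele arrays (AA, AB
#' or BB); reads are sampled from each haplotype at half the stated
#' coverage, and the HOR units fully contained in sampled reads are counted
#' per canonical pattern.  The truth records the planted genotypes and the
#' per-sample true unit counts, so that genotype clustering recovery
#' (including the mean(C0+C1) heterozygote relation) is mechanically
#' checkable.
#'
#' @param alleleA,alleleB results of \code{\link{genArray}}: the two allele
#'   array definitions of the locus.
#' @param genotypes character vector of \code{"AA"}, \code{"AB"},
#'   \code{"BB"} per sample, or \code{NULL} to draw from
#'   \code{genotypeFreqs}.
#' @param nSamples number of samples when drawing genotypes.
#' @param genotypeFreqs named probabilities for AA/AB/BB (default
#'   \code{c(AA = 0.25, AB = 0.5, BB = 0.25)}).
#' @param coverage per-sample fold coverage (each haplotype is sampled at
#'   half of it).
#' @param readRange read length range in bp.
#' @param seed integer seed.
#' @param keepReads if \code{TRUE}, sampled reads are returned per sample
#'   (memory permitting).
#' @return list with \code{samples} (data.frame sample/genotype/coverage),
#'   \code{counts} (HOR pattern x sample matrix of observed unit counts),
#'   \code{readLength} (total sampled bases per sample),
#'   \code{trueCounts} (pattern x sample matrix from haplotype
#'   composition), and optionally \code{reads}.
#' @export
genCohort <- function(alleleA, alleleB, genotypes = NULL, nSamples = 30L,
                      genotypeFreqs = c(AA = 0.25, AB = 0.5, BB = 0.25),
                      coverage = 10, readRange = c(5000L, 10000L),
                      seed = 1L, keepReads = FALSE) {
    set.seed(seed + 4L)
    if (is.null(genotypes))
        genotypes <- sample(names(genotypeFreqs), nSamples, replace = TRUE,
                            prob = genotypeFreqs)
    nSamples <- length(genotypes)
    alleles <- list(A = alleleA, B = alleleB)
    keys <- unique(c(alleleA$truth$canonical, alleleB$truth$canonical))
    counts <- matrix(0, length(keys), nSamples,
                     dimnames = list(keys, paste0("S", seq_len(nSamples))))
    trueCounts <- counts
    readLen <- numeric(nSamples)
    allReads <- if (keepReads) vector("list", nSamples) else NULL
    for (k in seq_len(nSamples)) {
        hap <- strsplit(genotypes[k], "")[[1]]
        for (h in seq_along(hap)) {
            al <- alleles[[hap[h]]]
            tu <- al$truth$units
            for (key in unique(al$truth$canonical))
                trueCounts[key, k] <- trueCounts[key, k] +
                    sum(al$truth$units$canonical == key)
            hspec <- simSpec(monomerCount = 1L, coverage = coverage / 2,
                             readRange = readRange,
                             seed = seed + 10L * k + h)
            rr <- genReads(setNames(list(al$sequence), "hap"), hspec)
            readLen[k] <- readLen[k] + sum(Biostrings::width(rr$reads))
            for (i in seq_len(nrow(rr$truth))) {
                inside <- tu$start >= rr$truth$start[i] &
                          tu$end <= rr$truth$end[i]
                if (any(inside)) {
                    tb <- table(tu$canonical[inside])
                    counts[names(tb), k] <- counts[names(tb), k] + tb
                }
            }
            if (keepReads) allReads[[k]] <- c(allReads[[k]], rr$reads)
        }
    }
    out <- list(samples = data.frame(sample = colnames(counts),
                                     genotype = genotypes,
                                     coverage = coverage,
                                     stringsAsFactors = FALSE),
                counts = counts, readLength = readLen,
                trueCounts = trueCounts)
    if (keepReads) out$reads <- allReads
    out
}
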