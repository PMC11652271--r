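#' Coverage-normalized HOR quantities for one sample
#'
#' The n-number of HOR j is its raw unit count divided by the sample's
#' sequencing fold-coverage, and the estimated HOR array size of a
#' chromosome is the total length of its HOR-carrying reads divided by the
#' coverage; both scale exactly as 1/coverage.
#'
#' @param counts named numeric vector of raw HOR unit counts \code{r_j}.
#' @param coverage sequencing fold-coverage \code{c > 0}.
#' @param readLength optional named numeric vector: total bases of
#'   HOR-carrying reads per chromosome \code{l_i}.
#' @return list with \code{n} (n-numbers \code{r/c}), \code{s} (estimated
#'   array sizes \code{l/c}, when \code{readLength} given), plus the
#'   inputs.
#' @examples
#' quantifySample(c(R1L5 = 100), coverage = 20)$n  # 5
#' @export
quantifySample <- function(counts, coverage, readLength = NULL) {
    if (!is.numeric(coverage) || length(coverage) != 1L || coverage <= 0)
        stop("argument error: coverage must be a single positive number")
    out <- list(n = counts / coverage, coverage = coverage,
                counts = counts)
    if (!is.null(readLength)) {
        out$s <- readLength / coverage
        out$readLength <- readLength
    }
    out
}

#' Aggregate per-sample HOR patterns into a cross-sample catalog
#'
#' Identical canonical patterns (shift/reverse grouped) are merged across
#' samples; catalog entries are named by total repeat count across samples
#' ("M + rank + L + unit monomer length") and each sample's per-sample
#' R-names are mapped onto the catalog M-names.  Assembly-derived patterns
#' aggregate the same way, so their names match the read-derived catalog
#' through the shared canonical key.
#'
#' @param perSample named list of pattern data.frames (columns
#'   \code{canonical}, \code{L}, \code{count}), one per sample, e.g.
#'   \code{horPatterns()} results.
#' @param chromPrefix optional chromosome label for the M-names.
#' @return list with \code{catalog} (canonical, L, totalCount, nSamples,
#'   rank, name) and \code{mapping} (sample, canonical, sampleName, name).
#' @export
aggregateHors <- function(perSample, chromPrefix = NULL) {
    if (is.null(names(perSample)))
        names(perSample) <- paste0("sample", seq_along(perSample))
    all <- do.call(rbind, lapply(names(perSample), function(s)
        cbind(perSample[[s]][, c("canonical", "L", "count")], sample = s)))
    agg <- do.call(rbind, lapply(split(all, all$canonical), function(d)
        data.frame(canonical = d$canonical[1L], L = d$L[1L],
                   count = sum(d$count), nSamples = length(unique(d$sample)),
                   stringsAsFactors = FALSE)))
    catalog <- nameHors(agg, scope = "aggregated",
                        chromPrefix = chromPrefix)
    names(catalog)[names(catalog) == "count"] <- "totalCount"
    mapping <- do.call(rbind, lapply(names(perSample), function(s) {
        p <- nameHors(perSample[[s]], scope = "per_sample")
        data.frame(sample = s, canonical = p$canonical,
                   sampleName = p$name,
                   name = catalog$name[match(p$canonical,
                                             catalog$canonical)],
                   stringsAsFactors = FALSE)
    }))
    rownames(mapping) <- NULL
    list(catalog = catalog, mapping = mapping)
}

#' Filter rare HORs
#'
#' A HOR is excluded when in every sample its n-number stays below 10\% of
#' the summed n-numbers of all HORs on its chromosome in that sample;
#' equivalently, it is retained when it reaches at least 10\% of its
#' chromosome's HOR content in at least one sample.
#'
#' @param n numeric matrix of n-numbers, HORs x samples (rownames = HOR
#'   ids).
#' @param chrom character vector: chromosome of each HOR (row).
#' @param minFraction the rare threshold (default 0.1).
#' @return logical vector per HOR: \code{TRUE} when retained.
#' @export
filterRareHors <- function(n, chrom, minFraction = 0.1) {
    stopifnot(nrow(n) == length(chrom))
    retained <- logical(nrow(n))
    for (j in seq_len(nrow(n))) {
        tot <- colSums(n[chrom == chrom[j], , drop = FALSE])
        retained[j] <- any(n[j, ] >= minFraction * tot)
    }
    names(retained) <- rownames(n)
    retained
}

#' Call variable HORs (v-HORs) from mean fold changes
#'
#' For each retained HOR the mean fold change of sample k is its n-number
#' divided by the HOR's mean n-number across samples (so the fold changes
#' average to 1), and the HOR is flagged variable when the standard
#' deviation of its fold changes exceeds 0.5.  Whether the population
#' (divide by n) or sample (divide by n-1) standard deviation is used is a
#' package configuration choice, reported in the output; the default is
#' population.
#'
#' @param n numeric matrix of n-numbers, HORs x samples (>= 2 samples).
#' @param retained optional logical/character selector of retained HORs
#'   (default: all rows).
#' @param sdType \code{"population"} or \code{"sample"}.
#' @param threshold dispersion threshold (default 0.5, strict \code{>}).
#' @return list with \code{table} (data.frame: hor, avgn, std, vhor,
#'   sdType) and \code{mf} (fold-change matrix).  HORs with zero mean are
#'   dropped with a warning.
#' @export
callVhors <- function(n, retained = NULL, sdType = c("population",
                      "sample"), threshold = 0.5) {
    sdType <- match.arg(sdType)
    if (ncol(n) < 2L) stop("need >= 2 samples")
    if (!is.null(retained)) n <- n[retained, , drop = FALSE]
    avg <- rowMeans(n)
    if (any(avg == 0)) {
        warning("dropping HOR(s) with zero mean n-number: ",
                paste(rownames(n)[avg == 0], collapse = ", "))
        n <- n[avg > 0, , drop = FALSE]
        avg <- avg[avg > 0]
    }
    mf <- n / avg
    std <- apply(mf, 1L, function(x) {
        if (sdType == "population") sqrt(mean((x - mean(x))^2)) else sd(x)
    })
    list(table = data.frame(hor = rownames(n), avgn = avg, std = std,
                            vhor = std > threshold, sdType = sdType,
                            row.names = NULL, stringsAsFactors = FALSE),
         mf = mf)
}

#' Cluster samples into centromere genotypes
#'
#' Hierarchical clustering (Ward linkage on z-scored n-numbers) of the
#' per-sample n-number vectors of one chromosome's variable HORs, with the
#' cluster count chosen between 2 and 3 by mean silhouette width.  With
#' three clusters, a cluster is called heterozygous (AB) when for every HOR
#' its cluster-mean n-number lies within \code{hetTol} (relative, default
#' 0.2) of the pairwise mean of the other two clusters' means; the
#' remaining clusters are then called AA and BB (AA = larger overall
#' n-number).  Cluster labels C0, C1, ... are assigned by decreasing
#' overall mean n-number, so memberships are invariant to sample order.
#'
#' @param n numeric matrix, samples x HORs (>= 4 samples), restricted to
#'   one chromosome's v-HORs.
#' @param populations optional factor/character of sample populations for
#'   per-population cluster frequencies.
#' @param kChoices candidate cluster counts (default \code{2:3}).
#' @param hetTol relative tolerance of the heterozygote test.
#' @return list with \code{cluster} (named C-labels per sample), \code{k},
#'   \code{zygosity} (named per cluster: AA/BB/AB or NA), \code{means}
#'   (cluster x HOR mean n-numbers), \code{silhouette}, and
#'   \code{populationFreq} when populations are given.
#' @export
clusterGenotypes <- function(n, populations = NULL, kChoices = 2:3,
                             hetTol = 0.2) {
    if (nrow(n) < 4L)
        stop("clustering refused: fewer than 4 samples")
    z <- scale(n)
    z[is.nan(z)] <- 0
    hc <- hclust(dist(z), method = "ward.D2")
    sil <- vapply(kChoices, function(k) {
        ct <- cutree(hc, k)
        if (length(unique(ct)) < 2L) return(-Inf)
        mean(cluster::silhouette(ct, dist(z))[, "sil_width"])
    }, 0)
    k <- kChoices[which.max(sil)]
    ct <- cutree(hc, k)
    means <- do.call(rbind, lapply(seq_len(k), function(g)
        colMeans(n[ct == g, , drop = FALSE])))
    ord <- order(-rowSums(means))
    relabel <- match(ct, ord) - 1L
    labels <- paste0("C", relabel)
    names(labels) <- rownames(n)
    means <- means[ord, , drop = FALSE]
    rownames(means) <- paste0("C", seq_len(k) - 1L)
    zyg <- setNames(rep(NA_character_, k), rownames(means))
    if (k == 3L) {
        eps <- hetTol * mean(n)
        pass <- vapply(1:3, function(h) {
            ab <- setdiff(1:3, h)
            pm <- (means[ab[1L], ] + means[ab[2L], ]) / 2
            all(ifelse(pm > 0, abs(means[h, ] - pm) / pm <= hetTol,
                       abs(means[h, ]) <= eps))
        }, TRUE)
        if (sum(pass) == 1L) {
            h <- which(pass)
            zyg[h] <- "AB"
            hom <- setdiff(1:3, h)
            # AA = larger overall n-number among the homozygous clusters
            if (sum(means[hom[1L], ]) >= sum(means[hom[2L], ])) {
                zyg[hom[1L]] <- "AA"; zyg[hom[2L]] <- "BB"
            } else {
                zyg[hom[1L]] <- "BB"; zyg[hom[2L]] <- "AA"
            }
        }
    } else if (k == 2L) {
        zyg[] <- c("AA", "BB")
    }
    out <- list(cluster = labels, k = k, zygosity = zyg, means = means,
                silhouette = setNames(sil, kChoices))
    if (!is.null(populations)) {
        tab <- table(populations, labels)
        out$populationFreq <- sweep(tab, 1L, rowSums(tab), "/")
    }
    out
}

#' Population comparison tests
#'
#' Two designs: a two-sided Wilcoxon rank sum test between two groups of
#' n-numbers, and a one-sided binomial test of an observed genotype count
#' against a fixed null proportion.
#'
#' @param x,y numeric vectors (Wilcoxon design).
#' @param k,n,p0 observed successes, trials and null proportion (binomial
#'   design).
#' @param design \code{"wilcoxon"} or \code{"binomial"}.
#' @param alternative for the binomial design, \code{"greater"} (p =
#'   P(X >= k)) or \code{"less"} (p = P(X <= k)).
#' @return the \code{htest} object.
#' @examples
#' comparePopulations(k = 10, n = 10, p0 = 0.5,
#'                    design = "binomial")$p.value  # 0.5^10
#' @export
comparePopulations <- function(x = NULL, y = NULL, k = NULL, n = NULL,
                               p0 = NULL,
                               design = c("wilcoxon", "binomial"),
                               alternative = "greater") {
    design <- match.arg(design)
    if (design == "wilcoxon") {
        if (!length(x) || !length(y))
            stop("argument error: both groups must be non-empty")
        wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                    correct = TRUE)
    } else {
        if (is.null(k) || is.null(n) || is.null(p0))
            stop("argument error: binomial design needs k, n, p0")
        binom.test(k, n, p0, alternative = alternative)
    }
}

#' Allele frequency from genotype calls or allele counts
#'
#' Counts each homozygote as two copies of its allele and each heterozygote
#' as one of each; alternatively takes raw allele counts directly.
#'
#' @param genotypes character vector of \code{"AA"}, \code{"AB"},
#'   \code{"BB"} calls (one per sample); or \code{NULL} when counts are
#'   given.
#' @param nAllele,nTotal direct allele counts: copies of the target allele
#'   and total allele count.
#' @param allele which allele to report (\code{"B"} or \code{"A"}).
#' @param percent report a percentage (default) or a fraction.
#' @return the allele frequency.
#' @examples
#' alleleFrequency(nAllele = 59, nTotal = 124)  # 47.58...
#' @export
alleleFrequency <- function(genotypes = NULL, nAllele = NULL,
                            nTotal = NULL, allele = "B", percent = TRUE) {
    if (!is.null(genotypes)) {
        nAllele <- sum(vapply(strsplit(genotypes, ""), function(g)
            sum(g == allele), 0L))
        nTotal <- 2L * length(genotypes)
    }
    if (is.null(nAllele) || is.null(nTotal) || nTotal <= 0)
        stop("argument error: supply genotypes or nAllele/nTotal")
    f <- nAllele / nTotal
    if (percent) 100 * f else f
}
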