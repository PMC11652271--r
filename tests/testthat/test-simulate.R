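test_that("generators are deterministic under a fixed seed", {
    spec <- simSpec(monomerCount = 4, nUnits = 20, seed = 61,
                    pattern = 1:4)
    expect_identical(as.character(genMonomers(spec)$monomers),
                     as.character(genMonomers(spec)$monomers))
    a1 <- genArray(spec); a2 <- genArray(spec)
    expect_identical(as.character(a1$sequence), as.character(a2$sequence))
    rspec <- simSpec(monomerCount = 1, coverage = 3,
                     readRange = c(2000, 4000), seed = 62)
    r1 <- genReads(list(x = a1$sequence), rspec)
    r2 <- genReads(list(x = a2$sequence), rspec)
    expect_identical(as.character(r1$reads), as.character(r2$reads))
})

test_that("monomer sets hit the requested cross-identity band", {
    spec <- simSpec(monomerCount = 6, crossIdentity = 0.75, seed = 63)
    gm <- genMonomers(spec)
    pid <- gm$pairwiseIdentity[upper.tri(gm$pairwiseIdentity)]
    expect_true(all(abs(pid - 0.75) <= 0.05))
    # single monomer: no pairwise constraint
    gm1 <- genMonomers(simSpec(monomerCount = 1, seed = 64))
    expect_length(gm1$monomers, 1L)
    expect_error(genMonomers(simSpec(crossIdentity = 0.2, seed = 1)),
                 "unreachable")
})

test_that("array construction follows the pattern arithmetic and truth tiles it", {
    spec <- simSpec(monomerCount = 5, pattern = 1:5, nUnits = 100,
                    mutationRate = 0, seed = 65)
    arr <- genArray(spec)
    expect_identical(length(arr$sequence), 100L * 5L * 171L)
    tu <- arr$truth$units
    expect_identical(tu$start[1], 1L)
    expect_identical(tu$end[nrow(tu)], length(arr$sequence))
    expect_true(all(tu$start[-1] == tu$end[-nrow(tu)] + 1L))
    # mutation 2% puts unit-vs-unit identity near 96%
    spec2 <- simSpec(monomerCount = 5, pattern = 1:5, nUnits = 30,
                     mutationRate = 0.02, seed = 66)
    arr2 <- genArray(spec2)
    tu2 <- arr2$truth$units
    us <- substring(as.character(arr2$sequence), tu2$start, tu2$end)
    id <- seqIdentity(us[seq(1, 29, 2)], us[seq(2, 30, 2)])
    expect_equal(mean(id), 0.96, tolerance = 0.012)
})

test_that("nesting events splice subpattern repeats into the stated units", {
    spec <- simSpec(monomerCount = 5, pattern = 1:5, nUnits = 10,
                    mutationRate = 0,
                    nesting = list(list(sub = 1L, count = 3L,
                                        units = 4:6)),
                    seed = 67)
    arr <- genArray(spec)
    tu <- arr$truth$units
    expect_identical(tu$expandedLength, rep(c(5L, 7L, 5L),
                                            c(3L, 3L, 4L)))
    expect_identical(tu$layout[4], "1-1-1-2-3-4-5")
    # htrm mining of the truth layout recovers a nested pattern there
    tok <- unlist(strsplit(tu$layout, "-"))
    ann <- htrmMine(tok)
    p <- horPatterns(ann)
    expect_true(any(p$L == 5L & grepl("1", p$nested)))
    expect_true(all(c(5L, 7L) %in% horUnits(ann)$expandedLength))
    expect_equal(sum(tokenCoverage(ann, tok)), 1)
})

test_that("read sampling matches coverage, length range and strand balance", {
    spec <- simSpec(monomerCount = 2, nUnits = 40, coverage = 20,
                    readRange = c(2000, 5000), seed = 68)
    arr <- genArray(spec)
    alen <- length(arr$sequence)
    rr <- genReads(list(a = arr$sequence), spec)
    w <- Biostrings::width(rr$reads)
    expect_true(all(w >= 2000 & w <= 5000))
    expect_equal(sum(w), 20 * alen, tolerance = 0.05)
    expect_equal(mean(rr$truth$strand == "-"), 0.5, tolerance = 0.01)
    # truth back-maps each read onto its source
    i <- 5L
    src <- as.character(Biostrings::subseq(arr$sequence,
        rr$truth$start[i], rr$truth$end[i]))
    got <- as.character(rr$reads[[i]])
    if (rr$truth$strand[i] == "-") src <- revComp(src)
    expect_identical(got, src)
})

test_that("diploid cohorts carry the planted genotype arithmetic", {
    spec <- simSpec(monomerCount = 3, pattern = 1:3, nUnits = 40,
                    mutationRate = 0, seed = 69)
    aA <- genArray(spec)
    aB <- genArray(simSpec(monomerCount = 3, pattern = c(1, 2, 3, 2, 3),
                           nUnits = 40, mutationRate = 0, seed = 70))
    coh <- genCohort(aA, aB, genotypes = c("AA", "AB", "BB"),
                     coverage = 8, seed = 71)
    keyA <- aA$truth$canonical; keyB <- aB$truth$canonical
    expect_identical(unname(coh$trueCounts[keyA, ]), c(80, 40, 0))
    expect_identical(unname(coh$trueCounts[keyB, ]), c(0, 40, 80))
    # observed counts follow the same proportions
    expect_gt(coh$counts[keyA, 1], coh$counts[keyA, 2])
    expect_identical(unname(coh$counts[keyA, 3]), 0)
    # determinism
    coh2 <- genCohort(aA, aB, genotypes = c("AA", "AB", "BB"),
                      coverage = 8, seed = 71)
    expect_identical(coh2$counts, coh$counts)
})

test_that("cohort genotype draws follow the planted frequencies", {
    spec <- simSpec(monomerCount = 2, pattern = 1:2, nUnits = 30,
                    mutationRate = 0, seed = 72)
    aA <- genArray(spec)
    aB <- genArray(simSpec(monomerCount = 2, pattern = c(1, 2, 2),
                           nUnits = 30, mutationRate = 0, seed = 73))
    coh <- genCohort(aA, aB, nSamples = 60, coverage = 4, seed = 74)
    freq <- table(coh$samples$genotype) / 60
    expect_equal(unname(freq["AB"]), 0.5, tolerance = 0.2)
})

test_that("the full pipeline recovers a planted pattern end to end", {
    spec <- simSpec(monomerCount = 5, pattern = 1:5, nUnits = 60,
                    mutationRate = 0.01, crossIdentity = 0.7, seed = 75)
    gm <- genMonomers(spec)
    arr <- genArray(spec, gm$monomers)
    res <- annotateSequence(arr$sequence, gm$template, gm$monomers)
    p <- horPatterns(res$annotation)
    top <- p[which.max(p$count), ]
    expect_identical(top$canonical, arr$truth$canonical)
    expect_equal(top$count, 60L, tolerance = 0.05)
    expect_gte(unname(tokenCoverage(res$annotation,
                                    res$monomers)["inUnit"]), 0.95)
})
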