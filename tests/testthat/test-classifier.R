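test_that("canonical 5-mer collapse yields exactly 512 features", {
    ck <- canonicalKmers()
    expect_identical(nrow(ck), 1024L)
    expect_identical(length(unique(ck$canonical)), 512L)
    # no palindromes at odd k
    expect_false(any(ck$kmer == ck$revcomp))
    expect_identical(ncol(kmerFeatures(c(r = strrep("ACGT", 10)))), 512L)
})

test_that("featurization counts windows, normalizes by length and skips N windows", {
    f <- kmerFeatures(c(r = "AAAAAA"))
    expect_equal(unname(f[1, "AAAAA"]), 2 / 6)
    expect_equal(sum(f[1, ] > 0), 1L)
    # an N voids the windows containing it
    f2 <- kmerFeatures(c(r = "AANAAAAA"))
    expect_equal(unname(f2[1, "AAAAA"]), 1 / 8)
    expect_warning(f3 <- kmerFeatures(c(a = "ACG", b = strrep("A", 10))),
                   "skipped")
    expect_identical(rownames(f3), "b")
})

test_that("feature vectors are exactly strand-invariant", {
    set.seed(31)
    for (i in 1:20) {
        x <- rndDna(sample(50:500, 1))
        expect_identical(kmerFeatures(c(r = x))[1, ],
                         kmerFeatures(c(r = revComp(x)))[1, ])
    }
})

test_that("training-read simulation honors length range, balance and strand split", {
    set.seed(32)
    arrs <- lapply(1:2, function(i) genArray(simSpec(monomerCount = 3,
        pattern = 1:3, nUnits = 60, seed = 40 + i)))
    asm <- genAssembly(list(chr1 = arrs[[1]]$sequence,
                            chr2 = arrs[[2]]$sequence),
                       flank = 30000, seed = 6)
    tr <- simulateTrainingReads(asm$assembly, asm$satellites, seed = 2,
                                readsPerChrom = 5, rounds = 4,
                                readRange = c(10000, 25000))
    lab <- tr$labels
    pos <- lab$stage1 == "Alpha"
    expect_identical(sum(pos), 2L * 5L * 4L)
    expect_identical(sum(!pos), sum(pos))
    expect_true(all(table(lab$chromosome[pos]) == 20L))
    w <- Biostrings::width(tr$reads)
    expect_true(all(w >= 10000 & w <= 25000))
    expect_equal(mean(lab$strand[pos] == "-"), 0.5, tolerance = 0.051)
    # negatives never overlap the satellite intervals: verify by content --
    # a negative read is flank DNA, so it cannot contain a monomer verbatim
    mono <- as.character(genMonomers(simSpec(monomerCount = 3,
        seed = 41))$monomers[[1]])
    neg <- as.character(tr$reads[!pos])
    expect_false(any(vapply(neg[1:5], function(s) grepl(mono, s,
        fixed = TRUE), TRUE)))
})

test_that("a chromosome with too-short satellite array is skipped with a warning", {
    set.seed(33)
    asm <- genAssembly(list(chrA = rndDna(60000), chrB = rndDna(5000)),
                       flank = 15000, seed = 7)
    expect_warning(tr <- simulateTrainingReads(asm$assembly,
        asm$satellites, seed = 1, readsPerChrom = 2, rounds = 2),
        "chrB")
    expect_false("chrB" %in% tr$labels$chromosome)
})

test_that("training retains components above the variance threshold and separates separable data", {
    set.seed(34)
    arrs <- lapply(1:2, function(i) genArray(simSpec(monomerCount = 3,
        pattern = 1:3, nUnits = 60, crossIdentity = 0.7,
        seed = 50 + i)))
    asm <- genAssembly(list(chr1 = arrs[[1]]$sequence,
                            chr2 = arrs[[2]]$sequence),
                       flank = 30000, seed = 8)
    tr <- simulateTrainingReads(asm$assembly, asm$satellites, seed = 3,
                                readsPerChrom = 4, rounds = 5)
    models <- trainTwoStage(tr$reads, tr$labels, seed = 4)
    expect_gt(models$stage1@varExplained, 0.95)
    expect_gt(models$stage2@varExplained, 0.95)
    # memorization: training reads classify back to their own labels
    pred <- classifyReads(tr$reads, models)
    expect_identical(pred$stage1, tr$labels$stage1)
    alpha <- tr$labels$stage1 == "Alpha"
    expect_identical(pred$chromosome[alpha], tr$labels$chromosome[alpha])
})

test_that("training errors name a class with fewer than 2 examples", {
    reads <- Biostrings::DNAStringSet(setNames(
        c(strrep("ACGTT", 20), strrep("ACGTT", 21), strrep("TTGCA", 20)),
        c("a", "b", "c")))
    labels <- data.frame(stage1 = c("Alpha", "Alpha", "Non-Alpha"),
                         chromosome = c("chr1", "chr1", NA))
    expect_error(trainTwoStage(reads, labels, seed = 1), "Non-Alpha")
})

test_that("classification is strand-invariant and deterministic", {
    set.seed(36)
    arrs <- lapply(1:2, function(i) genArray(simSpec(monomerCount = 3,
        pattern = 1:3, nUnits = 60, seed = 60 + i)))
    asm <- genAssembly(list(chr1 = arrs[[1]]$sequence,
                            chr2 = arrs[[2]]$sequence),
                       flank = 30000, seed = 9)
    tr <- simulateTrainingReads(asm$assembly, asm$satellites, seed = 5,
                                readsPerChrom = 3, rounds = 4)
    models <- trainTwoStage(tr$reads, tr$labels, seed = 6)
    sub <- tr$reads[1:10]
    p1 <- classifyReads(sub, models)
    p2 <- classifyReads(Biostrings::reverseComplement(sub), models)
    expect_identical(p1$stage1, p2$stage1)
    expect_identical(p1$chromosome, p2$chromosome)
    expect_identical(p1, classifyReads(sub, models))
    # random uniform DNA is non-alpha
    set.seed(37)
    rnd <- Biostrings::DNAStringSet(setNames(
        vapply(1:20, function(i) rndDna(12000), ""), paste0("r", 1:20)))
    expect_gte(mean(classifyReads(rnd, models)$stage1 == "Non-Alpha"),
               0.99)
})

test_that("feature-dimension mismatch raises a model error", {
    set.seed(38)
    arrs <- lapply(1:2, function(i) genArray(simSpec(monomerCount = 2,
        pattern = 1:2, nUnits = 50, seed = 70 + i)))
    asm <- genAssembly(list(chr1 = arrs[[1]]$sequence,
                            chr2 = arrs[[2]]$sequence),
                       flank = 25000, seed = 10)
    tr <- simulateTrainingReads(asm$assembly, asm$satellites, seed = 7,
                                readsPerChrom = 3, rounds = 3)
    models <- trainTwoStage(tr$reads, tr$labels, seed = 8)
    f <- kmerFeatures(tr$reads[1:2])[, 1:100]
    expect_error(centrosat:::.predictStage(models$stage1, f),
                 "dimension mismatch")
})
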