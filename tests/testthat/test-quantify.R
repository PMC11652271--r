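test_that("n-numbers and estimated sizes are counts and lengths over coverage", {
    q <- quantifySample(c(R1L5 = 100), coverage = 20,
                        readLength = c(chr5 = 60e6))
    expect_equal(unname(q$n), 5)
    expect_equal(unname(q$s), 3e6)
    # exact 1/coverage scaling: doubling both leaves quantities fixed
    q2 <- quantifySample(c(R1L5 = 200), coverage = 40,
                         readLength = c(chr5 = 120e6))
    expect_identical(q2$n, q$n)
    expect_identical(q2$s, q$s)
    expect_error(quantifySample(c(a = 1), coverage = 0), "argument error")
})

test_that("aggregation merges canonical patterns across samples and conserves counts", {
    pA <- data.frame(canonical = c("1-2-3-4", "1-2"), L = c(4L, 2L),
                     count = c(10L, 3L))
    pB <- data.frame(canonical = c("1-2-3-4", "1-3"), L = c(4L, 2L),
                     count = c(7L, 9L))
    pC <- data.frame(canonical = "1-2-3-4", L = 4L, count = 5L)
    agg <- aggregateHors(list(A = pA, B = pB, C = pC), chromPrefix = "5")
    cat5 <- agg$catalog
    expect_identical(nrow(cat5), 3L)
    main <- cat5[cat5$canonical == "1-2-3-4", ]
    expect_identical(main$nSamples, 3L)
    expect_identical(main$totalCount, 22L)
    expect_identical(main$name, "5_M1L4")
    expect_identical(sum(cat5$totalCount), sum(pA$count, pB$count,
                                               pC$count))
    # the same canonical unit maps to the same M-name from every sample
    m <- agg$mapping
    expect_identical(unique(m$name[m$canonical == "1-2-3-4"]), "5_M1L4")
    expect_identical(m$sampleName[m$sample == "B" &
                                  m$canonical == "1-3"], "R1L2")
})

test_that("rare-HOR exclusion implements the 10%-of-chromosome rule", {
    n <- rbind(h1 = c(9.5, 9.5, 9.5), h2 = c(0.5, 0.5, 0.5))
    chrom <- c("chr1", "chr1")
    expect_identical(unname(filterRareHors(n, chrom)), c(TRUE, FALSE))
    # a HOR sitting exactly at 10% of its chromosome total is retained
    expect_true(all(filterRareHors(rbind(a = c(9), b = c(1)),
                                   c("chr1", "chr1"))))
    # 5% everywhere but 30% once: retained by the existential clause
    n <- rbind(a = c(95, 70), b = c(5, 30))
    expect_true(filterRareHors(n, c("chr2", "chr2"))["b"])
    # a chromosome's only HOR is always retained
    n <- rbind(solo = c(0.4, 0.2))
    expect_true(filterRareHors(n, "chr3")["solo"])
})

test_that("rare-HOR filter equals brute-force evaluation on random tables", {
    set.seed(41)
    for (i in 1:20) {
        nh <- sample(2:5, 1); ns <- sample(2:10, 1)
        n <- matrix(round(runif(nh * ns, 0, 10), 2), nh, ns,
                    dimnames = list(paste0("h", 1:nh), NULL))
        chrom <- sample(c("c1", "c2"), nh, replace = TRUE)
        got <- filterRareHors(n, chrom)
        want <- vapply(seq_len(nh), function(j) {
            excl <- TRUE
            for (k in seq_len(ns)) {
                tot <- sum(n[chrom == chrom[j], k])
                if (n[j, k] >= 0.1 * tot) excl <- FALSE
            }
            !excl
        }, TRUE)
        expect_identical(unname(got), want)
    }
})

test_that("v-HOR calling computes fold changes with mean 1 and flags std > 0.5", {
    n <- rbind(flat = c(4, 4, 4, 4), var = c(1, 1, 9, 9))
    out <- callVhors(n)
    expect_equal(unname(rowMeans(out$mf)), c(1, 1), tolerance = 1e-12)
    expect_false(out$table$vhor[out$table$hor == "flat"])
    expect_identical(out$table$std[out$table$hor == "flat"], 0)
    expect_true(out$table$vhor[out$table$hor == "var"])
    # scale invariance
    out2 <- callVhors(n * 7)
    expect_equal(out2$table$std, out$table$std)
    expect_identical(out2$mf, out$mf)
})

test_that("the population/sample std choice decides the boundary case (1, 3)", {
    n <- rbind(h = c(1, 3))
    pop <- callVhors(n, sdType = "population")
    expect_equal(pop$table$std, 0.5)
    expect_false(pop$table$vhor)          # strict > 0.5
    smp <- callVhors(n, sdType = "sample")
    expect_equal(smp$table$std, sqrt(2) / 2, tolerance = 1e-12)
    expect_true(smp$table$vhor)
    expect_equal(unname(pop$mf[1, ]), c(0.5, 1.5))
})

test_that("zero-mean HORs are dropped with a warning", {
    n <- rbind(a = c(1, 2), z = c(0, 0))
    expect_warning(out <- callVhors(n), "zero mean")
    expect_identical(out$table$hor, "a")
})

test_that("genotype clustering recovers planted AA/BB/AB with the pairwise-mean test", {
    set.seed(42)
    mkS <- function(mu) pmax(0, mu + rnorm(2, 0, 0.15))
    n <- rbind(t(replicate(10, mkS(c(8, 0)))),    # AA
               t(replicate(10, mkS(c(0, 6)))),    # BB
               t(replicate(10, mkS(c(4, 3)))))    # AB
    rownames(n) <- paste0("s", 1:30)
    colnames(n) <- c("hA", "hB")
    truth <- rep(c("AA", "BB", "AB"), each = 10)
    gc <- clusterGenotypes(n, populations = rep(c("P1", "P2"), 15))
    expect_identical(gc$k, 3L)
    called <- gc$zygosity[gc$cluster]
    expect_gte(mean(called == truth), 0.95)
    # the AB cluster means sit at the pairwise mean of AA and BB
    ab <- names(gc$zygosity)[gc$zygosity == "AB"]
    hom <- setdiff(rownames(gc$means), ab)
    pm <- colMeans(gc$means[hom, ])
    expect_true(all(abs(gc$means[ab, ] - pm) / pm <= 0.2))
    expect_identical(dim(gc$populationFreq), c(2L, 3L))
})

test_that("a two-genotype cohort clusters into 2 groups with no AB call", {
    set.seed(43)
    n <- rbind(t(replicate(8, pmax(0, c(8, 0) + rnorm(2, 0, 0.2)))),
               t(replicate(8, pmax(0, c(0, 6) + rnorm(2, 0, 0.2)))))
    rownames(n) <- paste0("s", 1:16)
    gc <- clusterGenotypes(n)
    expect_identical(gc$k, 2L)
    expect_false(any(gc$zygosity == "AB", na.rm = TRUE))
})

test_that("clustering memberships are invariant to sample order and need >= 4 samples", {
    set.seed(44)
    n <- rbind(t(replicate(6, c(8, 0) + rnorm(2, 0, 0.2))),
               t(replicate(6, c(0, 6) + rnorm(2, 0, 0.2))),
               t(replicate(6, c(4, 3) + rnorm(2, 0, 0.2))))
    rownames(n) <- paste0("s", 1:18)
    gc1 <- clusterGenotypes(n)
    perm <- sample(nrow(n))
    gc2 <- clusterGenotypes(n[perm, ])
    expect_identical(gc2$cluster[rownames(n)], gc1$cluster)
    expect_error(clusterGenotypes(n[1:3, ]), "fewer than 4")
})

test_that("population tests match their closed forms", {
    x <- c(1, 2, 3, 4, 5)
    expect_equal(comparePopulations(x, x)$p.value, 1.0)
    p <- comparePopulations(k = 10, n = 10, p0 = 0.5,
                            design = "binomial")$p.value
    expect_equal(p, 0.5^10)
    expect_error(comparePopulations(numeric(0), x), "argument error")
})

test_that("one-sided binomial p equals direct summation of the binomial mass", {
    set.seed(45)
    for (i in 1:20) {
        n <- sample(5:60, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05,
                                                               0.95)
        pg <- comparePopulations(k = k, n = n, p0 = p0,
                                 design = "binomial",
                                 alternative = "greater")$p.value
        expect_equal(pg, sum(choose(n, k:n) * p0^(k:n) *
                                 (1 - p0)^(n - k:n)), tolerance = 1e-12)
        pl <- comparePopulations(k = k, n = n, p0 = p0,
                                 design = "binomial",
                                 alternative = "less")$p.value
        expect_equal(pl, sum(choose(n, 0:k) * p0^(0:k) *
                                 (1 - p0)^(n - 0:k)), tolerance = 1e-12)
    }
})

test_that("allele frequencies count homozygotes twice and heterozygotes once", {
    expect_equal(alleleFrequency(nAllele = 59, nTotal = 124),
                 100 * 59 / 124)
    g <- c(rep("BB", 10), rep("AB", 39), rep("AA", 13))
    expect_equal(alleleFrequency(g), 100 * (2 * 10 + 39) / 124)
    expect_equal(alleleFrequency(g, allele = "A", percent = FALSE),
                 (2 * 13 + 39) / 124)
})
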