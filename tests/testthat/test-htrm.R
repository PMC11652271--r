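test_that("pattern canonicalization groups shifted and reversed units", {
    canon <- canonicalizePattern(c(1, 2, 3, 4))
    for (p in list(c(4, 1, 2, 3), c(3, 4, 1, 2), c(2, 3, 4, 1),
                   c(4, 3, 2, 1)))
        expect_identical(canonicalizePattern(p), canon)
    expect_identical(canonicalizePattern(7L), 7L)
})

test_that("canonicalization is invariant under rotation/reversal for random units", {
    set.seed(2)
    for (i in 1:100) {
        L <- sample(2:8, 1)
        x <- sample(1:9, L, replace = TRUE)
        r <- sample(L, 1) - 1L
        rot <- if (r == 0) x else c(x[(r + 1):L], x[1:r])
        expect_identical(canonicalizePattern(rot), canonicalizePattern(x))
        expect_identical(canonicalizePattern(rev(x)),
                         canonicalizePattern(x))
    }
})

test_that("canonicalization partitions all short units over 4 monomer ids", {
    # exhaustive: x ~ y under rotation/reversal <=> same canonical form
    # rotation-by-one and reversal generate the whole rotation/reversal
    # orbit, so canonical invariance under both generators proves it for
    # every orbit member
    rotations <- function(x) {
        L <- length(x)
        lapply(seq_len(L) - 1L, function(r)
            if (r == 0) x else c(x[(r + 1):L], x[1:r]))
    }
    fails <- 0L
    for (L in 1:6) {
        grid <- as.matrix(expand.grid(rep(list(1:4), L)))
        for (i in seq_len(nrow(grid))) {
            x <- as.integer(grid[i, ])
            cx <- canonicalizePattern(x)
            rot1 <- if (L == 1) x else c(x[-1], x[1])
            if (!identical(canonicalizePattern(rot1), cx) ||
                !identical(canonicalizePattern(rev(x)), cx))
                fails <- fails + 1L
            # the canonical form is itself a member of the orbit
            orbit <- c(rotations(x), rotations(rev(x)))
            if (!any(vapply(orbit, identical, TRUE, y = cx)))
                fails <- fails + 1L
        }
    }
    expect_identical(fails, 0L)
})

test_that("compressed-pattern expansion reproduces stated monomer counts", {
    expect_identical(expandPattern("(1-2)x4-5-6-4-3")$monomerLength, 12L)
    expect_identical(
        expandPattern("3-5-6-8-1-2-3-4-(3-5-6-7)x2")$monomerLength, 16L)
    expect_identical(
        expandPattern("3-5-6-8-1-2-3-4-(3-5-6-7)x3")$monomerLength, 20L)
    expect_identical(expandPattern("(1-2)x3-5-6-4-3")$expanded,
                     c(1L, 2L, 1L, 2L, 1L, 2L, 5L, 6L, 4L, 3L))
    expect_identical(
        expandPattern(list(1L, list(sub = c(2L, 3L), count = 2L)))$expanded,
        c(1L, 2L, 3L, 2L, 3L))
    expect_error(expandPattern(list(list(sub = 1L, count = 0L))),
                 "argument error")
})

test_that("tandem run finder reports maximal runs with exact counts", {
    r <- findTandemRuns(c("1", "2", "1", "2", "1", "2"))
    expect_identical(r$start, 1L)
    expect_identical(r$unit, "1-2")
    expect_identical(r$count, 3L)

    r <- findTandemRuns(c("1", "1", "1"), maxUnit = 1L)
    expect_identical(r[, c("start", "unitLength", "count")],
                     data.frame(start = 1L, unitLength = 1L, count = 3L))

    # unknown tokens terminate runs
    r <- findTandemRuns(c("1", "2", "unknown", "1", "2"))
    expect_identical(nrow(r), 0L)
})

test_that("tandem run finder equals the brute-force enumeration on random strings", {
    set.seed(13)
    for (i in 1:30) {
        n <- sample(10:60, 1)
        tok <- as.character(sample(1:3, n, replace = TRUE))
        tok[sample(n, n %/% 12)] <- "unknown"
        got <- findTandemRuns(tok, maxUnit = 10L)
        want <- bruteTandemRuns(tok, maxUnit = 10L)
        rownames(got) <- rownames(want) <- NULL
        expect_identical(got, want)
    }
})

test_that("mining a homogeneous landscape yields one pattern with full coverage", {
    tok <- as.character(rep(1:5, 20))
    ann <- htrmMine(tok)
    p <- horPatterns(ann)
    expect_identical(nrow(p), 1L)
    expect_identical(p$L, 5L)
    expect_identical(p$count, 20L)
    expect_identical(p$nested, "")
    expect_identical(nrow(horUnits(ann)), 20L)
    cov <- tokenCoverage(ann, tok)
    expect_equal(unname(cov["inUnit"]), 1)
    expect_equal(sum(cov), 1)
})

test_that("a tandem-duplicated monomer is mined as a locally nested subunit", {
    tok <- as.character(rep(c(1, 1, 2, 3, 4, 5), 10))
    ann <- htrmMine(tok)
    p <- horPatterns(ann)
    outer <- p[p$L == 5L, ]
    expect_identical(nrow(outer), 1L)
    expect_identical(outer$nested, "1")
    expect_identical(outer$count, 10L)
    # the local monomer-1 expansion is a pattern in its own right
    inner <- p[p$L == 1L, ]
    expect_identical(inner$canonical, "1")
    expect_identical(inner$count, 20L)
    u <- horUnits(ann)
    expect_identical(unique(u$expandedLength), 6L)
    expect_equal(unname(tokenCoverage(ann, tok)["inUnit"]), 1)
})

test_that("units with different nesting levels collapse to one pattern with distinct expanded lengths", {
    # 10-mor and 12-mor variants of the same 6-monomer pattern
    u10 <- expandPattern("(1-2)x3-5-6-4-3")$expanded
    u12 <- expandPattern("(1-2)x4-5-6-4-3")$expanded
    tok <- as.character(c(rep(u10, 4), rep(u12, 3), rep(u10, 3)))
    ann <- htrmMine(tok)
    p <- horPatterns(ann)
    outer <- p[p$L == 6L, ]
    expect_identical(outer$canonical,
                     paste(canonicalizePattern(c(1, 2, 5, 6, 4, 3)),
                           collapse = "-"))
    expect_identical(outer$count, 10L)
    u <- horUnits(ann)
    expect_identical(sort(unique(u$expandedLength)), c(10L, 12L))
    expect_identical(sum(u$expandedLength[u$canonical ==
                                          outer$canonical]), 106L)
})

test_that("annotated unit intervals are non-overlapping, ordered, and cover the mined tokens", {
    set.seed(19)
    for (i in 1:10) {
        L <- sample(2:6, 1)
        pat <- sample(1:6, L)
        reps <- sample(5:15, 1)
        tok <- as.character(rep(pat, reps))
        noise <- sample(length(tok), max(0, length(tok) %/% 50))
        tok[noise] <- "unknown"
        ann <- htrmMine(tok)
        u <- horUnits(ann)
        if (nrow(u) > 1) {
            expect_true(all(diff(u$start) > 0))
            expect_true(all(u$start[-1] > u$end[-nrow(u)]))
        }
        expect_equal(sum(tokenCoverage(ann, tok)), 1)
    }
})

test_that("HOR naming sorts by repeat count with documented tie-breaks", {
    p <- data.frame(canonical = c("1-2-3-4-5", "1", "2-3"),
                    L = c(5L, 1L, 2L), count = c(20L, 4L, 4L))
    named <- nameHors(p)
    expect_identical(named$name, c("R1L5", "R2L1", "R3L2"))
    named <- nameHors(p, scope = "aggregated", chromPrefix = "5")
    expect_identical(named$name[1], "5_M1L5")
    # equal counts: smaller L wins the lower rank
    expect_lt(named$rank[named$canonical == "1"],
              named$rank[named$canonical == "2-3"])
})
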