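# Independent oracles used to cross-check the package implementations.

# full quadratic dynamic-programming Levenshtein table
rEditDistance <- function(a, b) {
    a <- strsplit(a, "")[[1]]
    b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    D <- matrix(0L, n + 1L, m + 1L)
    D[, 1L] <- 0:n
    D[1L, ] <- 0:m
    for (i in seq_len(n))
        for (j in seq_len(m))
            D[i + 1L, j + 1L] <- min(D[i, j] + (a[i] != b[j]),
                                     D[i, j + 1L] + 1L,
                                     D[i + 1L, j] + 1L)
    D[n + 1L, m + 1L]
}

# brute-force maximal tandem runs: for every period u and start s, extend the
# lag-u equality to the right as far as it holds; report left-maximal
# stretches of length >= u with count = floor(len/u) + 1
bruteTandemRuns <- function(tokens, maxUnit = 40L) {
    n <- length(tokens)
    eqat <- function(i, u) {
        i >= 1L && i + u <= n && !is.na(tokens[i]) &&
            tokens[i] != "unknown" && tokens[i + u] != "unknown" &&
            tokens[i] == tokens[i + u]
    }
    out <- list()
    for (u in seq_len(min(maxUnit, n %/% 2L))) {
        s <- 1L
        while (s + u <= n) {
            if (eqat(s, u) && !eqat(s - 1L, u)) {
                len <- 0L
                while (eqat(s + len, u)) len <- len + 1L
                if (len >= u)
                    out[[length(out) + 1L]] <- data.frame(
                        start = s, unitLength = u,
                        count = len %/% u + 1L,
                        unit = paste(tokens[s:(s + u - 1L)],
                                     collapse = "-"))
            }
            s <- s + 1L
        }
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(start = integer(0), unitLength = integer(0),
                          count = integer(0), unit = character(0))
    res[order(res$start, res$unitLength), , drop = FALSE]
}

# brute-force exact-match pair counts per sliding window
bruteExpansionTrack <- function(seqs, window = 10L, slide = 1L) {
    starts <- seq(1L, length(seqs) - window + 1L, by = slide)
    vapply(starts, function(i) {
        w <- seqs[i:(i + window - 1L)]
        cnt <- 0L
        for (a in seq_len(window - 1L))
            for (b in (a + 1L):window)
                if (w[a] == w[b]) cnt <- cnt + 1L
        cnt
    }, 0L)
}

rndDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                   replace = TRUE), collapse = "")

mutateDna <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]),
                                   1L)
    paste(ch, collapse = "")
}
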