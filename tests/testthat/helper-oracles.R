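# Independent R oracles used by the property and acceptance tests.
# These deliberately re-derive results with straightforward dynamic
# programming / exhaustive enumeration, independent of the package's
# C++ code paths.

SCORE_W <- 8192L

# Full Smith-Waterman DP (match +1, mismatch/indel -1) maximizing the same
# documented objective as the package aligner: score first, then fewest
# edited bases (combined additive key), with diag > up > left preference
# on ties and the first row-major maximum as alignment end.
r_local_align <- function(q, r) {
    qv <- strsplit(q, "")[[1]]
    rv <- strsplit(r, "")[[1]]
    n <- length(qv)
    m <- length(rv)
    H <- matrix(0L, n + 1L, m + 1L)
    D <- matrix(0L, n + 1L, m + 1L)
    best <- 0L; bi <- 0L; bj <- 0L
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            d <- H[i, j] + if (qv[i] == rv[j]) SCORE_W else -(SCORE_W + 1L)
            u <- H[i, j + 1L] - (SCORE_W + 1L)
            l <- H[i + 1L, j] - (SCORE_W + 1L)
            v <- d; dd <- 1L
            if (u > v) { v <- u; dd <- 2L }
            if (l > v) { v <- l; dd <- 3L }
            if (v <= 0L) { v <- 0L; dd <- 0L }
            H[i + 1L, j + 1L] <- v
            D[i + 1L, j + 1L] <- dd
            if (v > best) { best <- v; bi <- i; bj <- j }
        }
    }
    if (best <= 0L) return(NULL)
    i <- bi; j <- bj
    matches <- 0L; mism <- 0L; ins <- 0L; del <- 0L
    while (i > 0L && j > 0L) {
        dd <- D[i + 1L, j + 1L]
        if (dd == 0L) break
        if (dd == 1L) {
            if (qv[i] == rv[j]) matches <- matches + 1L else mism <- mism + 1L
            i <- i - 1L; j <- j - 1L
        } else if (dd == 2L) { ins <- ins + 1L; i <- i - 1L }
        else { del <- del + 1L; j <- j - 1L }
    }
    list(score = matches - mism - ins - del, matches = matches,
         mismatches = mism, inserted_bases = ins, deleted_bases = del,
         query_aligned_bases = matches + mism + ins,
         q_start = i + 1L, q_end = bi, r_start = j + 1L, r_end = bj)
}

# do two sequences share any exact k-mer? (enumeration, no hashing)
r_share_kmer <- function(a, b, k) {
    if (nchar(a) < k || nchar(b) < k) return(FALSE)
    ka <- substring(a, seq_len(nchar(a) - k + 1L),
                    seq_len(nchar(a) - k + 1L) + k - 1L)
    kb <- substring(b, seq_len(nchar(b) - k + 1L),
                    seq_len(nchar(b) - k + 1L) + k - 1L)
    length(intersect(ka, kb)) > 0L
}

# LCS length with a vectorized row update (cummax trick)
r_lcs <- function(av, bv) {
    m <- length(bv)
    prev <- integer(m + 1L)
    for (i in seq_along(av)) {
        cand <- ifelse(av[i] == bv, prev[-(m + 1L)] + 1L, 0L)
        prev <- c(0L, cummax(pmax(prev[-1L], cand)))
    }
    prev[m + 1L]
}

# exhaustive rotation-enumeration cyclic identity (both orientations)
r_circular_identity <- function(a, b) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    best <- 0L
    rots <- function(x) lapply(seq_along(x) - 1L, function(r)
        if (r == 0L) x else c(x[-seq_len(r)], x[seq_len(r)]))
    for (rb in rots(bv)) best <- max(best, r_lcs(av, rb))
    for (ra in rots(av)) best <- max(best, r_lcs(bv, ra))
    best / max(length(av), length(bv))
}

# naive double-loop confusion-count oracle
r_confusion <- function(assembled_sets, verified_sets) {
    res <- list()
    for (s in names(assembled_sets)) {
        tp <- 0L; fp <- 0L
        for (key in unique(assembled_sets[[s]])) {
            if (key %in% verified_sets[[s]]) tp <- tp + 1L else fp <- fp + 1L
        }
        fn <- 0L
        others <- character(0)
        for (t in names(verified_sets))
            if (t != s) others <- c(others, verified_sets[[t]])
        for (key in unique(others))
            if (!(key %in% assembled_sets[[s]])) fn <- fn + 1L
        res[[s]] <- data.frame(strategy = s, tp = tp, fp = fp, fn = fn)
    }
    do.call(rbind, res)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# mutate a string with substitutions only (rate per base)
mutate_seq <- function(s, rate) {
    b <- strsplit(s, "")[[1]]
    hit <- runif(length(b)) < rate
    if (any(hit))
        b[hit] <- vapply(b[hit], function(x)
            sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
    paste(b, collapse = "")
}
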