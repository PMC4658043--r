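# Independent oracles used across the suite. None of these call package
# internals beyond exported constructors; each recomputes the target quantity
# from first principles.

# --- local alignment oracle -------------------------------------------------
# Affine-gap Smith-Waterman DP over composite-encoded (score, matches, length)
# triples: composite = score*1e6 + matches*1e3 + (999 - length), so ordinary
# numeric max() performs the lexicographic comparison (score, then matches,
# then shorter alignment). A gap of length L costs gapOpen + L * gapExt.
swOracle <- function(a, b, sub, gapOpen = 11, gapExt = 1) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    n <- length(av); m <- length(bv)
    NEG <- -1e15
    EMPTY <- 999          # zero score, zero matches, zero length
    open1 <- (gapOpen + gapExt) * 1e6 + 1
    ext1 <- gapExt * 1e6 + 1
    M <- X <- Y <- matrix(NEG, n + 1, m + 1)
    best <- EMPTY
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            step <- sub[av[i], bv[j]] * 1e6 + (av[i] == bv[j]) * 1e3 - 1
            M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j], EMPTY) + step
            if (M[i + 1, j + 1] < 0) M[i + 1, j + 1] <- NEG
            X[i + 1, j + 1] <- max(M[i, j + 1] - open1, X[i, j + 1] - ext1)
            Y[i + 1, j + 1] <- max(M[i + 1, j] - open1, Y[i + 1, j] - ext1)
            if (M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
        }
    }
    score <- best %/% 1e6
    rem <- best %% 1e6
    matches <- rem %/% 1e3
    len <- 999 - rem %% 1e3
    list(score = score, matches = matches, length = len,
         identity = if (len > 0) matches / len else 0)
}

randomAA <- function(n) paste(sample(aminoAcids(), n, TRUE), collapse = "")

# --- motif oracle -----------------------------------------------------------
# position-by-position brute force over every start offset
bruteMotifScan <- function(seq, pattern) {
    s <- strsplit(toupper(seq), "")[[1]]
    els <- pattern@elements
    L <- length(els)
    starts <- integer(0)
    if (length(s) < L) return(starts)
    for (at in seq_len(length(s) - L + 1L)) {
        ok <- TRUE
        for (p in seq_len(L)) {
            e <- els[[p]]
            if (length(e) > 0L && !(s[at + p - 1L] %in% e)) { ok <- FALSE; break }
        }
        if (ok) starts <- c(starts, at)
    }
    starts
}

# random degenerate pattern over a tiny alphabet so matches are likely
randomPattern <- function(len = 6L, alphabet = c("A", "C", "D", "E")) {
    els <- lapply(seq_len(len), function(i) {
        kind <- sample(3, 1)
        if (kind == 1) character(0)                     # wildcard
        else if (kind == 2) sample(alphabet, 1)          # fixed
        else sort(sample(alphabet, 2))                   # alternatives
    })
    new("MotifPattern", elements = els, label = "rand")
}

# --- hypergeometric oracle --------------------------------------------------
# exhaustive enumeration of all C(N, n) equally likely draws from an urn with
# K successes; returns P[X >= k]
hyperOracle <- function(k, K, n, N) {
    if (n == 0) return(as.numeric(k <= 0))
    draws <- combn(N, n)
    hits <- colSums(draws <= K)
    mean(hits >= k)
}

# --- rank-sum oracle --------------------------------------------------------
# exact two-sided Mann-Whitney p by enumerating every assignment of bin
# positions among the combined (tie-free) values; mirrors the two-sided rule
# p = min(1, 2 * min tail) around the observed U
ranksumOracle <- function(bin, bg) {
    nb <- length(bin); nt <- nb + length(bg)
    ranks <- rank(c(bin, bg))
    uObs <- sum(ranks[seq_len(nb)]) - nb * (nb + 1) / 2
    combos <- combn(nt, nb)
    uAll <- apply(combos, 2, function(ix) sum(ix) - nb * (nb + 1) / 2)
    p <- if (uObs > nb * (nt - nb) / 2) mean(uAll >= uObs) else mean(uAll <= uObs)
    min(1, 2 * p)
}

# --- small expression fixture ----------------------------------------------
# deterministic toy experiment: 3 tissues x 2 conditions x 2 reps
toyExperiment <- function(fpkmRows, genes = rownames(fpkmRows)) {
    tissues <- rep(c("leaf", "stem", "root"), each = 4)
    conds <- rep(rep(c("drought", "control"), each = 2), 3)
    reps <- rep(1:2, 6)
    FpkmExperiment(fpkmRows, tissue = tissues, condition = conds,
                   replicate = reps)
}
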