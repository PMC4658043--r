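test_that("the expression floor keeps genes above the cutoff in every cell", {
    m <- rbind(low  = c(0.05, 0.05, rep(5, 10)),   # leaf drought below floor
               high = rep(c(2, 3), 6),
               edge = rep(0.1, 12))                # exactly at the floor: out
    fe <- toyExperiment(m)
    kept <- filterExpressed(fe, 0.1)
    expect_identical(rownames(kept), "high")
    # "any" scope keeps the gene expressed somewhere
    expect_setequal(rownames(filterExpressed(fe, 0.1, scope = "any")),
                    c("low", "high"))
    # all genes above the floor: identity
    allUp <- toyExperiment(matrix(runif(36, 1, 10), 3,
                                  dimnames = list(paste0("g", 1:3), NULL)))
    expect_identical(rownames(filterExpressed(allUp)), paste0("g", 1:3))

    # brute-force row scan on random matrices
    set.seed(17)
    for (i in 1:5) {
        mm <- matrix(runif(120, 0, 0.5), 10,
                     dimnames = list(paste0("g", 1:10), NULL))
        fe2 <- toyExperiment(mm)
        cells <- collapseReplicates(fe2)
        manual <- rownames(cells)[apply(cells, 1, function(r) all(r > 0.1))]
        expect_identical(rownames(filterExpressed(fe2)), manual)
    }
})

test_that("soft-threshold weights follow |r|^beta", {
    x <- c(1, 2, 3, 4, 5, 6)
    expect_equal(coexprWeight(x, x), 1)
    expect_equal(coexprWeight(x, -x), 1)   # unsigned network
    y <- c(1, 2, 3, 4, 5, 7)
    # hand-computed Pearson r via the definitional sums
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(coexprWeight(x, y), abs(r)^6)
    expect_equal(coexprWeight(x, y, beta = 1), abs(r))
    expect_error(coexprWeight(rep(1, 6), x), "constant")
})

test_that("network construction yields a symmetric unit-diagonal weight matrix", {
    set.seed(23)
    m <- matrix(2^rnorm(60, 3, 1), 5, dimnames = list(paste0("g", 1:5), NULL))
    m <- rbind(m, dup = m["g1", ])
    fe <- toyExperiment(m)
    net <- buildNetwork(fe)
    w <- net@weights
    expect_identical(dim(w), c(6L, 6L))
    expect_equal(w, t(w))
    expect_equal(unname(diag(w)), rep(1, 6))
    # duplicated profile: weight exactly 1 between the copies
    expect_equal(networkWeight(net, "g1", "dup"), 1)
    expect_error(buildNetwork(toyExperiment(
        matrix(1, 2, 12, dimnames = list(c("a", "b"), NULL)))), "constant")
})

test_that("the pathway Z-score satisfies its formula and selection rules", {
    set.seed(29)
    m <- matrix(2^rnorm(240, 3, 1), 20, dimnames = list(paste0("g", 1:20), NULL))
    net <- buildNetwork(toyExperiment(m))
    regs <- paste0("g", 1:4)
    degs <- paste0("g", 10:16)

    for (cutoff in c(0, 0.1, 0.3)) {
        res <- pathwayZscore(net, degs, regs, cutoff = cutoff)
        # brute-force recomputation from the weight matrix
        pw <- outer(degs, regs, Vectorize(function(d, r) networkWeight(net, d, r)))
        sel <- pw > cutoff
        bg <- c()
        for (r in regs) for (g in networkGenes(net))
            if (g != r && !(g %in% regs && match(g, regs) < match(r, regs)))
                bg <- c(bg, networkWeight(net, r, g))
        expect_equal(res$mu, mean(bg))
        expect_equal(res$delta, sd(bg))
        if (any(sel)) {
            expect_equal(res$Sm, mean(pw[sel]))
            expect_identical(res$m, sum(colSums(sel) > 0))
            expect_equal(res$Z, (res$Sm - res$mu) * res$m / res$delta)
        } else {
            expect_identical(res$m, 0L)
            expect_equal(res$Z, 0)
        }
    }

    # raising the cutoff never increases m
    ms <- vapply(c(0, 0.05, 0.1, 0.2, 0.5, 0.99),
                 function(ct) pathwayZscore(net, degs, regs, cutoff = ct)$m,
                 numeric(1))
    expect_true(all(diff(ms) <= 0))
    # no pair above cutoff 1 is possible
    expect_equal(pathwayZscore(net, degs, regs, cutoff = 1)$Z, 0)
    expect_error(pathwayZscore(net, c(degs, regs[1]), regs), "disjoint")
    expect_error(pathwayZscore(net, "absent", regs), "network genes")
})

test_that("Z is linear in m when Sm, mu and delta are held fixed", {
    # direct formula arithmetic: Sm=0.5, mu=0.3, delta=0.1, m=4 -> Z=8
    expect_equal((0.5 - 0.3) * 4 / 0.1, 8)
    set.seed(30)
    m <- matrix(2^rnorm(240, 3, 1), 20, dimnames = list(paste0("g", 1:20), NULL))
    net <- buildNetwork(toyExperiment(m))
    res <- pathwayZscore(net, paste0("g", 10:16), paste0("g", 1:4), cutoff = 0)
    expect_equal(res$Z / res$m, (res$Sm - res$mu) / res$delta)
})

test_that("high co-expression pairs equal a brute-force filter, sorted", {
    set.seed(27)
    m <- matrix(2^rnorm(144, 3, 1), 12, dimnames = list(paste0("g", 1:12), NULL))
    net <- buildNetwork(toyExperiment(m))
    regs <- paste0("g", 1:3)
    for (cutoff in c(0, 0.2, 0.9)) {
        got <- highCoexprPairs(net, regs, cutoff)
        manual <- do.call(rbind, lapply(regs, function(r)
            do.call(rbind, lapply(setdiff(networkGenes(net), r), function(g) {
                w <- networkWeight(net, r, g)
                if (w > cutoff) data.frame(regulator = r, gene = g, weight = w)
                else NULL
            }))))
        if (is.null(manual)) {
            expect_identical(nrow(got), 0L)
        } else {
            manual <- manual[order(-manual$weight, manual$regulator,
                                   manual$gene), ]
            expect_equal(got$weight, manual$weight)
            expect_identical(got$regulator, manual$regulator)
            expect_identical(got$gene, manual$gene)
        }
    }
    # cutoff 0 returns every regulator pair
    expect_identical(nrow(highCoexprPairs(net, regs, 0)),
                     length(regs) * (length(networkGenes(net)) - 1L))
})
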