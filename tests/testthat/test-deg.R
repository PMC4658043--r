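test_that("fold change follows the pseudocount arithmetic", {
    expect_equal(foldChange(10, 10, 0.1), 1)
    expect_equal(foldChange(40, 10, 0.1), 40.1 / 10.1)
    expect_equal(foldChange(5, 0, 0.1), 51)
    expect_error(foldChange(-1, 2), "non-negative")
    expect_error(foldChange(1, 2, 0), "positive")
    # reciprocal identity
    set.seed(2)
    a <- runif(20, 0, 50); b <- runif(20, 0, 50)
    expect_equal(foldChange(a, b, 0.1) * foldChange(b, a, 0.1),
                 rep(1, 20))
})

test_that("the replicate test is a two-sided Welch t on log2(FPKM + 1)", {
    # identical replicate vectors on both sides: zero difference, floored
    # variance, p = 1
    expect_equal(degTest(c(4, 4), c(4, 4)), 1)

    # frozen case: log2 values 5.0/5.2 vs 2.0/2.2 gives t = 3/(0.1*sqrt(2)),
    # Welch df = 2 (equal n, equal variance)
    d <- 2^c(5.0, 5.2) - 1
    c0 <- 2^c(2.0, 2.2) - 1
    p <- degTest(d, c0)
    tStat <- 3 / (0.1 * sqrt(2))
    expect_equal(p, 2 * pt(-tStat, df = 2))
    # independent oracle route
    expect_equal(p, t.test(log2(d + 1), log2(c0 + 1))$p.value)
    # symmetry
    expect_equal(degTest(c0, d), p)
    expect_error(degTest(5, c(1, 2)), "2 replicates")
})

test_that("the DEG rule is strict on fold change and inclusive on p", {
    # drought/control means engineered to fold change exactly 2 with the
    # 0.1 pseudocount: (1.9 + 0.1)/(0.9 + 0.1)
    m <- rbind(boundary = c(1.9, 1.9, 0.9, 0.9,  rep(c(10, 10), 4)),
               above    = c(2.5, 2.5, 0.9, 0.9,  rep(c(10, 10), 4)),
               down     = c(0.4, 0.4, 1.9, 1.9,  rep(c(10, 10), 4)))
    fe <- toyExperiment(m)
    degs <- callDegs(fe)
    leaf <- degs[degs$tissue == "leaf", ]
    expect_false("boundary" %in% leaf$gene_id)  # "greater than two" is strict
    expect_setequal(leaf$gene_id, c("above", "down"))
    expect_identical(leaf$direction[leaf$gene_id == "above"], "up")
    expect_identical(leaf$direction[leaf$gene_id == "down"], "down")
    # stem and root columns are flat: no calls
    expect_false(any(degs$tissue != "leaf"))
})

test_that("no planted effect and no noise means no calls; up/down partition holds", {
    ge <- genExpression(2, nGenes = 100, degFraction = 0, noiseSd = 0)
    expect_identical(nrow(callDegs(ge$experiment)), 0L)

    ge2 <- genExpression(2, nGenes = 500, degFraction = 0.15)
    degs <- callDegs(ge2$experiment)
    expect_true(all(degs$direction %in% c("up", "down")))
    for (ts in unique(degs$tissue)) {
        sub <- degs[degs$tissue == ts, ]
        expect_identical(sum(sub$direction == "up") +
                         sum(sub$direction == "down"), nrow(sub))
        expect_false(anyDuplicated(sub$gene_id) > 0)
    }
})

test_that("tightening thresholds never adds a call", {
    ge <- genExpression(4, nGenes = 400, degFraction = 0.2, noiseSd = 0.3,
                        lfcMean = 1.5)
    key <- function(d) paste(d$gene_id, d$tissue)
    base <- callDegs(ge$experiment, fcThreshold = 2, pThreshold = 0.05)
    expect_true(all(key(callDegs(ge$experiment, fcThreshold = 3)) %in% key(base)))
    expect_true(all(key(callDegs(ge$experiment, pThreshold = 0.01)) %in% key(base)))
})

test_that("the Venn partition matches exhaustive membership enumeration", {
    p <- overlapPartition(paste0("g", 1:10), paste0("g", 1:10), paste0("g", 1:10))
    expect_identical(unname(p$counts["common"]), 10L)
    expect_identical(sum(p$counts) - unname(p$counts["common"]), 0L)

    q <- overlapPartition(paste0("a", 1:2), paste0("b", 1:3), paste0("c", 1:4))
    expect_identical(unname(q$counts[c("leaf_only", "stem_only", "root_only")]),
                     c(2L, 3L, 4L))
    expect_identical(sum(q$counts), q$total)

    set.seed(9)
    for (i in 1:10) {
        u <- paste0("g", 1:30)
        L <- sample(u, sample(5:20, 1)); S <- sample(u, sample(5:20, 1))
        R <- sample(u, sample(5:20, 1))
        res <- overlapPartition(L, S, R)
        # brute-force region assignment per element of the union
        regions <- table(factor(vapply(union(union(L, S), R), function(g) {
            inL <- g %in% L; inS <- g %in% S; inR <- g %in% R
            if (inL && inS && inR) "common"
            else if (inL && inS) "leaf_stem"
            else if (inL && inR) "leaf_root"
            else if (inS && inR) "stem_root"
            else if (inL) "leaf_only" else if (inS) "stem_only" else "root_only"
        }, ""), levels = names(res$counts)))
        expect_identical(res$counts, setNames(as.integer(regions),
                                              names(res$counts)))
        expect_identical(sum(res$counts), res$total)
    }
})

test_that("direction concordance counts genes without a unanimous direction", {
    rec <- function(g, ts, dir) data.frame(gene_id = g, tissue = ts,
                                           direction = dir)
    allUp <- do.call(rbind, lapply(c("leaf", "stem", "root"), function(ts)
        rec(paste0("g", 1:5), ts, "up")))
    expect_equal(directionConcordance(allUp), 0)

    mixed <- rbind(rec(c("g1", "g2", "g3", "g4"), "leaf", "up"),
                   rec(c("g1", "g2", "g3", "g4"), "stem",
                       c("up", "down", "up", "down")),
                   rec(c("g1", "g2", "g3", "g4"), "root", "up"))
    expect_equal(directionConcordance(mixed), 0.5)

    incomplete <- rbind(rec("g1", "leaf", "up"), rec("g1", "stem", "up"))
    expect_error(directionConcordance(rbind(mixed, rec("g9", "leaf", "up")),
                                      common = "g9"), "lacks a record")

    # brute-force agreement on random direction tables
    set.seed(13)
    for (i in 1:5) {
        genes <- paste0("g", 1:12)
        tab <- do.call(rbind, lapply(c("leaf", "stem", "root"), function(ts)
            rec(genes, ts, sample(c("up", "down"), 12, TRUE))))
        got <- directionConcordance(tab)
        manual <- mean(vapply(genes, function(g) {
            dirs <- tab$direction[tab$gene_id == g]
            !all(dirs == dirs[1])
        }, logical(1)))
        expect_equal(got, manual)
    }
})
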