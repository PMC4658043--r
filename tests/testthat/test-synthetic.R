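test_that("proteome generator plants the promised counts deterministically", {
    gp <- genProteins(1, nPerSubfamily = 5, nBackground = 20, length = 300)
    expect_length(gp$candidates, 35L)
    expect_length(gp$truth$family_members, 15L)
    expect_identical(sort(unique(unname(gp$truth$subfamily_of))),
                     c("MEKK", "Raf", "ZIK"))
    expect_true(all(nchar(gp$candidates) == 300L))
    # determinism
    expect_identical(genProteins(1, 5, 20, 300), gp)
    expect_error(genProteins(1, length = 10), "longest motif")
})

test_that("planted members carry exactly one own-subfamily motif; background none", {
    gp <- genProteins(2, nPerSubfamily = 3, nBackground = 10, length = 150)
    motifs <- mapkkkMotifs()
    ids <- sub(" .*", "", names(gp$candidates))
    for (i in seq_along(gp$candidates)) {
        s <- gp$candidates[[i]]
        own <- gp$truth$subfamily_of[ids[i]]
        for (lab in names(motifs)) {
            nhit <- length(scanMotif(s, motifs[[lab]]))
            if (!is.na(own) && lab == own) expect_identical(nhit, 1L)
            else expect_identical(nhit, 0L)
        }
    }
})

test_that("expression generator: zero effect and zero noise give equal means", {
    ge <- genExpression(1, nGenes = 50, degFraction = 0, noiseSd = 0)
    m <- collapseReplicates(ge$experiment)
    for (ts in c("leaf", "stem", "root"))
        expect_equal(m[, paste0(ts, "_drought")], m[, paste0(ts, "_control")])
    expect_identical(nrow(ge$experiment), 50L)
    expect_error(genExpression(1, reps = 1), "2 replicates")
    expect_error(genExpression(1, degFraction = 0.1, lfcMean = 0.5),
                 "exceed 1")
})

test_that("expression generator is reproducible down to the written table", {
    ge1 <- genExpression(9, nGenes = 30)
    ge2 <- genExpression(9, nGenes = 30)
    expect_identical(fpkm(ge1$experiment), fpkm(ge2$experiment))
    expect_identical(ge1$truth, ge2$truth)
    f1 <- tempfile(); f2 <- tempfile()
    writeExpressionTsv(ge1$experiment, f1)
    writeExpressionTsv(ge2$experiment, f2)
    expect_identical(readLines(f1), readLines(f2))
    # round trip through the TSV reader
    back <- readExpressionTsv(f1)
    expect_equal(fpkm(back), fpkm(ge1$experiment))
})

test_that("planted DEG magnitudes are at least a doubling in the stated direction", {
    ge <- genExpression(3, nGenes = 300, degFraction = 0.2, noiseSd = 0)
    m <- collapseReplicates(ge$experiment)
    for (ts in names(ge$truth$deg_ids)) {
        tr <- ge$truth$deg_ids[[ts]]
        lfc <- log2(m[tr$gene_id, paste0(ts, "_drought")] /
                    m[tr$gene_id, paste0(ts, "_control")])
        expect_true(all(abs(lfc) > 1))
        expect_identical(unname(ifelse(lfc > 0, "up", "down")), tr$direction)
        expect_equal(unname(lfc), tr$lfc)
    }
})

test_that("gene-set generator packs one term and rejects bad overlaps", {
    genes <- paste0("g", 1:500)
    degs <- paste0("g", 1:40)
    gs <- genGenesets(5, nTerms = 8, genes = genes, degIds = degs,
                      enrichedTermSize = 20, degOverlap = 20)
    expect_length(gs$genesets, 8L)
    expect_true(all(gs$genesets[[gs$truth$enriched_term]] %in% degs))
    expect_identical(genGenesets(5, 8, genes, degs, 20, 20), gs)
    one <- genGenesets(5, nTerms = 1, genes = genes, degIds = degs,
                       enrichedTermSize = 10)
    expect_length(one$genesets, 1L)
    expect_error(genGenesets(5, 8, genes, degs, enrichedTermSize = 10,
                             degOverlap = 11), "cannot exceed")
})

test_that("qPCR generator back-computes Ct exactly in the noise-free limit", {
    q <- genQpcrBiomass(6, nLines = 8, trueRho = 1, ctNoiseSd = 0)
    rq <- ddctTable(q$ct)
    expect_equal(setNames(rq$target, rq$line), q$truth$rel_expr,
                 tolerance = 1e-9)
    # degenerate bivariate case: sample r exactly 1
    expect_equal(cor(q$truth$rel_expr, q$truth$dti), 1)
    # the biomass table reproduces the planted DTI
    b <- q$biomass
    d <- merge(b[b$condition == "drought", ], b[b$condition == "control", ],
               by = "line")
    expect_equal(setNames(computeDti(d$fresh_g.x, d$fresh_g.y), d$line),
                 q$truth$dti[d$line])
    expect_identical(genQpcrBiomass(6, 8, 1, ctNoiseSd = 0), q)
    expect_error(genQpcrBiomass(1, nLines = 2), "3 lines")
    expect_error(genQpcrBiomass(1, trueRho = 1.2), "\\[-1, 1\\]")
})

test_that("co-expression generator plants exact correlations", {
    gc <- genCoexpression(8, nGenes = 60, nPathways = 3, blockSize = 5,
                          nRegulators = 2)
    m <- collapseReplicates(gc$experiment)
    block <- gc$pathways[[gc$truth$planted_pathway]]
    # block genes are exact affine copies: pairwise correlation 1
    cc <- cor(t(m[block, ]))
    expect_equal(max(abs(cc - 1)), 0, tolerance = 1e-12)
    # each regulator correlates with the block at exactly rho
    for (r in gc$regulators)
        expect_equal(unname(cor(m[r, ], m[block[1], ])), gc$truth$rho,
                     tolerance = 1e-10)
    # orthogonalised background: no background gene touches a regulator
    bg <- setdiff(rownames(m), c(block, gc$regulators))
    crossCor <- cor(t(m[gc$regulators, , drop = FALSE]), t(m[bg, ]))
    expect_lt(max(abs(crossCor)), sqrt(1 - gc$truth$rho^2) + 1e-10)
})
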