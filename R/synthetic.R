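# All generators are pure functions of (seed, parameters): the global RNG
# state is saved and restored around each call.
withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

randomProtein <- function(n) {
    paste(sample(aminoAcids(), n, replace = TRUE), collapse = "")
}

# substitute residues outside [protect_from, protect_to] at the given rate
mutateProtein <- function(seq, rate, protectFrom = 0L, protectTo = -1L) {
    v <- strsplit(seq, "")[[1]]
    pos <- seq_along(v)
    eligible <- pos < protectFrom | pos > protectTo
    hit <- eligible & runif(length(v)) < rate
    v[hit] <- sample(aminoAcids(), sum(hit), replace = TRUE)
    paste(v, collapse = "")
}

# fixed cross-family-safe instantiations: the Raf signature GTxx(W/Y)MAPE is
# a degenerate superset of MEKK instantiations carrying T/W, so the planted
# instances pick alternatives that match exactly one subfamily pattern
safeMotifInstances <- function() {
    c(ZIK = "GTPEFMAPELY", MEKK = "GSPAFMAPEV", Raf = "GTADYMAPE")
}

motifCountsOk <- function(seq, own, patterns) {
    for (lab in names(patterns)) {
        nhit <- length(scanMotif(seq, patterns[[lab]]))
        if (lab == own && nhit != 1L) return(FALSE)
        if (lab != own && nhit != 0L) return(FALSE)
    }
    TRUE
}

noMotif <- function(seq, patterns) {
    all(vapply(patterns, function(p) length(scanMotif(seq, p)) == 0L,
               logical(1)))
}

#' Generate a synthetic proteome with planted family structure
#'
#' Builds, for each of the three MAPKKK subfamilies, a random seed protein
#' carrying exactly one instance of the subfamily's kinase-domain motif, then
#' derives family members and homology-search queries as substitution-mutated
#' copies (motif region re-planted), plus motif-free uniform-random background
#' proteins. Members retain well over 40% identity to their subfamily seed;
#' background sequences are rejected and resampled in the (rare) event they
#' contain any subfamily motif.
#'
#' Planted motif instances use residue alternatives that match exactly one
#' subfamily pattern, since the Raf signature genuinely subsumes some MEKK
#' instantiations.
#'
#' @param seed integer RNG seed.
#' @param nPerSubfamily members planted per subfamily (default 5).
#' @param nBackground background (non-member) proteins (default 20).
#' @param length protein length in residues (>= 30 and at least the longest
#'   motif; default 300).
#' @param nQueries query variants emitted per subfamily (default 6, so a
#'   member clears the default 5-hit membership rule).
#' @param memberMutationRate,queryMutationRate per-residue substitution rates
#'   for members and queries (defaults 0.25 and 0.2).
#' @return List with `candidates` (named character vector of member +
#'   background proteins, FASTA-style `id chrom=<c>` names), `queries` (named
#'   character vector), and `truth` (list: `family_members`, `subfamily_of`,
#'   `chromosome_of`, `query_ids`).
#' @export
genProteins <- function(seed, nPerSubfamily = 5L, nBackground = 20L,
                        length = 300L, nQueries = 6L,
                        memberMutationRate = 0.25, queryMutationRate = 0.2) {
    stopifnot(nPerSubfamily >= 0L, nBackground >= 0L, nQueries >= 1L)
    patterns <- mapkkkMotifs()
    instances <- safeMotifInstances()
    if (length < max(nchar(instances)))
        stop("length must be at least the longest motif (",
             max(nchar(instances)), " residues)")
    if (length < 30L) stop("length must be >= 30 residues")
    withSeed(seed, {
        subfams <- names(patterns)
        candidates <- character(0)
        queries <- character(0)
        subfamily_of <- character(0)
        chromosome_of <- character(0)
        for (sf in subfams) {
            inst <- instances[[sf]]
            at <- sample(seq_len(length - nchar(inst) + 1L), 1L)
            plant <- function(s) {
                substr(s, at, at + nchar(inst) - 1L) <- inst
                s
            }
            repeat {
                seedSeq <- plant(randomProtein(length))
                if (motifCountsOk(seedSeq, sf, patterns)) break
            }
            derive <- function(rate) {
                repeat {
                    s <- plant(mutateProtein(seedSeq, rate, at,
                                             at + nchar(inst) - 1L))
                    if (motifCountsOk(s, sf, patterns)) return(s)
                }
            }
            for (q in seq_len(nQueries)) {
                queries[paste0("Q_", sf, "_", q)] <- derive(queryMutationRate)
            }
            for (i in seq_len(nPerSubfamily)) {
                id <- paste0(sf, "_", i)
                chrom <- as.character(sample(1:10, 1L))
                candidates[paste0(id, " chrom=", chrom)] <-
                    derive(memberMutationRate)
                subfamily_of[id] <- sf
                chromosome_of[id] <- chrom
            }
        }
        for (i in seq_len(nBackground)) {
            repeat {
                s <- randomProtein(length)
                if (noMotif(s, patterns)) break
            }
            chrom <- as.character(sample(1:10, 1L))
            candidates[paste0("BG_", i, " chrom=", chrom)] <- s
        }
        list(candidates = candidates,
             queries = queries,
             truth = list(
                 family_members = names(subfamily_of),
                 subfamily_of = subfamily_of,
                 chromosome_of = chromosome_of,
                 query_ids = names(queries)))
    })
}

# lfc magnitudes: normal around lfcMean, resampled to stay > 1 so every
# planted effect is at least a doubling
sampleLfc <- function(n, lfcMean, lfcSd = 0.5) {
    x <- rnorm(n, lfcMean, lfcSd)
    while (any(x <= 1)) x[x <= 1] <- rnorm(sum(x <= 1), lfcMean, lfcSd)
    x
}

#' Generate an FPKM matrix with planted differential expression
#'
#' Baseline abundance is log-normal (`2^N(baselineLog2Mean, baselineLog2Sd)`,
#' the heavy-tailed range typical of FPKM summaries), shared across tissues.
#' In each tissue an independent fraction of genes is planted as
#' differentially expressed: the drought mean is the baseline times
#' `2^(+/- lfc)` with `lfc > 1` drawn around `lfcMean`. Replicate noise is
#' multiplicative log-normal with standard deviation `noiseSd` log2 units.
#'
#' @param seed integer RNG seed.
#' @param nGenes number of genes.
#' @param tissues tissue labels (default leaf, stem, root).
#' @param reps replicates per tissue x condition (default 2; must be >= 2).
#' @param degFraction fraction of genes planted as DEGs per tissue, in
#'   `[0, 1]` (default 0.1).
#' @param lfcMean mean planted |log2 fold change| (default 3; must exceed 1
#'   when `degFraction > 0`).
#' @param noiseSd replicate noise sd in log2 units (default 0.1).
#' @param baselineLog2Mean,baselineLog2Sd baseline log2-FPKM distribution
#'   (defaults 3 and 2).
#' @return List with `experiment` (an [FpkmExperiment-class]) and `truth`
#'   (list with `deg_ids`: per-tissue `data.frame(gene_id, direction, lfc)`).
#' @export
genExpression <- function(seed, nGenes = 2000L,
                          tissues = c("leaf", "stem", "root"), reps = 2L,
                          degFraction = 0.1, lfcMean = 3, noiseSd = 0.1,
                          baselineLog2Mean = 3, baselineLog2Sd = 2) {
    if (reps < 2L) stop("at least 2 replicates are required")
    stopifnot(degFraction >= 0, degFraction <= 1, nGenes >= 1L)
    if (degFraction > 0 && lfcMean <= 1)
        stop("lfcMean must exceed 1 for recoverable planted effects")
    withSeed(seed, {
        genes <- sprintf("gene%04d", seq_len(nGenes))
        baseline <- 2^rnorm(nGenes, baselineLog2Mean, baselineLog2Sd)
        nDeg <- floor(degFraction * nGenes)
        cols <- list(); meta <- list(); deg_ids <- list()
        for (ts in tissues) {
            idx <- sort(sample.int(nGenes, nDeg))
            dir <- sample(c(1, -1), nDeg, replace = TRUE)
            lfc <- if (nDeg) sampleLfc(nDeg, lfcMean) else numeric(0)
            mu <- cbind(drought = baseline, control = baseline)
            mu[idx, "drought"] <- baseline[idx] * 2^(dir * lfc)
            for (cond in c("drought", "control")) {
                for (r in seq_len(reps)) {
                    nm <- paste(ts, cond, r, sep = "_")
                    cols[[nm]] <- mu[, cond] * 2^rnorm(nGenes, 0, noiseSd)
                    meta[[nm]] <- c(ts, cond, r)
                }
            }
            deg_ids[[ts]] <- data.frame(
                gene_id = genes[idx],
                direction = ifelse(dir > 0, "up", "down"),
                lfc = dir * lfc, stringsAsFactors = FALSE)
        }
        m <- do.call(cbind, cols)
        rownames(m) <- genes
        meta <- do.call(rbind, meta)
        fe <- FpkmExperiment(m, tissue = meta[, 1], condition = meta[, 2],
                             replicate = as.integer(meta[, 3]))
        list(experiment = fe, truth = list(deg_ids = deg_ids))
    })
}

#' Generate gene sets with one planted enriched term
#'
#' One designated term is packed with `degOverlap` ids drawn from the study
#' (DEG) list, topped up to `enrichedTermSize` with non-study genes; every
#' other term samples genes uniformly from the full list.
#'
#' @param seed integer RNG seed.
#' @param nTerms number of terms.
#' @param genes character vector of all (background) gene ids.
#' @param degIds study gene ids the designated term is packed with.
#' @param enrichedTermSize size of the designated term (default 30; at most
#'   `length(genes)`).
#' @param degOverlap study ids packed into the designated term (default
#'   `enrichedTermSize`; must not exceed it).
#' @param termSizeRange size range for the remaining, uniform terms
#'   (default 10-50).
#' @return List with `genesets` (named list, designated term first) and
#'   `truth` (list with `enriched_term`).
#' @export
genGenesets <- function(seed, nTerms, genes, degIds,
                        enrichedTermSize = 30L,
                        degOverlap = enrichedTermSize,
                        termSizeRange = c(10L, 50L)) {
    stopifnot(nTerms >= 1L, enrichedTermSize <= length(genes))
    if (degOverlap > enrichedTermSize)
        stop("degOverlap cannot exceed enrichedTermSize")
    if (degOverlap > length(degIds))
        stop("degOverlap cannot exceed the number of study ids")
    withSeed(seed, {
        sets <- vector("list", nTerms)
        names(sets) <- sprintf("term%03d", seq_len(nTerms))
        packed <- c(sample(degIds, degOverlap),
                    sample(setdiff(genes, degIds),
                           enrichedTermSize - degOverlap))
        sets[[1L]] <- packed
        for (i in seq_len(nTerms)[-1L]) {
            sz <- sample(termSizeRange[1]:termSizeRange[2], 1L)
            sets[[i]] <- sample(genes, min(sz, length(genes)))
        }
        list(genesets = sets,
             truth = list(enriched_term = names(sets)[1L]))
    })
}

#' Generate qPCR Ct and biomass tables with a planted correlation
#'
#' Per-line drought relative expression and biomass drought tolerance index
#' (DTI) are drawn from a bivariate normal with correlation `trueRho` (pairs
#' re-drawn in the rare event a value is non-positive). Ct values are
#' back-computed so that delta-delta-Ct analysis reproduces the planted
#' relative expression exactly in the noise-free limit; measurement noise, if
#' any, enters additively on the Ct scale, where the method is linear.
#'
#' @param seed integer RNG seed.
#' @param nLines number of inbred lines (>= 3; default 8).
#' @param trueRho planted expression-DTI correlation in `[-1, 1]`
#'   (default 0.8).
#' @param reps technical qPCR replicates per measurement (default 3).
#' @param ctNoiseSd additive Ct noise sd in cycles (default 0.05; 0 gives the
#'   exact closed form).
#' @param exprMean,exprSd marginal distribution of the planted relative
#'   expression (defaults 4 and 1.2).
#' @param dtiMean,dtiSd marginal distribution of the planted DTI (defaults
#'   0.6 and 0.08, the observed range of seedling biomass ratios).
#' @param gene target gene id used in the Ct table (default `"target"`).
#' @return List with `ct` (long `data.frame`: line, gene, condition,
#'   ct_target, ct_reference, rep), `biomass` (`data.frame`: line, condition,
#'   fresh_g, dry_g) and `truth` (list: `rel_expr`, `dti`, `true_rho`).
#' @export
genQpcrBiomass <- function(seed, nLines = 8L, trueRho = 0.8, reps = 3L,
                           ctNoiseSd = 0.05, exprMean = 4, exprSd = 1.2,
                           dtiMean = 0.6, dtiSd = 0.08, gene = "target") {
    if (nLines < 3L) stop("at least 3 lines are required")
    if (abs(trueRho) > 1) stop("trueRho must lie in [-1, 1]")
    stopifnot(reps >= 1L)
    withSeed(seed, {
        lines <- sprintf("line%02d", seq_len(nLines))
        draw <- function() {
            u <- rnorm(1); v <- trueRho * u + sqrt(1 - trueRho^2) * rnorm(1)
            c(expr = exprMean + exprSd * u, dti = dtiMean + dtiSd * v)
        }
        pairs <- t(vapply(lines, function(l) {
            repeat {
                p <- draw()
                if (p["expr"] > 0.05 && p["dti"] > 0.05) return(p)
            }
        }, c(expr = 0, dti = 0)))
        relExpr <- setNames(pairs[, "expr"], lines)
        dti <- setNames(pairs[, "dti"], lines)

        refCt <- 20; controlTargetCt <- 24
        dctControl <- controlTargetCt - refCt
        ct <- do.call(rbind, lapply(lines, function(l) {
            do.call(rbind, lapply(c("drought", "control"), function(cond) {
                target <- if (cond == "control") controlTargetCt
                          else refCt + dctControl - log2(relExpr[[l]])
                data.frame(line = l, gene = gene, condition = cond,
                           ct_target = target + rnorm(reps, 0, ctNoiseSd),
                           ct_reference = refCt + rnorm(reps, 0, ctNoiseSd),
                           rep = seq_len(reps), stringsAsFactors = FALSE)
            }))
        }))
        controlFresh <- runif(nLines, 8, 12)
        biomass <- rbind(
            data.frame(line = lines, condition = "control",
                       fresh_g = controlFresh, dry_g = 0.1 * controlFresh,
                       stringsAsFactors = FALSE),
            data.frame(line = lines, condition = "drought",
                       fresh_g = dti * controlFresh,
                       dry_g = dti * 0.1 * controlFresh,
                       stringsAsFactors = FALSE))
        rownames(ct) <- rownames(biomass) <- NULL
        list(ct = ct, biomass = biomass,
             truth = list(rel_expr = relExpr, dti = dti, true_rho = trueRho))
    })
}

#' Generate expression data with a planted co-expressed pathway block
#'
#' Builds a six-cell (three tissues by two conditions) expression profile set
#' in which one pathway's genes are exact affine copies of a shared latent
#' profile (pairwise correlation 1) and every regulator is constructed to
#' correlate with that profile at exactly `rho` (Gram-Schmidt construction,
#' so the sample correlation is exact, not approximate). All remaining genes
#' are, by default, affine transforms of random profiles orthogonalised
#' against the latent profile, the zero-noise idealisation of an independent
#' background: a profile independent of the block has *population*
#' correlation zero with it, and with as few as six observations the
#' zero-noise limit places the sample correlation at that population value.
#' (Orthogonality to the latent profile bounds any background gene's
#' correlation with every regulator by `sqrt(1 - rho^2)`, i.e. its network
#' weight by `(1 - rho^2)^(beta/2)`, about 0.001 at the defaults — no
#' spurious selection is possible.) `orthogonalBackground = FALSE` draws
#' plain independent profiles instead, whose chance sample correlations over
#' six observations are occasionally large. The remaining pathways are random
#' subsets of the background. Replicates are exact duplicates, so the planted
#' structure survives replicate averaging unchanged.
#'
#' @param seed integer RNG seed.
#' @param nGenes total genes including the block and regulators
#'   (default 200).
#' @param nPathways number of pathways, the first one planted (default 5).
#' @param blockSize genes per pathway (default 10).
#' @param nRegulators regulator genes, all planted as co-expressed with the
#'   block (default 3); see Details of [pathwayZscore()] for why the planted
#'   signal spans all regulators.
#' @param rho planted regulator-block correlation (default 0.95).
#' @param reps duplicate replicates emitted per cell (default 2).
#' @param orthogonalBackground if `TRUE` (default), background profiles are
#'   orthogonalised against the latent block profile; see Details.
#' @return List with `experiment` (an [FpkmExperiment-class]), `pathways`
#'   (named list of gene ids, planted pathway first), `regulators` (ids) and
#'   `truth` (list: `planted_pathway`, `coexpressed_pairs`, `rho`).
#' @export
genCoexpression <- function(seed, nGenes = 200L, nPathways = 5L,
                            blockSize = 10L, nRegulators = 3L, rho = 0.95,
                            reps = 2L, orthogonalBackground = TRUE) {
    stopifnot(nPathways >= 1L, blockSize >= 2L, nRegulators >= 1L,
              abs(rho) <= 1, reps >= 2L)
    if (nGenes < nPathways * blockSize + nRegulators)
        stop("nGenes too small for the requested pathways and regulators")
    withSeed(seed, {
        cells <- as.vector(outer(c("leaf", "stem", "root"),
                                 c("drought", "control"), paste, sep = "_"))
        nObs <- length(cells)
        std <- function(x) (x - mean(x)) / sd(x)
        z <- std(rnorm(nObs))
        affineOf <- function(latent) {
            base <- 2^rnorm(1, 3, 1)
            base * (1 + 0.2 * latent)
        }
        genes <- sprintf("g%04d", seq_len(nGenes))
        regIds <- sprintf("MAPKKK%02d", seq_len(nRegulators))
        blockIds <- genes[seq_len(blockSize)]
        otherIds <- genes[-seq_len(blockSize)]

        profiles <- matrix(0, nGenes + nRegulators, nObs,
                           dimnames = list(c(genes, regIds), cells))
        for (g in blockIds) profiles[g, ] <- affineOf(z)
        for (g in otherIds) {
            if (orthogonalBackground) {
                repeat {
                    u <- rnorm(nObs)
                    u <- u - mean(u)
                    u <- u - z * sum(u * z) / sum(z^2)
                    if (sd(u) > 1e-8) break
                }
                profiles[g, ] <- affineOf(std(u))
            } else {
                profiles[g, ] <- 2^rnorm(nObs, 3, 1)
            }
        }
        for (r in regIds) {
            e <- rnorm(nObs)
            e <- e - mean(e)
            e <- e - z * sum(e * z) / sum(z^2)
            w <- rho * z + sqrt(1 - rho^2) * std(e)
            profiles[r, ] <- affineOf(w)
        }
        m <- profiles[, rep(seq_len(nObs), each = reps)]
        parts <- strsplit(cells, "_", fixed = TRUE)
        fe <- FpkmExperiment(m,
            tissue = rep(vapply(parts, `[`, "", 1L), each = reps),
            condition = rep(vapply(parts, `[`, "", 2L), each = reps),
            replicate = rep(seq_len(reps), times = nObs))

        pathways <- list(blockIds)
        pool <- otherIds
        for (i in seq_len(nPathways - 1L)) {
            pick <- sample(pool, blockSize)
            pool <- setdiff(pool, pick)
            pathways <- c(pathways, list(pick))
        }
        names(pathways) <- sprintf("pathway%02d", seq_len(nPathways))
        list(experiment = fe, pathways = pathways, regulators = regIds,
             truth = list(planted_pathway = names(pathways)[1L],
                          coexpressed_pairs = data.frame(
                              pathway = names(pathways)[1L],
                              regulator = regIds,
                              stringsAsFactors = FALSE),
                          rho = rho))
    })
}

#' Write protein sequences as wrapped FASTA
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @param width line-wrap column (default 60).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(sequences, path, width = 60L) {
    aa <- Biostrings::AAStringSet(sequences)
    Biostrings::writeXStringSet(aa, path, width = width)
    invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (full description lines as
#'   names).
#' @export
readFasta <- function(path) {
    aa <- Biostrings::readAAStringSet(path)
    setNames(as.character(aa), names(aa))
}
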