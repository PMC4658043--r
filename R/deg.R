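#' Drought/control fold change with pseudocount
#'
#' `(meanDrought + pseudocount) / (meanControl + pseudocount)`. The
#' pseudocount bounds behaviour at zero expression; the default 0.1 FPKM is
#' the same floor used to declare a transcript expressed.
#'
#' @param meanDrought,meanControl replicate-mean FPKM values (vectorised).
#' @param pseudocount positive FPKM offset (default 0.1).
#' @return Fold-change ratio(s).
#' @export
foldChange <- function(meanDrought, meanControl, pseudocount = 0.1) {
    if (any(meanDrought < 0) || any(meanControl < 0))
        stop("mean FPKM values must be non-negative")
    if (pseudocount <= 0) stop("pseudocount must be positive")
    (meanDrought + pseudocount) / (meanControl + pseudocount)
}

# vectorised Welch t on log2(FPKM + 1) rows; per-group variance floored so
# zero-variance replicate sets give a defined statistic
welchRows <- function(d, c, varFloor = 1e-8) {
    n1 <- ncol(d); n2 <- ncol(c)
    m1 <- rowMeans(d); m2 <- rowMeans(c)
    v1 <- pmax(rowSums((d - m1)^2) / (n1 - 1), varFloor)
    v2 <- pmax(rowSums((c - m2)^2) / (n2 - 1), varFloor)
    se2 <- v1 / n1 + v2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    2 * pt(-abs(t), df)
}

#' Replicate test for differential expression
#'
#' Two-sided Welch t-test on `log2(FPKM + 1)` values, with each group's
#' variance floored at `1e-8` so that identical replicates (zero variance)
#' yield a defined p-value: equal group means then give p = 1.
#'
#' @param droughtReps,controlReps FPKM replicate values, at least 2 per side.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
degTest <- function(droughtReps, controlReps) {
    if (length(droughtReps) < 2L || length(controlReps) < 2L)
        stop("at least 2 replicates per condition are required")
    welchRows(matrix(log2(droughtReps + 1), nrow = 1),
              matrix(log2(controlReps + 1), nrow = 1))
}

#' Call differentially expressed genes per tissue
#'
#' A gene is called in a tissue when its drought/control fold change is
#' strictly greater than `fcThreshold` or strictly less than
#' `1/fcThreshold`, and the replicate-test p-value is at most `pThreshold`
#' ("fold change greater than two and p-value at most 0.05"). Raw p-values
#' are used; no multiple-testing correction is applied at this stage.
#'
#' @param x an [FpkmExperiment-class].
#' @param fcThreshold fold-change threshold (default 2; strict).
#' @param pThreshold p-value threshold (default 0.05; inclusive).
#' @param pseudocount FPKM offset for [foldChange()] (default 0.1).
#' @return `data.frame` of DEG records with columns `gene_id`, `tissue`,
#'   `log2fc`, `fold_change`, `p_value`, `direction` (`"up"`/`"down"`).
#' @export
callDegs <- function(x, fcThreshold = 2, pThreshold = 0.05,
                     pseudocount = 0.1) {
    stopifnot(is(x, "FpkmExperiment"))
    cd <- SummarizedExperiment::colData(x)
    a <- fpkm(x)
    la <- log2(a + 1)
    out <- lapply(tissueNames(x), function(ts) {
        di <- cd$tissue == ts & cd$condition == "drought"
        ci <- cd$tissue == ts & cd$condition == "control"
        fc <- foldChange(rowMeans(a[, di, drop = FALSE]),
                         rowMeans(a[, ci, drop = FALSE]), pseudocount)
        p <- welchRows(la[, di, drop = FALSE], la[, ci, drop = FALSE])
        call <- (fc > fcThreshold | fc < 1 / fcThreshold) & p <= pThreshold
        data.frame(gene_id = rownames(a)[call],
                   tissue = rep(ts, sum(call)),
                   log2fc = log2(fc[call]),
                   fold_change = fc[call],
                   p_value = p[call],
                   direction = ifelse(fc[call] > fcThreshold, "up", "down"),
                   stringsAsFactors = FALSE, row.names = NULL)
    })
    do.call(rbind, out)
}

#' Three-set overlap partition
#'
#' Exact counts for the seven regions of the three-set Venn partition of
#' per-tissue DEG id sets, plus the triple intersection ("commonly regulated"
#' genes).
#'
#' @param leaf,stem,root character vectors of gene ids (duplicates ignored).
#' @return List with `counts` (named 7-vector: `leaf_only`, `stem_only`,
#'   `root_only`, `leaf_stem`, `leaf_root`, `stem_root`, `common`), `common`
#'   (ids in all three sets) and `total` (size of the union).
#' @export
overlapPartition <- function(leaf, stem, root) {
    leaf <- unique(leaf); stem <- unique(stem); root <- unique(root)
    all_ids <- union(union(leaf, stem), root)
    inL <- all_ids %in% leaf; inS <- all_ids %in% stem; inR <- all_ids %in% root
    counts <- c(
        leaf_only = sum(inL & !inS & !inR),
        stem_only = sum(!inL & inS & !inR),
        root_only = sum(!inL & !inS & inR),
        leaf_stem = sum(inL & inS & !inR),
        leaf_root = sum(inL & !inS & inR),
        stem_root = sum(!inL & inS & inR),
        common    = sum(inL & inS & inR))
    list(counts = counts,
         common = all_ids[inL & inS & inR],
         total = length(all_ids))
}

#' Direction concordance among commonly regulated genes
#'
#' For genes called in all three tissues, the fraction whose up/down direction
#' is not identical across tissues ("oppositely regulated").
#'
#' @param records `data.frame` of DEG records (as from [callDegs()]) covering
#'   the common genes; every common gene must have a record in each of the
#'   three tissues.
#' @param common character vector of common gene ids; default: genes present
#'   in all three tissues of `records`.
#' @return Proportion of common genes with discordant directions; `NaN` if
#'   there are no common genes.
#' @export
directionConcordance <- function(records, common = NULL) {
    tissues <- unique(records$tissue)
    if (is.null(common)) {
        byGene <- split(records$tissue, records$gene_id)
        common <- names(byGene)[vapply(byGene, function(ts)
            all(tissues %in% ts), logical(1))]
    }
    if (length(common) == 0L) return(NaN)
    discordant <- vapply(common, function(g) {
        rec <- records[records$gene_id == g, ]
        if (!all(tissues %in% rec$tissue))
            stop("gene ", g, " lacks a record in some tissue")
        length(unique(rec$direction)) > 1L
    }, logical(1))
    mean(discordant)
}
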