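#' FpkmExperiment: genes-by-samples FPKM container
#'
#' A thin [SummarizedExperiment::SummarizedExperiment-class] subclass holding
#' one `fpkm` assay with per-sample `tissue`, `condition` and `replicate`
#' metadata. Validity enforces non-negative FPKM and at least two replicates
#' per tissue/condition cell, the minimum the replicate test needs.
#'
#' @export
setClass("FpkmExperiment", contains = "SummarizedExperiment")

setValidity("FpkmExperiment", function(object) {
    msgs <- character()
    if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
        return("an 'fpkm' assay is required")
    a <- SummarizedExperiment::assay(object, "fpkm")
    if (any(!is.finite(a)) || any(a < 0))
        msgs <- c(msgs, "FPKM values must be finite and non-negative")
    cd <- SummarizedExperiment::colData(object)
    need <- c("tissue", "condition", "replicate")
    if (!all(need %in% colnames(cd)))
        return(paste("colData needs columns:", paste(need, collapse = ", ")))
    if (!all(cd$condition %in% c("drought", "control")))
        msgs <- c(msgs, "condition must be 'drought' or 'control'")
    reps <- table(paste(cd$tissue, cd$condition))
    if (any(reps < 2L))
        msgs <- c(msgs, "every tissue x condition cell needs >= 2 replicates")
    if (length(msgs)) msgs else TRUE
})

#' Construct an FpkmExperiment
#'
#' @param fpkm numeric matrix (genes x samples) of FPKM values; rownames are
#'   gene ids.
#' @param tissue,condition,replicate per-sample descriptors; `condition` must
#'   be `"drought"` or `"control"`.
#' @return An [FpkmExperiment-class].
#' @examples
#' m <- matrix(runif(24, 1, 50), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), NULL))
#' fe <- FpkmExperiment(m,
#'     tissue    = rep("leaf", 8),
#'     condition = rep(c("drought", "control"), each = 4),
#'     replicate = rep(1:4, 2))
#' @export
FpkmExperiment <- function(fpkm, tissue, condition, replicate) {
    fpkm <- as.matrix(fpkm)
    if (is.null(rownames(fpkm)))
        rownames(fpkm) <- paste0("gene", seq_len(nrow(fpkm)))
    colnames(fpkm) <- paste(tissue, condition, replicate, sep = "_")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(fpkm = fpkm),
        colData = S4Vectors::DataFrame(
            tissue = as.character(tissue),
            condition = as.character(condition),
            replicate = as.integer(replicate),
            row.names = colnames(fpkm)))
    new("FpkmExperiment", se)
}

#' FPKM assay accessor
#'
#' @param x an [FpkmExperiment-class].
#' @return The genes-by-samples FPKM matrix.
#' @export
fpkm <- function(x) SummarizedExperiment::assay(x, "fpkm")

#' Tissues present in an experiment
#'
#' @param x an [FpkmExperiment-class].
#' @return Character vector of distinct tissue labels, in column order.
#' @export
tissueNames <- function(x) unique(SummarizedExperiment::colData(x)$tissue)

#' Average replicates within tissue x condition
#'
#' Collapses the replicate dimension, returning the genes-by-cell matrix of
#' replicate-mean FPKM with columns named `tissue_condition`. With the default
#' three tissues and two conditions this yields the six columns the expression
#' floor and the co-expression network operate on.
#'
#' @param x an [FpkmExperiment-class].
#' @return Numeric matrix, one column per tissue/condition combination.
#' @export
collapseReplicates <- function(x) {
    stopifnot(is(x, "FpkmExperiment"))
    cd <- SummarizedExperiment::colData(x)
    key <- paste(cd$tissue, cd$condition, sep = "_")
    cells <- unique(key)
    m <- vapply(cells, function(k)
        rowMeans(fpkm(x)[, key == k, drop = FALSE]),
        numeric(nrow(x)))
    dimnames(m) <- list(rownames(x), cells)
    m
}

#' Read an FPKM table from TSV
#'
#' Expects a header row `gene_id` followed by sample columns named
#' `tissue_condition_rep` (e.g. `leaf_drought_1`).
#'
#' @param path file path.
#' @return An [FpkmExperiment-class].
#' @export
readExpressionTsv <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    stopifnot(colnames(df)[1] == "gene_id")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene_id
    parts <- strsplit(colnames(m), "_", fixed = TRUE)
    bad <- lengths(parts) != 3L
    if (any(bad))
        stop("sample columns must be named tissue_condition_rep; offending: ",
             paste(colnames(m)[bad], collapse = ", "))
    FpkmExperiment(m,
        tissue = vapply(parts, `[`, "", 1L),
        condition = vapply(parts, `[`, "", 2L),
        replicate = as.integer(vapply(parts, `[`, "", 3L)))
}

#' Write an FPKM table to TSV
#'
#' @param x an [FpkmExperiment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionTsv <- function(x, path) {
    df <- data.frame(gene_id = rownames(x), fpkm(x), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a GMT-like gene-set file
#'
#' Tab-separated lines: term id, description, then member gene ids.
#'
#' @param path file path.
#' @return Named list of character vectors (term -> gene ids).
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(fields, function(f) f[-(1:2)])
    names(sets) <- vapply(fields, `[`, "", 1L)
    sets
}

#' Write a GMT-like gene-set file
#'
#' @param genesets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional per-term description strings (defaults to the
#'   term ids).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(genesets, path, descriptions = names(genesets)) {
    lines <- vapply(seq_along(genesets), function(i)
        paste(c(names(genesets)[i], descriptions[i], genesets[[i]]),
              collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Read a one-id-per-line gene list
#'
#' @param path file path.
#' @return Character vector of ids.
#' @export
readGeneList <- function(path) {
    x <- readLines(path)
    x[nzchar(x)]
}
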