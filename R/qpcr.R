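#' Delta-delta-Ct relative expression
#'
#' Classic relative quantification with a reference gene and a calibrator
#' condition, assuming perfect doubling per cycle: within each measurement
#' set, `dCt = mean(ct_target) - mean(ct_reference)`; then
#' `ddCt = dCt_treat - dCt_calib` and the relative expression is
#' `2^(-ddCt)`.
#'
#' @param treat,calib `data.frame`s of replicate measurements with numeric
#'   columns `ct_target` and `ct_reference` (e.g. drought and well-watered
#'   sets for one line and gene).
#' @return Positive fold ratio `2^(-ddCt)`.
#' @export
ddctRelativeExpression <- function(treat, calib) {
    for (d in list(treat, calib)) {
        if (!all(c("ct_target", "ct_reference") %in% colnames(d)))
            stop("measurement sets need ct_target and ct_reference columns")
        if (nrow(d) == 0L || any(!is.finite(d$ct_target)) ||
            any(!is.finite(d$ct_reference)) || any(d$ct_target <= 0) ||
            any(d$ct_reference <= 0))
            stop("Ct values must be positive and finite")
    }
    dct_t <- mean(treat$ct_target) - mean(treat$ct_reference)
    dct_c <- mean(calib$ct_target) - mean(calib$ct_reference)
    2^(-(dct_t - dct_c))
}

#' Relative expression per line and gene from a Ct table
#'
#' Splits a long-format Ct table by line and gene and applies
#' [ddctRelativeExpression()] with the drought condition as treatment and the
#' control condition as calibrator.
#'
#' @param ct `data.frame` with columns `line`, `gene`, `condition`
#'   (`"drought"`/`"control"`), `ct_target`, `ct_reference` (and optionally
#'   `rep`).
#' @return `data.frame` of `line` x `gene` relative expression, wide format
#'   (first column `line`, one column per gene).
#' @export
ddctTable <- function(ct) {
    lines <- unique(ct$line); genes <- unique(ct$gene)
    m <- sapply(genes, function(g) vapply(lines, function(l) {
        sub <- ct[ct$line == l & ct$gene == g, ]
        ddctRelativeExpression(sub[sub$condition == "drought", ],
                               sub[sub$condition == "control", ])
    }, 0))
    out <- data.frame(line = lines, m, check.names = FALSE)
    rownames(out) <- NULL
    out
}

#' Drought tolerance index
#'
#' The drought-to-control biomass ratio, an integrative drought-response
#' phenotype; scale-invariant in the measurement units.
#'
#' @param droughtBiomass,controlBiomass positive biomass values (grams),
#'   vectorised.
#' @return DTI ratio(s).
#' @export
computeDti <- function(droughtBiomass, controlBiomass) {
    if (any(droughtBiomass <= 0) || any(controlBiomass <= 0))
        stop("biomass values must be positive")
    droughtBiomass / controlBiomass
}

#' Pearson correlation with two-sided significance
#'
#' Sample Pearson r with the usual t transform,
#' `t = r * sqrt((n - 2) / (1 - r^2))` against `n - 2` degrees of freedom,
#' two-sided. The significance star uses strict `p < alpha`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, neither constant.
#' @param alpha significance level for the flag (default 0.05).
#' @return List with `r`, `n`, `p_value`, `significant`.
#' @export
pearsonWithP <- function(x, y, alpha = 0.05) {
    stopifnot(length(x) == length(y))
    if (length(x) < 3L) stop("at least 3 paired observations are required")
    if (sd(x) == 0 || sd(y) == 0)
        stop("correlation is undefined for a constant vector")
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    list(r = unname(ct$estimate), n = length(x),
         p_value = ct$p.value, significant = ct$p.value < alpha)
}

#' Expression-phenotype correlation table
#'
#' Pearson correlation of each gene's relative expression across inbred lines
#' with the fresh and dry biomass drought tolerance indices, with a
#' significance star at `p < alpha`.
#'
#' @param expr `data.frame` with a `line` column and one numeric column per
#'   gene (relative expression in drought).
#' @param dti `data.frame` with columns `line`, `fresh_dti`, `dry_dti`.
#' @param alpha star threshold (default 0.05, strict).
#' @return `data.frame` with one row per gene x trait: `gene`, `trait`
#'   (`"fresh"`/`"dry"`), `r`, `n`, `p_value`, `significant`, `star`.
#' @export
correlationTable <- function(expr, dti, alpha = 0.05) {
    shared <- intersect(expr$line, dti$line)
    if (length(shared) < 3L) stop("fewer than 3 shared lines")
    e <- expr[match(shared, expr$line), , drop = FALSE]
    d <- dti[match(shared, dti$line), , drop = FALSE]
    genes <- setdiff(colnames(expr), "line")
    rows <- lapply(genes, function(g) {
        do.call(rbind, lapply(c(fresh = "fresh_dti", dry = "dry_dti"),
            function(col) {
                r <- pearsonWithP(e[[g]], d[[col]], alpha)
                data.frame(gene = g,
                           trait = if (col == "fresh_dti") "fresh" else "dry",
                           r = r$r, n = r$n, p_value = r$p_value,
                           significant = r$significant,
                           star = if (r$significant) "*" else "",
                           stringsAsFactors = FALSE)
            }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Packaged maize qRT-PCR / biomass panel
#'
#' The published panel of eight maize inbred lines: drought relative
#' expression (qRT-PCR, delta-delta Ct) of eight MAPKKK genes and the fresh-
#' and dry-biomass drought tolerance indices, shipped as plain-text fixtures.
#'
#' @return List with `expression` (`data.frame`: `line` + 8 gene columns) and
#'   `dti` (`data.frame`: `line`, `fresh_dti`, `dry_dti`).
#' @export
maizeQpcrPanel <- function() {
    dir <- system.file("extdata", package = "droughtMAPKKK")
    list(expression = read.delim(file.path(dir,
             "maize_qpcr_panel_expression.tsv"), check.names = FALSE),
         dti = read.delim(file.path(dir, "maize_qpcr_panel_dti.tsv")))
}
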