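#' Hypergeometric upper-tail enrichment p-value
#'
#' Probability of observing at least `k` annotated genes when drawing `n`
#' study genes from a background of `N` genes of which `K` carry the
#' annotation: `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k study hits (vectorised).
#' @param K term size in the background.
#' @param n study size.
#' @param N background size.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
hypergeomPvalue <- function(k, K, n, N) {
    if (any(K > N) || any(n > N) || any(k > pmin(n, K)) || any(k < 0) ||
        any(c(K, n, N) < 0))
        stop("inconsistent hypergeometric counts")
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param method adjustment method (default `"BH"`; `"BY"` for the
#'   Benjamini-Yekutieli variant).
#' @return Vector of q-values, same order as `p`.
#' @export
bhFdr <- function(p, method = c("BH", "BY")) {
    method <- match.arg(method)
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    p.adjust(p, method = method)
}

#' Singular enrichment analysis over flat gene sets
#'
#' Tests each term for over-representation of study genes against the
#' background by the hypergeometric upper tail, adjusts across all tested
#' terms by Benjamini-Hochberg, and flags terms with q at most
#' `fdrThreshold`. Terms are treated as flat sets; no ontology propagation is
#' performed.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `background`).
#' @param background character vector of background gene ids.
#' @param genesets named list of character vectors (term -> gene ids), e.g.
#'   from [readGmt()].
#' @param fdrThreshold q-value threshold for the `enriched` flag
#'   (default 0.05, inclusive).
#' @param method FDR method, see [bhFdr()].
#' @return `data.frame` with one row per term: `term`, `k`, `n`, `K`, `N`,
#'   `p_value`, `q_value`, `enriched`.
#' @export
seaEnrich <- function(study, background, genesets, fdrThreshold = 0.05,
                      method = "BH") {
    study <- unique(study); background <- unique(background)
    if (!all(study %in% background))
        stop("study genes must be a subset of the background")
    n <- length(study); N <- length(background)
    K <- unname(vapply(genesets, function(g) sum(unique(g) %in% background), 0L))
    k <- unname(vapply(genesets, function(g) sum(unique(g) %in% study), 0L))
    p <- hypergeomPvalue(k, K, n, N)
    q <- bhFdr(p, method)
    data.frame(term = names(genesets), k = k, n = n, K = K, N = N,
               p_value = p, q_value = q,
               enriched = q <= fdrThreshold,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' PageMan-style signed category z-score
#'
#' Compares the log2 fold changes of one functional category (bin) against
#' the background values by a two-sided Wilcoxon rank-sum test, then converts
#' the p-value into a signed z-score:
#' `z = sign(median(bin) - median(background)) * |qnorm(p / 2)|`.
#' Any p-value above `alpha` is set to a z-score of 0, as are bins smaller
#' than `minSize` (tiny bins are uninformative in PageMan-style displays).
#' The exact rank-sum distribution is used when both samples have fewer than
#' 50 values and there are no ties; otherwise the normal approximation with
#' continuity correction.
#'
#' @param binValues log2 fold changes of the category members.
#' @param backgroundValues log2 fold changes of the remaining genes (disjoint
#'   from the bin; must be non-empty).
#' @param alpha significance level for the zeroing rule (default 0.05).
#' @param minSize minimum bin size (default 3).
#' @return List with `p_value`, `z` and `direction`
#'   (`"up"`, `"down"` or `"none"`).
#' @export
pagemanZ <- function(binValues, backgroundValues, alpha = 0.05, minSize = 3L) {
    if (length(backgroundValues) == 0L) stop("background must be non-empty")
    if (length(binValues) < minSize)
        return(list(p_value = NA_real_, z = 0, direction = "none"))
    p <- suppressWarnings(
        wilcox.test(binValues, backgroundValues, correct = TRUE)$p.value)
    s <- sign(median(binValues) - median(backgroundValues))
    z <- if (p > alpha || s == 0) 0 else s * abs(qnorm(p / 2))
    list(p_value = p, z = z,
         direction = if (z > 0) "up" else if (z < 0) "down" else "none")
}

#' Category z-scores for a set of bins
#'
#' Applies [pagemanZ()] to every term of a gene-set map, using each gene's
#' log2 fold change; the background for a bin is all values outside the bin.
#'
#' @param values named numeric vector of per-gene log2 fold changes.
#' @param genesets named list of character vectors (term -> gene ids).
#' @param alpha,minSize see [pagemanZ()].
#' @return `data.frame` with columns `category`, `size`, `p_value`, `z`,
#'   `direction`.
#' @export
categoryZscores <- function(values, genesets, alpha = 0.05, minSize = 3L) {
    stopifnot(!is.null(names(values)))
    rows <- lapply(names(genesets), function(term) {
        inBin <- names(values) %in% genesets[[term]]
        r <- pagemanZ(values[inBin], values[!inBin], alpha, minSize)
        data.frame(category = term, size = sum(inBin), p_value = r$p_value,
                   z = r$z, direction = r$direction,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
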