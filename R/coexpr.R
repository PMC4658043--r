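#' Filter transcripts by expression floor
#'
#' Keeps genes whose replicate-mean FPKM exceeds `minFpkm` in the
#' tissue/condition cells ("FPKM > 0.1 in six samples" with the default three
#' tissues and two conditions). `scope = "all"` requires the floor in every
#' cell; `"any"` in at least one.
#'
#' @param x an [FpkmExperiment-class].
#' @param minFpkm expression floor (default 0.1, strict `>`).
#' @param scope `"all"` (default) or `"any"`.
#' @return The input experiment subset to retained genes, order preserved.
#' @export
filterExpressed <- function(x, minFpkm = 0.1, scope = c("all", "any")) {
    scope <- match.arg(scope)
    m <- collapseReplicates(x)
    keep <- if (scope == "all") rowSums(m > minFpkm) == ncol(m)
            else rowSums(m > minFpkm) > 0L
    x[keep, ]
}

#' Soft-threshold co-expression weight
#'
#' Unsigned weighted-correlation adjacency between two expression profiles:
#' `|cor(x, y)|^beta`.
#'
#' @param x,y numeric expression profiles of equal length >= 3; neither may
#'   be constant.
#' @param beta soft-threshold exponent (default 6, the usual unsigned
#'   default).
#' @return Weight in `[0, 1]`.
#' @export
coexprWeight <- function(x, y, beta = 6) {
    stopifnot(length(x) == length(y), length(x) >= 3)
    if (sd(x) == 0 || sd(y) == 0)
        stop("correlation is undefined for a constant profile")
    abs(cor(x, y))^beta
}

#' Build a co-expression network
#'
#' Averages replicates within each tissue/condition cell and computes the
#' unsigned soft-threshold adjacency `|r|^beta` for every unordered gene
#' pair over the resulting (typically six) observations.
#'
#' @param x an [FpkmExperiment-class], normally already passed through
#'   [filterExpressed()].
#' @param beta soft-threshold exponent (default 6).
#' @return A [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(x, beta = 6) {
    m <- collapseReplicates(x)
    if (nrow(m) < 2L) stop("at least 2 genes are required")
    sds <- apply(m, 1, sd)
    if (any(sds == 0))
        stop("constant expression profile(s): ",
             paste(utils::head(rownames(m)[sds == 0], 5), collapse = ", "))
    w <- abs(cor(t(m)))^beta
    diag(w) <- 1
    new("CoexpressionNetwork", weights = w, beta = beta,
        minFpkm = NA_real_)
}

#' Pathway co-expression Z-score
#'
#' Summarises how strongly a set of regulator genes is co-expressed with a
#' pathway's differentially expressed genes:
#' `Z = (Sm - mu) * m / delta`, where the candidate pairs are all
#' (pathway DEG, regulator) pairs, the selected pairs are those with weight
#' strictly above `cutoff`, `Sm` is the mean weight of the selected pairs,
#' `m` is the number of distinct regulators appearing in selected pairs, and
#' `mu`, `delta` are the mean and standard deviation of the background weight
#' population. With `background = "regulators"` (default) that population is
#' every regulator-by-network-gene pair (self-pairs excluded) — the
#' population selected pairs are drawn from; `"all_pairs"` uses all unordered
#' gene pairs of the network instead.
#'
#' If no pair exceeds the cutoff, `m = 0` and `Z = 0` (with `Sm = NA`).
#'
#' @param network a [CoexpressionNetwork-class].
#' @param pathwayDegs gene ids of the pathway's DEGs (subset of the network,
#'   disjoint from `regulators`).
#' @param regulators regulator gene ids (subset of the network).
#' @param cutoff co-expression threshold for selection (default 0.2,
#'   strict `>`).
#' @param background `"regulators"` (default) or `"all_pairs"`; see Details.
#' @return One-row `data.frame` with `m`, `Sm`, `mu`, `delta`, `Z`,
#'   `n_selected`.
#' @export
pathwayZscore <- function(network, pathwayDegs, regulators, cutoff = 0.2,
                          background = c("regulators", "all_pairs")) {
    background <- match.arg(background)
    stopifnot(is(network, "CoexpressionNetwork"))
    genes <- networkGenes(network)
    if (!all(pathwayDegs %in% genes) || !all(regulators %in% genes))
        stop("pathway DEGs and regulators must be network genes")
    if (length(intersect(pathwayDegs, regulators)))
        stop("pathway DEGs and regulators must be disjoint")
    w <- network@weights

    bg <- if (background == "regulators") {
        v <- w[regulators, , drop = FALSE]
        v[cbind(seq_along(regulators),
                match(regulators, colnames(v)))] <- NA  # drop self-pairs
        # regulator-regulator pairs appear once per unordered pair
        if (length(regulators) > 1L) {
            rr <- match(regulators, colnames(v))
            for (i in seq_along(regulators)[-1L])
                v[i, rr[seq_len(i - 1L)]] <- NA
        }
        v[!is.na(v)]
    } else {
        w[upper.tri(w)]
    }
    mu <- mean(bg)
    delta <- sd(bg)
    if (!is.finite(delta) || delta == 0)
        stop("degenerate background: zero spread in co-expression weights")

    pairW <- w[pathwayDegs, regulators, drop = FALSE]
    sel <- pairW > cutoff
    if (!any(sel)) {
        return(data.frame(m = 0L, Sm = NA_real_, mu = mu, delta = delta,
                          Z = 0, n_selected = 0L))
    }
    Sm <- mean(pairW[sel])
    m <- sum(colSums(sel) > 0L)
    data.frame(m = m, Sm = Sm, mu = mu, delta = delta,
               Z = (Sm - mu) * m / delta, n_selected = sum(sel))
}

#' Pathway Z-scores for a gene-set map
#'
#' Applies [pathwayZscore()] to every pathway, intersecting each pathway's
#' gene list with the network genes and dropping regulator overlap.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param pathways named list of character vectors (pathway -> DEG ids).
#' @param regulators regulator gene ids.
#' @param ... passed to [pathwayZscore()].
#' @return `data.frame` with one row per pathway, columns `pathway`, `m`,
#'   `Sm`, `mu`, `delta`, `Z`, `n_selected`.
#' @export
pathwayZscoreTable <- function(network, pathways, regulators, ...) {
    genes <- networkGenes(network)
    rows <- lapply(names(pathways), function(pw) {
        degs <- setdiff(intersect(pathways[[pw]], genes), regulators)
        if (length(degs) == 0L)
            return(data.frame(pathway = pw, m = 0L, Sm = NA_real_,
                              mu = NA_real_, delta = NA_real_, Z = 0,
                              n_selected = 0L))
        cbind(pathway = pw,
              pathwayZscore(network, degs, intersect(regulators, genes), ...))
    })
    do.call(rbind, rows)
}

#' Highly co-expressed regulator-gene pairs
#'
#' All (regulator, gene) pairs with weight strictly above the cutoff, sorted
#' by descending weight, then lexically by regulator and gene id.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param regulators regulator gene ids (subset of the network).
#' @param cutoff weight threshold (default 0.2, strict `>`).
#' @return `data.frame` with columns `regulator`, `gene`, `weight`.
#' @export
highCoexprPairs <- function(network, regulators, cutoff = 0.2) {
    stopifnot(is(network, "CoexpressionNetwork"))
    genes <- networkGenes(network)
    if (!all(regulators %in% genes))
        stop("regulators must be network genes")
    w <- network@weights[regulators, , drop = FALSE]
    idx <- which(w > cutoff, arr.ind = TRUE)
    df <- data.frame(regulator = regulators[idx[, 1]],
                     gene = colnames(w)[idx[, 2]],
                     weight = w[idx],
                     stringsAsFactors = FALSE)
    df <- df[df$regulator != df$gene, , drop = FALSE]
    df[order(-df$weight, df$regulator, df$gene), , drop = FALSE]
}
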