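#' @import methods
#' @importFrom stats cor cor.test median p.adjust phyper pnorm pt qnorm
#'   rnorm runif sd setNames var wilcox.test
#' @importFrom utils read.delim write.table combn
NULL

#' Canonical amino-acid alphabet
#'
#' The 20 canonical residues, used for pattern validation and for the
#' synthetic proteome generator.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
aminoAcids <- function() {
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' MotifPattern: a degenerate protein motif
#'
#' A positional pattern over amino acids defining a kinase subfamily
#' signature. Each element is either a single fixed residue, a non-empty set
#' of alternative residues, or a wildcard (any residue), represented as a
#' character vector of length 1, length > 1, or length 0 respectively.
#'
#' @slot elements list of character vectors, one per motif position.
#' @slot label subfamily name the pattern diagnoses (e.g. "ZIK").
#'
#' @seealso [parseMotifPattern()], [scanMotif()], [mapkkkMotifs()]
#' @export
setClass("MotifPattern",
    representation(elements = "list", label = "character"))

setValidity("MotifPattern", function(object) {
    msgs <- character()
    if (length(object@elements) < 5L)
        msgs <- c(msgs, "a motif needs at least 5 positions")
    if (length(object@label) != 1L || is.na(object@label))
        msgs <- c(msgs, "label must be a single string")
    ok <- vapply(object@elements, function(e) {
        is.character(e) && !anyNA(e) && all(e %in% aminoAcids()) &&
            !anyDuplicated(e)
    }, logical(1))
    if (!all(ok))
        msgs <- c(msgs,
            "every element must be a set of distinct canonical residues (empty = wildcard)")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "MotifPattern", function(object) {
    cat("MotifPattern <", object@label, ">: ",
        motifToString(object), "  (", length(object@elements),
        " positions)\n", sep = "")
})

#' @describeIn MotifPattern-class number of motif positions.
#' @param x a `MotifPattern`.
#' @export
setMethod("length", "MotifPattern", function(x) length(x@elements))

#' Motif label accessor
#'
#' @param x a [MotifPattern-class] object.
#' @return The subfamily label string.
#' @export
motifLabel <- function(x) {
    stopifnot(is(x, "MotifPattern"))
    x@label
}

#' CoexpressionNetwork: soft-threshold co-expression weights
#'
#' Symmetric gene-by-gene matrix of unsigned soft-threshold adjacency values
#' `|r|^beta`, built over the per-tissue/condition mean expression profiles of
#' the filtered transcripts.
#'
#' @slot weights symmetric numeric matrix in `[0, 1]` with unit diagonal,
#'   dimnames = gene ids.
#' @slot beta soft-threshold exponent used.
#' @slot minFpkm expression floor the genes were filtered at.
#'
#' @seealso [buildNetwork()], [pathwayZscore()], [highCoexprPairs()]
#' @export
setClass("CoexpressionNetwork",
    representation(weights = "matrix", beta = "numeric", minFpkm = "numeric"))

setValidity("CoexpressionNetwork", function(object) {
    w <- object@weights
    msgs <- character()
    if (nrow(w) != ncol(w) || is.null(rownames(w)) ||
        !identical(rownames(w), colnames(w)))
        msgs <- c(msgs, "weights must be square with matching gene dimnames")
    else {
        if (max(abs(w - t(w))) > 1e-12)
            msgs <- c(msgs, "weights must be symmetric")
        if (any(w < 0 | w > 1 + 1e-12))
            msgs <- c(msgs, "weights must lie in [0, 1]")
        if (any(abs(diag(w) - 1) > 1e-12))
            msgs <- c(msgs, "self-weights must equal 1")
    }
    if (length(object@beta) != 1L || object@beta <= 0)
        msgs <- c(msgs, "beta must be a single positive number")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "CoexpressionNetwork", function(object) {
    cat("CoexpressionNetwork with", nrow(object@weights), "genes,",
        "beta =", object@beta, "\n")
})

#' Genes in a co-expression network
#'
#' @param network a [CoexpressionNetwork-class].
#' @return Character vector of gene ids.
#' @export
networkGenes <- function(network) {
    stopifnot(is(network, "CoexpressionNetwork"))
    rownames(network@weights)
}

#' Co-expression weight lookup
#'
#' @param network a [CoexpressionNetwork-class].
#' @param g1,g2 gene ids.
#' @return The soft-threshold adjacency between `g1` and `g2`.
#' @export
networkWeight <- function(network, g1, g2) {
    stopifnot(is(network, "CoexpressionNetwork"))
    network@weights[g1, g2]
}
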