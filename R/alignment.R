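#' Simple match/mismatch scoring matrix
#'
#' @param match score for identical residues (default 1).
#' @param mismatch score for differing residues (default -1).
#' @param alphabet residue alphabet (default the 20 canonical amino acids).
#' @return Square integer scoring matrix with dimnames = alphabet.
#' @export
scoringMatrix <- function(match = 1L, mismatch = -1L, alphabet = aminoAcids()) {
    k <- length(alphabet)
    m <- matrix(as.integer(mismatch), k, k, dimnames = list(alphabet, alphabet))
    diag(m) <- as.integer(match)
    m
}

blosum62 <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            e <- new.env()
            utils::data("BLOSUM62", package = "Biostrings", envir = e)
            cache <<- e$BLOSUM62
        }
        cache
    }
})

#' Local-alignment pairwise identity
#'
#' Smith-Waterman local alignment with affine gaps (a gap of length L costs
#' `gapOpening + L * gapExtension`), scored with BLOSUM62 by default. Among
#' co-optimal alignments the one with the most identical pairs (shortest on
#' further ties) is reported, so the identity is deterministic.
#'
#' Two denominators are supported. `"alignment"` divides identical pairs by
#' the alignment length, gap columns included; it measures similarity within
#' the aligned span only, and for unrelated full-length proteins the optimal
#' local span is short and its identity is far from zero. `"shortest"`
#' divides by the length of the shorter sequence, a coverage-aware identity
#' in the spirit of whole-query BLAT identity; this is the scale on which a
#' low family-membership threshold such as 25% is meaningful (see
#' [identifyFamily()]).
#'
#' An empty optimal alignment (no positive-scoring pair) yields identity 0.
#'
#' @param a,b amino-acid strings (or objects coercible via `as.character`);
#'   uppercased on input.
#' @param substitutionMatrix square scoring matrix with residue dimnames;
#'   default BLOSUM62. See [scoringMatrix()] for simple match/mismatch
#'   scoring.
#' @param gapOpening,gapExtension affine gap penalties (positive costs);
#'   defaults 11 and 1.
#' @param denominator `"alignment"` (default) or `"shortest"`; see Details.
#' @param details if `TRUE`, return a list with `score`, `matches`, `length`
#'   and `identity` instead of the bare identity.
#' @return Identity in `[0, 1]`, or a detail list.
#' @examples
#' pairwiseIdentity("MKTAYIAKQR", "MKTAYIAKQR")            # 1
#' pairwiseIdentity("AAAA", "CCCC", scoringMatrix(1, -1))  # 0
#' @export
pairwiseIdentity <- function(a, b, substitutionMatrix = NULL,
                             gapOpening = 11, gapExtension = 1,
                             denominator = c("alignment", "shortest"),
                             details = FALSE) {
    denominator <- match.arg(denominator)
    a <- toupper(as.character(a)); b <- toupper(as.character(b))
    if (length(a) != 1L || length(b) != 1L || !nzchar(a) || !nzchar(b))
        stop("a and b must be single non-empty sequences")
    if (is.null(substitutionMatrix)) substitutionMatrix <- blosum62()
    storage.mode(substitutionMatrix) <- "integer"
    res <- .sw_identity(a, b, substitutionMatrix,
                        paste(rownames(substitutionMatrix), collapse = ""),
                        as.integer(gapOpening), as.integer(gapExtension))
    res$identity <- if (denominator == "shortest") {
        res$matches / min(nchar(a), nchar(b))
    } else res$identity
    if (details) res else res$identity
}
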