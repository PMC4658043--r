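#' Parse a degenerate motif pattern string
#'
#' Patterns use uppercase residue letters for fixed positions, `x` (either
#' case) for wildcards, and parenthesised slash-separated alternatives such as
#' `(L/V)`. Whitespace is ignored. `"GTPEFMAPE (L/V) (Y/F)"` is the ZIK
#' kinase-domain signature; see [mapkkkMotifs()] for the three built-in
#' subfamily patterns.
#'
#' @param text pattern string.
#' @param label subfamily label to attach (default `"motif"`).
#' @return A [MotifPattern-class].
#' @examples
#' parseMotifPattern("G (T/S) Px (W/F) MAPEV", label = "MEKK")
#' @export
parseMotifPattern <- function(text, label = "motif") {
    stopifnot(is.character(text), length(text) == 1L)
    chars <- strsplit(gsub("[[:space:]]", "", text), "")[[1]]
    elements <- list()
    i <- 1L
    n <- length(chars)
    while (i <= n) {
        ch <- chars[i]
        if (ch == "(") {
            close <- which(chars == ")" & seq_len(n) > i)
            if (!length(close))
                stop("unbalanced parenthesis at position ", i)
            close <- close[1L]
            inner <- chars[(i + 1L):(close - 1L)]
            alts <- strsplit(paste(inner, collapse = ""), "/", fixed = TRUE)[[1]]
            alts <- alts[nzchar(alts)]
            inner_str <- paste(inner, collapse = "")
            if (length(alts) == 0L ||
                length(alts) != length(strsplit(inner_str, "/", fixed = TRUE)[[1]]) ||
                grepl("^/|/$|//", inner_str))
                stop("empty alternative in group ending at position ", close)
            if (!all(alts %in% aminoAcids()))
                stop("non-residue character in alternative group at position ", i)
            elements <- c(elements, list(sort(unique(alts))))
            i <- close + 1L
        } else if (ch == ")") {
            stop("unbalanced parenthesis at position ", i)
        } else if (ch %in% c("x", "X")) {
            elements <- c(elements, list(character(0)))
            i <- i + 1L
        } else if (ch %in% aminoAcids()) {
            elements <- c(elements, list(ch))
            i <- i + 1L
        } else {
            stop("non-residue character '", ch, "' at position ", i)
        }
    }
    new("MotifPattern", elements = elements, label = label)
}

#' Canonical string form of a motif
#'
#' Inverse of [parseMotifPattern()] up to whitespace: fixed residues printed
#' as-is, wildcards as `x`, alternatives as `(A/B)`.
#'
#' @param pattern a [MotifPattern-class].
#' @return A single string.
#' @export
motifToString <- function(pattern) {
    stopifnot(is(pattern, "MotifPattern"))
    paste(vapply(pattern@elements, function(e) {
        if (length(e) == 0L) "x"
        else if (length(e) == 1L) e
        else paste0("(", paste(e, collapse = "/"), ")")
    }, ""), collapse = "")
}

motifRegex <- function(pattern) {
    paste(vapply(pattern@elements, function(e) {
        if (length(e) == 0L) "."
        else if (length(e) == 1L) e
        else paste0("[", paste(e, collapse = ""), "]")
    }, ""), collapse = "")
}

#' Scan a sequence for motif matches
#'
#' Finds every (possibly overlapping) start position at which all pattern
#' elements are satisfied. Sequences shorter than the pattern yield an empty
#' result, not an error.
#'
#' @param sequence amino-acid string (or an object coercible via
#'   `as.character`, e.g. an `AAString`); uppercased on input.
#' @param pattern a [MotifPattern-class].
#' @return Integer vector of 1-based match start positions.
#' @examples
#' raf <- parseMotifPattern("GTxx (W/Y) MAPE", "Raf")
#' scanMotif("MGTQKWMAPEL", raf)   # matches at position 2
#' @export
scanMotif <- function(sequence, pattern) {
    stopifnot(is(pattern, "MotifPattern"))
    s <- toupper(as.character(sequence))
    stopifnot(length(s) == 1L)
    if (nchar(s) < length(pattern)) return(integer(0))
    # lookahead so overlapping occurrences are all reported
    hits <- gregexpr(paste0("(?=", motifRegex(pattern), ")"), s, perl = TRUE)[[1]]
    if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

#' Built-in maize MAPKKK subfamily motifs
#'
#' The conserved kinase-domain signatures of the three MAPKKK subfamilies:
#' ZIK `GTPEFMAPE(L/V)(Y/F)`, MEKK `G(T/S)Px(W/F)MAPEV`, and Raf
#' `GTxx(W/Y)MAPE`.
#'
#' @return Named list of three [MotifPattern-class] objects.
#' @export
mapkkkMotifs <- function() {
    list(
        ZIK  = parseMotifPattern("GTPEFMAPE (L/V) (Y/F)", "ZIK"),
        MEKK = parseMotifPattern("G (T/S) Px (W/F) MAPEV", "MEKK"),
        Raf  = parseMotifPattern("GTxx (W/Y) MAPE", "Raf"))
}

#' Assign subfamily labels by motif scanning
#'
#' A sequence receives every label whose pattern matches at least once; an
#' empty set means unclassified. Distinct patterns can genuinely co-match
#' (the Raf signature is a degenerate superset of some MEKK instantiations),
#' so the result is a set, not a single label.
#'
#' @param sequences character vector or `AAStringSet` of protein sequences.
#' @param patterns list of [MotifPattern-class] objects with distinct labels
#'   (default [mapkkkMotifs()]).
#' @return Named list (by sequence name, if any) of character vectors of
#'   matching labels.
#' @export
classifySubfamily <- function(sequences, patterns = mapkkkMotifs()) {
    labels <- vapply(patterns, motifLabel, "")
    if (anyDuplicated(labels)) stop("pattern labels must be distinct")
    seqs <- as.character(sequences)
    out <- lapply(seqs, function(s) {
        hit <- vapply(patterns, function(p) length(scanMotif(s, p)) > 0L,
                      logical(1))
        unname(labels[hit])
    })
    names(out) <- names(sequences)
    out
}
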