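#' Identify gene-family members by identity threshold and hit count
#'
#' A candidate is a family member when at least `minHits` distinct query
#' sequences each align to it with pairwise identity strictly above
#' `identityThreshold`. This operationalises homology search against a panel
#' of known family members (e.g. Arabidopsis and rice MAPKKKs) with a 25%
#' identity floor and a minimum of 5 qualifying hits.
#'
#' Identity is coverage-aware by default (`denominator = "shortest"`,
#' identical pairs over the shorter sequence length): within-span identity of
#' an optimal local alignment of two *unrelated* proteins is typically well
#' above 25% over a short segment, so the aligned-span identity cannot
#' discriminate family members at so low a threshold; coverage-aware identity
#' can. See [pairwiseIdentity()].
#'
#' Subfamily labels are assigned by degenerate motif scanning
#' ([classifySubfamily()]). Chromosome labels are taken from a `chrom=` key in
#' the FASTA description line when present, else `"unknown"`.
#'
#' @param candidates,queries named character vectors or `AAStringSet`s of
#'   protein sequences; `queries` must be non-empty.
#' @param identityThreshold identity a query hit must exceed (default 0.25,
#'   strict `>`).
#' @param minHits qualifying hits needed for membership (default 5,
#'   inclusive `>=`).
#' @param patterns subfamily motif list for classification (default
#'   [mapkkkMotifs()]); `NULL` skips classification.
#' @param denominator identity denominator, passed to [pairwiseIdentity()].
#' @param ... further arguments (scoring) for [pairwiseIdentity()].
#' @return `data.frame` in candidate input order with columns `candidate_id`,
#'   `qualifying_hits`, `is_member`, `subfamilies` (comma-joined label set,
#'   `""` if unclassified), `chromosome`.
#' @export
identifyFamily <- function(candidates, queries,
                           identityThreshold = 0.25, minHits = 5L,
                           patterns = mapkkkMotifs(),
                           denominator = "shortest", ...) {
    stopifnot(identityThreshold > 0, identityThreshold <= 1, minHits >= 1L)
    if (length(queries) == 0L) stop("queries must be non-empty")
    chrom <- fastaChromosomes(candidates)
    cand <- as.character(candidates)
    names(cand) <- names(candidates)  # as.character drops names
    qry <- as.character(queries)
    # FASTA convention: the id is the first whitespace-delimited token
    ids <- if (is.null(names(cand))) paste0("seq", seq_along(cand))
           else sub("[[:space:]].*$", "", names(cand))

    hits <- vapply(cand, function(cs) {
        sum(vapply(qry, function(qs)
            pairwiseIdentity(cs, qs, denominator = denominator, ...) >
                identityThreshold, logical(1)))
    }, integer(1), USE.NAMES = FALSE)

    subfam <- if (is.null(patterns)) rep("", length(cand)) else
        vapply(classifySubfamily(cand, patterns), paste, "", collapse = ",")

    data.frame(candidate_id = ids,
               qualifying_hits = hits,
               is_member = hits >= minHits,
               subfamilies = subfam,
               chromosome = chrom,
               stringsAsFactors = FALSE)
}

# chromosome from a "chrom=<label>" key in FASTA description lines
fastaChromosomes <- function(sequences) {
    nm <- names(sequences)
    if (is.null(nm)) return(rep("unknown", length(sequences)))
    m <- regmatches(nm, regexpr("chrom=[^[:space:]]+", nm))
    out <- rep("unknown", length(sequences))
    has <- grepl("chrom=", nm, fixed = TRUE)
    out[has] <- sub("^chrom=", "", m)
    out
}

#' Chromosome distribution of family members
#'
#' Counts members per chromosome label, including an `"unknown"` bucket for
#' members whose chromosome is undetermined. Non-members are ignored; the
#' counts sum to the number of members.
#'
#' @param assignments `data.frame` from [identifyFamily()] (needs `is_member`
#'   and `chromosome` columns).
#' @return Named integer vector of member counts per chromosome label; empty
#'   when there are no members.
#' @export
chromosomeDistribution <- function(assignments) {
    members <- assignments[assignments$is_member, , drop = FALSE]
    if (nrow(members) == 0L) return(setNames(integer(0), character(0)))
    tab <- table(members$chromosome)
    setNames(as.integer(tab), names(tab))
}

#' Write a family-identification report
#'
#' @param assignments `data.frame` from [identifyFamily()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeFamilyReport <- function(assignments, path) {
    write.table(assignments, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
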