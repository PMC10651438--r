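## Internal helpers shared across modules.

## Canonical triple key used for dedup and membership tests.
.tripleKey <- function(head, relation, tail)
    paste(head, relation, tail, sep = "\r")

#' Normalize an identifier to CURIE form
#'
#' Converts underscore-separated identifiers (`"OGG_3000007157"`) to the
#' canonical colon form (`"OGG:3000007157"`). Identifiers already containing a
#' colon are returned unchanged. Comparison of CURIEs is case-sensitive
#' throughout the package.
#'
#' @param x character vector of identifiers.
#' @return character vector of normalized CURIEs.
#' @examples
#' normalizeCurie(c("OGG_3000007157", "DOID:1612"))
#' @export
normalizeCurie <- function(x) {
    noColon <- !grepl(":", x, fixed = TRUE)
    x[noColon] <- sub("_", ":", x[noColon])
    x
}

## Prefix of a normalized CURIE.
.curiePrefix <- function(curie) sub(":.*$", "", curie)

## Empty triple table with the right columns.
.emptyTriples <- function()
    data.frame(head = character(0), relation = character(0),
               tail = character(0), stringsAsFactors = FALSE)

.emptyTerms <- function()
    data.frame(curie = character(0), label = character(0),
               namespace = character(0), stringsAsFactors = FALSE)

## Deduplicate triples, keeping first occurrence (insertion order).
.dedupTriples <- function(triples) {
    if (!nrow(triples)) return(triples)
    keep <- !duplicated(.tripleKey(triples$head, triples$relation,
                                   triples$tail))
    out <- triples[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

.assertScalarString <- function(x, what) {
    if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
        stop(what, " must be a single non-empty string", call. = FALSE)
}
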