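#' Construct a KnowledgeGraph
#'
#' Builds a validated [KnowledgeGraph-class] from a term table and a triple
#' table. Duplicate triples are dropped (first occurrence wins, so insertion
#' order is preserved); everything else must satisfy the class invariants.
#'
#' @param terms data.frame with columns `curie`, `label`, `namespace`. Missing
#'   `label`/`namespace` columns are filled (empty label; namespace from the
#'   CURIE prefix).
#' @param triples data.frame with columns `head`, `relation`, `tail`;
#'   relations must be `"subclass_of"` or `"associated"`.
#' @return a `KnowledgeGraph`.
#' @examples
#' kg <- KnowledgeGraph(
#'     terms = data.frame(curie = c("G:1", "G:2")),
#'     triples = data.frame(head = "G:2", relation = "subclass_of",
#'                          tail = "G:1"))
#' numTriples(kg)
#' @export
KnowledgeGraph <- function(terms = .emptyTerms(), triples = .emptyTriples()) {
    terms <- as.data.frame(terms, stringsAsFactors = FALSE)
    if (!"curie" %in% names(terms))
        stop("terms must have a 'curie' column")
    terms$curie <- as.character(terms$curie)
    if (!"label" %in% names(terms)) terms$label <- ""
    if (!"namespace" %in% names(terms))
        terms$namespace <- .curiePrefix(terms$curie)
    terms <- terms[, c("curie", "label", "namespace")]
    rownames(terms) <- NULL
    triples <- as.data.frame(triples, stringsAsFactors = FALSE)
    if (nrow(triples)) {
        triples <- triples[, c("head", "relation", "tail")]
        triples[] <- lapply(triples, as.character)
    } else {
        triples <- .emptyTriples()
    }
    new("KnowledgeGraph", terms = terms, triples = .dedupTriples(triples))
}

#' @describeIn KnowledgeGraph-class term table accessor
#' @param x,object a `KnowledgeGraph`.
#' @export
kgTerms <- function(x) x@terms

#' @describeIn KnowledgeGraph-class triple table accessor
#' @export
kgTriples <- function(x) x@triples

#' @describeIn KnowledgeGraph-class entity CURIEs, in term order
#' @export
entityNames <- function(x) x@terms$curie

#' @describeIn KnowledgeGraph-class number of terms
#' @export
numTerms <- function(x) nrow(x@terms)

#' @describeIn KnowledgeGraph-class number of triples
#' @export
numTriples <- function(x) nrow(x@triples)

#' @describeIn KnowledgeGraph-class subset of `subclass_of` triples
#' @export
subclassTriples <- function(x) {
    tr <- x@triples[x@triples$relation == "subclass_of", , drop = FALSE]
    rownames(tr) <- NULL
    tr
}

#' @describeIn KnowledgeGraph-class subset of `associated` triples
#' @export
associatedTriples <- function(x) {
    tr <- x@triples[x@triples$relation == "associated", , drop = FALSE]
    rownames(tr) <- NULL
    tr
}

setMethod("show", "KnowledgeGraph", function(object) {
    ns <- table(object@terms$namespace)
    rel <- table(factor(object@triples$relation, levels = .KG_RELATIONS))
    cat("KnowledgeGraph with", nrow(object@terms), "terms and",
        nrow(object@triples), "triples\n")
    cat("  namespaces:",
        paste(sprintf("%s (%d)", names(ns), as.integer(ns)),
              collapse = ", "), "\n")
    cat("  relations: subclass_of (", rel[["subclass_of"]],
        "), associated (", rel[["associated"]], ")\n", sep = "")
})

## Check two KGs share no namespace (precondition for joining).
.namespaceDisjoint <- function(kg1, kg2)
    !length(intersect(unique(kg1@terms$namespace),
                      unique(kg2@terms$namespace)))
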