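#' @import methods
NULL

## Relation vocabulary used throughout. Intra-ontology hierarchy edges and
## cross-ontology association edges are the only two relation types.
.KG_RELATIONS <- c("subclass_of", "associated")

#' KnowledgeGraph: terms plus a duplicate-free, insertion-ordered triple set
#'
#' A `KnowledgeGraph` holds the concepts (terms) of one or more ontologies and
#' a set of directed triples over two relations: `subclass_of` (the is_a
#' hierarchy inside one ontology) and `associated` (cross-ontology bridge
#' edges, stored in both directions). Terms are identified by CURIEs in
#' normalized `PREFIX:LOCAL` form; a term's namespace is its CURIE prefix.
#'
#' Validity enforces: unique, well-formed CURIEs; triples referencing known
#' terms only; no duplicate triples; `subclass_of` restricted to
#' same-namespace pairs with head != tail; `associated` restricted to
#' cross-namespace pairs.
#'
#' @slot terms data.frame with columns `curie`, `label`, `namespace`.
#' @slot triples data.frame with columns `head`, `relation`, `tail`;
#'   insertion-ordered and duplicate-free.
#'
#' @seealso [KnowledgeGraph()] for construction, [parseOBO()],
#'   [parseEdgeList()], [buildJointKG()]
#' @exportClass KnowledgeGraph
setClass("KnowledgeGraph",
    representation(terms = "data.frame", triples = "data.frame"))

setValidity("KnowledgeGraph", function(object) {
    tm <- object@terms
    tr <- object@triples
    msgs <- character(0)
    need <- c("curie", "label", "namespace")
    if (!all(need %in% names(tm)))
        return(paste("terms must have columns", paste(need, collapse = ", ")))
    if (!all(c("head", "relation", "tail") %in% names(tr)))
        return("triples must have columns head, relation, tail")
    if (anyDuplicated(tm$curie))
        msgs <- c(msgs, "duplicate term CURIEs")
    bad <- !grepl("^[^:[:space:]]+:[^:[:space:]]+$", tm$curie)
    if (any(bad))
        msgs <- c(msgs, paste("malformed CURIE:", tm$curie[bad][1L]))
    if (nrow(tr)) {
        if (!all(tr$relation %in% .KG_RELATIONS))
            msgs <- c(msgs, "relation outside {subclass_of, associated}")
        miss <- setdiff(c(tr$head, tr$tail), tm$curie)
        if (length(miss))   # later checks need resolvable endpoints
            return(paste("triple endpoint not in terms:", miss[1L]))
        if (anyDuplicated(paste(tr$head, tr$relation, tr$tail, sep = "\r")))
            msgs <- c(msgs, "duplicate triples")
        ns <- stats::setNames(tm$namespace, tm$curie)
        sub <- tr$relation == "subclass_of"
        if (any(sub & tr$head == tr$tail))
            msgs <- c(msgs, "subclass_of triple with head == tail")
        if (any(sub & ns[tr$head] != ns[tr$tail]))
            msgs <- c(msgs, "subclass_of triple across namespaces")
        asc <- tr$relation == "associated"
        if (any(asc & ns[tr$head] == ns[tr$tail]))
            msgs <- c(msgs, "associated triple within one namespace")
    }
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' EmbeddingModel: per-family KGE parameter store
#'
#' Holds the learned parameters of one knowledge-graph-embedding family over a
#' fixed entity and relation vocabulary. The parameter list layout depends on
#' the family:
#' \describe{
#'   \item{UM}{`E` (entities x dim, real). Relation-blind.}
#'   \item{TorusE}{`E`, `R` with all coordinates on the unit torus `[0,1)`.}
#'   \item{RotatE}{`Ere`/`Eim` complex entity parts; `Rphase` relation phases
#'     (implied rotation moduli exactly 1).}
#'   \item{PairRE}{`E` (rows L2-normalized to 1), `RH`, `RT`.}
#'   \item{ComplEx}{`Ere`/`Eim`, `Rre`/`Rim`.}
#'   \item{SimplE}{dual role matrices `Eh`/`Et` plus `R`/`Rinv`.}
#'   \item{KG2E}{diagonal Gaussians: means `Emu`/`Rmu` and diagonal variances
#'     `Ev`/`Rv` clamped to `[cMin, cMax]`.}
#' }
#'
#' @slot family one of `"UM"`, `"TorusE"`, `"RotatE"`, `"PairRE"`,
#'   `"ComplEx"`, `"SimplE"`, `"KG2E"`.
#' @slot dim embedding dimension.
#' @slot entities character vector of entity CURIEs (row order of the
#'   parameter matrices).
#' @slot relations character vector of relation names.
#' @slot params named list of numeric matrices (see Description).
#' @slot config training configuration list, see [kgeConfig()].
#'
#' @seealso [initModel()], [trainModel()], [scoreTriples()]
#' @exportClass EmbeddingModel
setClass("EmbeddingModel",
    representation(family = "character", dim = "integer",
                   entities = "character", relations = "character",
                   params = "list", config = "list"))

.KGE_FAMILIES <- c("UM", "TorusE", "RotatE", "PairRE", "ComplEx", "SimplE",
                   "KG2E")

setValidity("EmbeddingModel", function(object) {
    if (!(object@family %in% .KGE_FAMILIES))
        return(paste("unknown family:", object@family))
    if (length(object@dim) != 1L || object@dim < 1L)
        return("dim must be a single positive integer")
    if (anyDuplicated(object@entities))
        return("duplicate entity names")
    pr <- object@params
    ne <- length(object@entities)
    for (nm in names(pr)) {
        if (!is.matrix(pr[[nm]]) || ncol(pr[[nm]]) != object@dim)
            return(paste("parameter", nm, "is not a matrix with dim columns"))
    }
    if (object@family == "TorusE") {
        for (nm in c("E", "R"))
            if (any(pr[[nm]] < 0 | pr[[nm]] >= 1))
                return("TorusE coordinates outside [0,1)")
    }
    if (object@family == "KG2E") {
        cl <- object@config
        for (nm in c("Ev", "Rv"))
            if (any(pr[[nm]] <= 0))
                return("KG2E variance at or below 0")
    }
    if (ne && !all(vapply(pr[.entityParamNames(object@family)], nrow,
                          integer(1)) == ne))
        return("entity parameter row count != number of entities")
    TRUE
})

#' RankingReport: rank-based link-prediction metrics
#'
#' Result container for [evaluateRanking()]: mean rank (MR), mean reciprocal
#' rank (MRR) and Hits@k for k in {1,3,5}, together with the protocol and the
#' corruption sides that produced them.
#'
#' @slot mr mean rank (>= 1).
#' @slot mrr mean reciprocal rank in (0, 1].
#' @slot hits named numeric vector (`"1"`, `"3"`, `"5"`), fractions in [0,1].
#' @slot protocol `"raw"` or `"filtered"`.
#' @slot sides `"head"`, `"tail"` or `"both"`.
#' @slot nEvaluated number of pooled ranking cases.
#'
#' @exportClass RankingReport
setClass("RankingReport",
    representation(mr = "numeric", mrr = "numeric", hits = "numeric",
                   protocol = "character", sides = "character",
                   nEvaluated = "integer"))

setValidity("RankingReport", function(object) {
    h <- object@hits
    if (!all(c("1", "3", "5") %in% names(h)))
        return("hits must be named '1','3','5'")
    if (is.unsorted(h[c("1", "3", "5")]))
        return("hits@k must be non-decreasing in k")
    if (any(h < 0 | h > 1))
        return("hits@k outside [0,1]")
    if (object@mr < 1)
        return("mean rank below 1")
    if (object@mrr < h[["1"]] - 1e-12)
        return("MRR below Hits@1")
    if (!(object@protocol %in% c("raw", "filtered")))
        return("protocol must be raw or filtered")
    TRUE
})
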