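## Rank-based link-prediction evaluation: MR, MRR, Hits@k under raw and
## filtered protocols, with head- and/or tail-corruption.

#' Evaluation configuration
#'
#' @param candidates `"all-entities"` (every model entity competes for the
#'   corrupted slot) or `"type-constrained"` (only entities sharing the true
#'   entity's namespace compete).
#' @param tiePolicy how rank ties on equal scores are resolved: `"average"`
#'   (mean of the optimistic and pessimistic rank), `"optimistic"`,
#'   `"pessimistic"`.
#' @param protocol `"filtered"` (candidates forming known positive triples
#'   are removed before ranking, never the true entity) or `"raw"`.
#' @param sides corrupt the `"head"`, the `"tail"`, or `"both"` (ranks
#'   pooled).
#' @return named list of class `evalConfig`.
#' @export
evalConfig <- function(candidates = c("all-entities", "type-constrained"),
                       tiePolicy = c("average", "optimistic", "pessimistic"),
                       protocol = c("filtered", "raw"),
                       sides = c("both", "head", "tail")) {
    cfg <- list(candidates = match.arg(candidates),
                tiePolicy = match.arg(tiePolicy),
                protocol = match.arg(protocol),
                sides = match.arg(sides))
    class(cfg) <- "evalConfig"
    cfg
}

## Rank of the true score among candidate scores under a tie policy.
.rankOf <- function(sTrue, sCand, tiePolicy) {
    better <- sum(sCand > sTrue)
    ties <- sum(sCand == sTrue)
    switch(tiePolicy,
        optimistic = better + 1,
        pessimistic = better + ties + 1,
        average = better + ties / 2 + 1)
}

#' Rank the true entity of one triple against corrupted candidates
#'
#' Scores every candidate replacement of the corrupted slot, then ranks the
#' true entity (higher score = better rank). The filtered rank is recomputed
#' after removing candidates that form known positive triples — never the
#' true entity itself — so the filtered rank is always <= the raw rank.
#'
#' @param model an [EmbeddingModel-class].
#' @param triple character vector `c(head, relation, tail)` or one-row
#'   data.frame.
#' @param side which slot is corrupted: `"head"` or `"tail"`.
#' @param candidates character vector of candidate entities for the corrupted
#'   slot; must contain the true entity. Defaults to all model entities.
#' @param filterSet data.frame of known positive triples (columns `head`,
#'   `relation`, `tail`) used by the filtered protocol; typically training
#'   plus test triples.
#' @param tiePolicy `"average"`, `"optimistic"` or `"pessimistic"`.
#' @return named numeric vector `c(raw = ..., filtered = ...)`.
#' @export
rankTriple <- function(model, triple, side = c("tail", "head"),
                       candidates = modelEntities(model),
                       filterSet = NULL,
                       tiePolicy = c("average", "optimistic",
                                     "pessimistic")) {
    side <- match.arg(side)
    tiePolicy <- match.arg(tiePolicy)
    if (is.data.frame(triple))
        triple <- c(triple$head[1L], triple$relation[1L], triple$tail[1L])
    truth <- if (side == "head") triple[1L] else triple[3L]
    if (!(truth %in% candidates))
        stop("true entity ", truth, " not among candidates")
    rIdx <- if (model@family == "UM") 1L else
        .relationIdx(model, triple[2L])
    cIdx <- .entityIdx(model, candidates)
    fixedIdx <- .entityIdx(model, if (side == "head") triple[3L] else
                                      triple[1L])
    sCand <- if (side == "head")
        .scoreIdx(model@family, model@params, cIdx,
                  rep_len(rIdx, length(cIdx)), rep_len(fixedIdx, length(cIdx)))
    else
        .scoreIdx(model@family, model@params, rep_len(fixedIdx, length(cIdx)),
                  rep_len(rIdx, length(cIdx)), cIdx)
    isTrue <- candidates == truth
    sTrue <- sCand[which(isTrue)[1L]]
    raw <- .rankOf(sTrue, sCand[!isTrue], tiePolicy)
    filtered <- raw
    if (!is.null(filterSet) && nrow(filterSet)) {
        if (side == "head") {
            knownEnts <- filterSet$head[filterSet$relation == triple[2L] &
                                        filterSet$tail == triple[3L]]
        } else {
            knownEnts <- filterSet$tail[filterSet$relation == triple[2L] &
                                        filterSet$head == triple[1L]]
        }
        drop <- !isTrue & candidates %in% knownEnts
        filtered <- .rankOf(sTrue, sCand[!isTrue & !drop], tiePolicy)
    }
    c(raw = raw, filtered = filtered)
}

#' Summarize pooled ranks into MR, MRR and Hits@k
#'
#' @param ranks numeric vector of ranks (>= 1).
#' @param ks Hits@k cutoffs (default 1, 3, 5).
#' @return list with `mr`, `mrr` and named `hits`.
#' @examples
#' rankingMetrics(c(1, 2, 10))  # MR 13/3, MRR 0.5333..., Hits@1 1/3
#' @export
rankingMetrics <- function(ranks, ks = c(1L, 3L, 5L)) {
    if (!length(ranks)) stop("no ranks to summarize")
    hits <- vapply(ks, function(k) mean(ranks <= k), numeric(1))
    list(mr = mean(ranks), mrr = mean(1 / ranks),
         hits = stats::setNames(hits, as.character(ks)))
}

#' Evaluate link prediction on a test triple set
#'
#' For every test triple, ranks the head-corruption and/or tail-corruption
#' case and pools all ranks into a [RankingReport-class]: MR (mean rank), MRR
#' (mean reciprocal rank) and Hits@k for k in {1,3,5}. Under the filtered
#' protocol the filter set is the union of training and test triples (all
#' known positives), so ranking is never penalized for preferring another
#' true association.
#'
#' @param model an [EmbeddingModel-class].
#' @param testTriples data.frame of test triples (columns `head`, `relation`,
#'   `tail`), disjoint from the training triples.
#' @param trainKG the training [KnowledgeGraph-class].
#' @param config an [evalConfig()].
#' @return a [RankingReport-class].
#' @export
evaluateRanking <- function(model, testTriples, trainKG,
                            config = evalConfig()) {
    if (is.null(testTriples) || !nrow(testTriples))
        stop("empty test set")
    filterSet <- if (config$protocol == "filtered")
        rbind(kgTriples(trainKG)[, c("head", "relation", "tail")],
              testTriples[, c("head", "relation", "tail")])
    else NULL
    ns <- stats::setNames(kgTerms(trainKG)$namespace, kgTerms(trainKG)$curie)
    allEnts <- modelEntities(model)
    sides <- switch(config$sides, both = c("head", "tail"),
                    head = "head", tail = "tail")
    ranks <- numeric(0)
    for (side in sides) {
        for (i in seq_len(nrow(testTriples))) {
            tri <- c(testTriples$head[i], testTriples$relation[i],
                     testTriples$tail[i])
            truth <- if (side == "head") tri[1L] else tri[3L]
            cand <- if (config$candidates == "type-constrained")
                allEnts[ns[allEnts] == ns[[truth]]]
            else allEnts
            rk <- rankTriple(model, tri, side = side, candidates = cand,
                             filterSet = filterSet,
                             tiePolicy = config$tiePolicy)
            ranks <- c(ranks,
                       rk[[if (config$protocol == "filtered") "filtered"
                           else "raw"]])
        }
    }
    met <- rankingMetrics(ranks)
    new("RankingReport", mr = met$mr, mrr = met$mrr, hits = met$hits,
        protocol = config$protocol, sides = config$sides,
        nEvaluated = length(ranks))
}

setMethod("show", "RankingReport", function(object) {
    cat("RankingReport (", object@protocol, ", sides = ", object@sides,
        ", n = ", object@nEvaluated, ")\n", sep = "")
    cat(sprintf("  MR %.2f | MRR %.4f | Hits@1 %.4f  @3 %.4f  @5 %.4f\n",
                object@mr, object@mrr, object@hits[["1"]],
                object@hits[["3"]], object@hits[["5"]]))
})

#' @describeIn RankingReport-class metrics as a one-row data.frame
#' @param x a `RankingReport`.
#' @export
reportMetrics <- function(x)
    data.frame(mr = x@mr, mrr = x@mrr, hits1 = x@hits[["1"]],
               hits3 = x@hits[["3"]], hits5 = x@hits[["5"]],
               protocol = x@protocol, sides = x@sides,
               n = x@nEvaluated, row.names = NULL)

#' Format several ranking reports as a plain-text comparison table
#'
#' One row per method, columns MR, MRR, Hits@1/3/5 — the conventional layout
#' for comparing KGE families on one benchmark.
#'
#' @param reports named list of [RankingReport-class] objects (names are the
#'   method labels).
#' @return character vector of table lines (also printed).
#' @export
reportTable <- function(reports) {
    rows <- vapply(names(reports), function(nm) {
        r <- reports[[nm]]
        sprintf("%-8s %10.3f %8.4f %8.4f %8.4f %8.4f", nm, r@mr, r@mrr,
                r@hits[["1"]], r@hits[["3"]], r@hits[["5"]])
    }, character(1))
    out <- c(sprintf("%-8s %10s %8s %8s %8s %8s", "method", "MR", "MRR",
                     "Hits@1", "Hits@3", "Hits@5"), rows)
    cat(out, sep = "\n")
    invisible(out)
}
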