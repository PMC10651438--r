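## Bridge selection and joint-KG assembly.
##
## A "bridge" is an associated edge between a gene-ontology term and a
## disease-ontology term, derived from corpus mention counts. Bridges join
## two otherwise disjoint hierarchies into one knowledge graph; association
## edges are stored in both directions because gene-disease association is
## bidirectional, which matters for embedding models.

#' Select the top-K most-mentioned gene-disease pairs as bridge candidates
#'
#' Returns the `k` pairs with highest association mention count. Selection is
#' deterministic: pairs are sorted by support descending, then by
#' `gene_id` ascending, then `disease_id` ascending (C-locale lexicographic
#' tie-break). Because the sort is total, the selection is prefix-monotone:
#' the top-45 set is always contained in the top-120 set.
#'
#' @param counts data.frame from [countAssociations()] (columns `gene_id`,
#'   `disease_id`, `count`).
#' @param k number of pairs to select (>= 1). If fewer than `k` pairs exist,
#'   all are returned with a warning. `k = Inf` selects all pairs.
#' @return data.frame with columns `gene_id`, `disease_id`, `support`, in
#'   selection order.
#' @export
selectBridges <- function(counts, k) {
    if (is.null(counts) || !nrow(counts))
        stop("selectBridges: empty count table")
    if (!is.infinite(k) && (length(k) != 1L || k < 1))
        stop("k must be a single integer >= 1 (or Inf for all)")
    ord <- order(-counts$count, counts$gene_id, counts$disease_id,
                 method = "radix")
    counts <- counts[ord, , drop = FALSE]
    kk <- min(k, nrow(counts))
    if (is.finite(k) && kk < k)
        warning("only ", kk, " pairs available; requested k = ", k)
    out <- data.frame(gene_id = counts$gene_id[seq_len(kk)],
                      disease_id = counts$disease_id[seq_len(kk)],
                      support = counts$count[seq_len(kk)],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

.asCurieMap <- function(map, what) {
    if (is.data.frame(map)) {
        if (!all(c("id", "curie") %in% names(map)))
            stop(what, " map must have columns id, curie")
        map <- stats::setNames(as.character(map$curie), as.character(map$id))
    }
    if (anyDuplicated(names(map)))
        stop(what, " map is not single-valued")
    map
}

#' Read a two-column id-to-CURIE mapping table
#'
#' @param path TSV with columns `id` and `curie` (header required).
#' @return named character vector (names are source ids, values CURIEs).
#' @export
readCurieMap <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    .asCurieMap(df, path)
}

#' Map selected gene-disease pairs to ontology-term bridges
#'
#' Resolves each selected pair to a pair of ontology CURIEs through the
#' supplied id-to-CURIE maps. Pairs whose gene and disease both map to a term
#' present in the respective knowledge graph become bridges; all others are
#' returned in `unmapped` (never silently dropped). Partial mapping is a
#' normal outcome: corpora mention many more pairs than any curated map
#' covers.
#'
#' @param pairs data.frame from [selectBridges()].
#' @param geneMap,diseaseMap named character vectors (or `id`/`curie`
#'   data.frames) mapping source-vocabulary ids to ontology CURIEs.
#' @param geneKG,diseaseKG the two ontology [KnowledgeGraph-class] objects.
#' @param oggHeuristic if `TRUE`, a gene id absent from `geneMap` is tried as
#'   `OGG:3000<id>` (the OGG convention of embedding the NCBI gene id);
#'   applied only when that CURIE resolves in `geneKG`. Off by default.
#' @return list with data.frames `bridges` (`gene_curie`, `disease_curie`,
#'   `support`) and `unmapped` (the untranslatable rows of `pairs`).
#' @export
mapPairsToBridges <- function(pairs, geneMap, diseaseMap, geneKG, diseaseKG,
                              oggHeuristic = FALSE) {
    geneMap <- .asCurieMap(geneMap, "gene")
    diseaseMap <- .asCurieMap(diseaseMap, "disease")
    gCur <- unname(geneMap[as.character(pairs$gene_id)])
    if (oggHeuristic) {
        tryC <- paste0("OGG:3000", pairs$gene_id)
        use <- is.na(gCur) & tryC %in% entityNames(geneKG)
        gCur[use] <- tryC[use]
    }
    dCur <- unname(diseaseMap[as.character(pairs$disease_id)])
    ok <- !is.na(gCur) & !is.na(dCur) &
        gCur %in% entityNames(geneKG) & dCur %in% entityNames(diseaseKG)
    bridges <- data.frame(gene_curie = gCur[ok], disease_curie = dCur[ok],
                          support = pairs$support[ok],
                          stringsAsFactors = FALSE)
    unmapped <- pairs[!ok, , drop = FALSE]
    rownames(bridges) <- rownames(unmapped) <- NULL
    list(bridges = bridges, unmapped = unmapped)
}

#' Assemble the joint gene-disease knowledge graph
#'
#' Unions the subclass triples of the two (namespace-disjoint) ontologies and
#' adds, for every bridge, both directed `associated` triples
#' `(gene, associated, disease)` and `(disease, associated, gene)`. After
#' deduplication the triple count equals `|S1| + |S2| + 2 * B` for `S1`, `S2`
#' the two subclass sets and `B` the number of distinct bridges, and the
#' `associated` relation is exactly symmetric.
#'
#' @param geneKG,diseaseKG the two ontology [KnowledgeGraph-class] objects;
#'   their namespaces must be disjoint.
#' @param bridges data.frame with columns `gene_curie`, `disease_curie`
#'   (e.g. from [mapPairsToBridges()]).
#' @return the joint [KnowledgeGraph-class].
#' @export
buildJointKG <- function(geneKG, diseaseKG, bridges) {
    if (!.namespaceDisjoint(geneKG, diseaseKG))
        stop("gene and disease KGs share a namespace")
    missG <- setdiff(bridges$gene_curie, entityNames(geneKG))
    if (length(missG))
        stop("bridge endpoint not in gene KG: ", missG[1L])
    missD <- setdiff(bridges$disease_curie, entityNames(diseaseKG))
    if (length(missD))
        stop("bridge endpoint not in disease KG: ", missD[1L])
    terms <- rbind(kgTerms(geneKG), kgTerms(diseaseKG))
    n <- nrow(bridges)
    assoc <- if (n) {
        both <- data.frame(
            head = c(bridges$gene_curie, bridges$disease_curie),
            relation = "associated",
            tail = c(bridges$disease_curie, bridges$gene_curie),
            stringsAsFactors = FALSE)
        ## interleave so both directions of a bridge stay adjacent
        both[as.vector(rbind(seq_len(n), seq_len(n) + n)), , drop = FALSE]
    } else .emptyTriples()
    KnowledgeGraph(terms, rbind(subclassTriples(geneKG),
                                subclassTriples(diseaseKG), assoc))
}

## Undirected pair key for an associated triple: endpoints in sorted order.
.pairKey <- function(head, tail)
    paste(pmin(head, tail), pmax(head, tail), sep = "\r")

#' Split associated triples into train and test by undirected pair
#'
#' Holds out a seeded random fraction of the *undirected* associated pairs as
#' test triples: both directions of a held-out pair leave the training graph
#' together, so the bidirectional duplicate of a test edge can never leak into
#' training. All subclass triples stay in the training graph.
#'
#' @param kg joint [KnowledgeGraph-class] containing associated triples.
#' @param testFraction fraction of undirected pairs held out, in (0, 1).
#' @param seed integer seed.
#' @return list with `train` (a `KnowledgeGraph`) and `test` (data.frame of
#'   directed associated triples).
#' @export
splitAssociatedTriples <- function(kg, testFraction, seed) {
    assoc <- associatedTriples(kg)
    if (!nrow(assoc)) stop("no associated triples to split")
    if (testFraction <= 0 || testFraction >= 1)
        stop("testFraction must be in (0, 1)")
    keys <- .pairKey(assoc$head, assoc$tail)
    pairIds <- unique(keys)
    nTest <- max(1L, round(testFraction * length(pairIds)))
    testPairs <- withr::with_seed(seed, sample(pairIds, nTest))
    isTest <- keys %in% testPairs
    test <- assoc[isTest, , drop = FALSE]
    rownames(test) <- NULL
    trainTriples <- rbind(subclassTriples(kg), assoc[!isTest, , drop = FALSE])
    list(train = KnowledgeGraph(kgTerms(kg), trainTriples), test = test)
}
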