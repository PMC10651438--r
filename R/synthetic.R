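## Seeded synthetic generators: ontology trees, sentence corpora with a
## Zipf-shaped pair-mention law, and planted-block association graphs. These
## emulate the statistical shape of the real inputs (two subclass
## hierarchies; an NA-dominated sentence corpus over gene-disease pairs; a
## long-tailed mention distribution) so the full pipeline runs and is
## testable with no downloads.

#' Specification of a synthetic study
#'
#' Bundles the generator parameters. The defaults are the fixed study
#' conditions used throughout the package's benchmarks: 200 terms per
#' ontology with branching factor 4, four latent blocks, 1000 planted
#' associated pairs (2000 directed triples), a 20% pair-level test split,
#' Zipf exponent 1.1 for mention counts and an NA fraction of 0.5 over 4000
#' sentences.
#'
#' @param nGeneTerms,nDiseaseTerms ontology sizes.
#' @param branching maximum children per term in the generated trees.
#' @param nSentences corpus size (sentences).
#' @param nTruePairs number of planted associated gene-disease pairs.
#' @param zipfExponent exponent of the Zipf law governing per-pair non-NA
#'   mention counts (larger = heavier head).
#' @param naFraction fraction of sentences with the `NA` label, in [0, 1).
#' @param nBlocks number of latent blocks for the planted association
#'   structure (>= 2).
#' @param testFraction fraction of undirected associated pairs held out as
#'   test (in (0,1)).
#' @param seed integer seed; every generator is bitwise-deterministic in it.
#' @return named list of class `syntheticSpec`.
#' @export
syntheticSpec <- function(nGeneTerms = 200L, nDiseaseTerms = 200L,
                          branching = 4L, nSentences = 4000L,
                          nTruePairs = 1000L, zipfExponent = 1.1,
                          naFraction = 0.5, nBlocks = 4L,
                          testFraction = 0.2, seed = 1L) {
    spec <- list(nGeneTerms = as.integer(nGeneTerms),
                 nDiseaseTerms = as.integer(nDiseaseTerms),
                 branching = as.integer(branching),
                 nSentences = as.integer(nSentences),
                 nTruePairs = as.integer(nTruePairs),
                 zipfExponent = zipfExponent, naFraction = naFraction,
                 nBlocks = as.integer(nBlocks),
                 testFraction = testFraction, seed = as.integer(seed))
    stopifnot(spec$nGeneTerms >= 1L, spec$nDiseaseTerms >= 1L,
              spec$branching >= 1L, spec$nSentences >= 1L,
              spec$nTruePairs >= 1L, spec$zipfExponent > 0,
              spec$naFraction >= 0, spec$naFraction < 1,
              spec$nBlocks >= 2L, spec$testFraction > 0,
              spec$testFraction < 1)
    class(spec) <- "syntheticSpec"
    spec
}

#' Generate a random rooted subclass tree
#'
#' Term `i` (for `i >= 2`) receives a `subclass_of` edge to a seeded-random
#' parent among the earlier terms that still have fewer than `branching`
#' children, so the result is a rooted tree with exactly `nTerms - 1`
#' subclass triples and bounded out-degree.
#'
#' @param nTerms number of terms (>= 1).
#' @param branching maximum children per term.
#' @param namespace CURIE prefix for the generated terms.
#' @param seed integer seed.
#' @return a [KnowledgeGraph-class].
#' @export
genOntology <- function(nTerms, branching = 4L, namespace = "SYN", seed = 1L) {
    nTerms <- as.integer(nTerms)
    if (nTerms < 1L) stop("nTerms must be >= 1")
    curies <- paste0(namespace, ":", sprintf("%07d", seq_len(nTerms)))
    parent <- integer(0)
    if (nTerms > 1L) {
        childCount <- integer(nTerms)
        parent <- integer(nTerms - 1L)
        withr::with_seed(seed, {
            for (i in 2:nTerms) {
                eligible <- which(childCount[seq_len(i - 1L)] < branching)
                pick <- eligible[sample.int(length(eligible), 1L)]
                parent[i - 1L] <- pick
                childCount[pick] <- childCount[pick] + 1L
            }
        })
    }
    terms <- data.frame(curie = curies,
                        label = paste(namespace, "term", seq_len(nTerms)),
                        namespace = namespace, stringsAsFactors = FALSE)
    triples <- data.frame(head = curies[seq_len(nTerms)[-1L]],
                          relation = rep("subclass_of", max(nTerms - 1L, 0L)),
                          tail = curies[parent], stringsAsFactors = FALSE)
    if (nTerms == 1L) triples <- .emptyTriples()
    KnowledgeGraph(terms, triples)
}

#' Generate a synthetic gene-disease sentence corpus
#'
#' Plants `nTruePairs` distinct gene-disease pairs and gives pair of Zipf
#' rank `j` a non-NA mention count of `1` plus a multinomial allocation with
#' probability proportional to `j^-zipfExponent`, so every planted pair is
#' mentioned at least once and the counts follow the spec's long-tailed law
#' while summing to `round(nSentences * (1 - naFraction))`. Each non-NA
#' sentence is labeled uniformly from \{therapeutic, biomarker, genomic\};
#' the remaining sentences are `NA` co-mentions of uniformly random pairs.
#' Sentence text embeds both entity names. The exact planted per-pair count
#' table is returned as ground truth.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `instances` (corpus data.frame, shuffled sentence order)
#'   and `counts` (data.frame `gene_id`, `disease_id`, `count`, sorted like
#'   [countAssociations()]).
#' @export
genCorpus <- function(spec = syntheticSpec()) {
    nG <- spec$nGeneTerms; nD <- spec$nDiseaseTerms
    nPairs <- spec$nTruePairs
    if (nPairs > nG * nD)
        stop("nTruePairs exceeds the gene x disease Cartesian product")
    nNonNA <- round(spec$nSentences * (1 - spec$naFraction))
    if (nNonNA < nPairs)
        stop("too few non-NA sentences (", nNonNA, ") to mention all ",
             nPairs, " planted pairs")
    geneIds <- as.character(1000L + seq_len(nG))
    geneNames <- paste0("GENE", seq_len(nG))
    diseaseIds <- sprintf("C%07d", seq_len(nD))
    diseaseNames <- paste("disease", seq_len(nD))
    withr::with_seed(spec$seed, {
        cell <- sample.int(nG * nD, nPairs)        # distinct planted pairs
        gi <- ((cell - 1L) %% nG) + 1L
        di <- ((cell - 1L) %/% nG) + 1L
        w <- seq_len(nPairs)^(-spec$zipfExponent)
        extra <- stats::rmultinom(1L, nNonNA - nPairs, prob = w)[, 1L]
        counts <- 1L + extra
        posG <- rep(gi, counts); posD <- rep(di, counts)
        posLab <- sample(c("therapeutic", "biomarker", "genomic"),
                         nNonNA, replace = TRUE)
        nNA <- spec$nSentences - nNonNA
        naG <- sample.int(nG, nNA, replace = TRUE)
        naD <- sample.int(nD, nNA, replace = TRUE)
        allG <- c(posG, naG); allD <- c(posD, naD)
        lab <- c(posLab, rep("NA", nNA))
        ord <- sample.int(length(allG))
    })
    allG <- allG[ord]; allD <- allD[ord]; lab <- lab[ord]
    instances <- data.frame(
        text = sprintf("%s is co-mentioned with %s in this sentence.",
                       geneNames[allG], diseaseNames[allD]),
        gene_id = geneIds[allG], gene_name = geneNames[allG],
        disease_id = diseaseIds[allD], disease_name = diseaseNames[allD],
        label = lab, stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = geneIds[gi], disease_id = diseaseIds[di],
                        count = as.integer(counts), stringsAsFactors = FALSE)
    truth <- truth[order(truth$gene_id, truth$disease_id, method = "radix"), ,
                   drop = FALSE]
    rownames(truth) <- NULL
    list(instances = instances, counts = truth)
}

#' Generate a planted-block association benchmark
#'
#' Builds the two ontology trees, partitions genes and diseases into
#' `nBlocks` matched groups, samples `nTruePairs` associated pairs only
#' within matched groups (a dense within-block signal every embedding family
#' can represent), joins everything into one knowledge graph with
#' bidirectional `associated` edges, and holds out `testFraction` of the
#' undirected pairs via [splitAssociatedTriples()].
#'
#' @param spec a [syntheticSpec()].
#' @return list with `train` (a [KnowledgeGraph-class]), `test` (data.frame
#'   of directed associated test triples), and `blocks` (list of named block
#'   assignments `gene`, `disease`).
#' @export
genPlantedKG <- function(spec = syntheticSpec()) {
    geneKG <- genOntology(spec$nGeneTerms, spec$branching, "G", spec$seed)
    diseaseKG <- genOntology(spec$nDiseaseTerms, spec$branching, "D",
                             spec$seed + 1L)
    genes <- entityNames(geneKG)
    diseases <- entityNames(diseaseKG)
    nB <- spec$nBlocks
    withr::with_seed(spec$seed + 2L, {
        gBlock <- sample(rep_len(seq_len(nB), length(genes)))
        dBlock <- sample(rep_len(seq_len(nB), length(diseases)))
        perBlock <- vapply(seq_len(nB), function(b)
            sum(gBlock == b) * sum(dBlock == b), numeric(1))
        if (spec$nTruePairs > sum(perBlock))
            stop("nTruePairs exceeds within-block pair capacity")
        ## enumerate within-block cells once, then sample pairs uniformly
        cells <- do.call(rbind, lapply(seq_len(nB), function(b)
            expand.grid(g = which(gBlock == b), d = which(dBlock == b))))
        pick <- cells[sample.int(nrow(cells), spec$nTruePairs), ]
    })
    bridges <- data.frame(gene_curie = genes[pick$g],
                          disease_curie = diseases[pick$d],
                          support = 1L, stringsAsFactors = FALSE)
    joint <- buildJointKG(geneKG, diseaseKG, bridges)
    split <- splitAssociatedTriples(joint, spec$testFraction,
                                    seed = spec$seed + 3L)
    list(train = split$train, test = split$test,
         blocks = list(gene = stats::setNames(gBlock, genes),
                       disease = stats::setNames(dBlock, diseases)))
}
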