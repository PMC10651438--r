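# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# Two-namespace toy graph: 4 gene terms (3 subclass edges), 3 disease terms
# (2 subclass edges).
tinyGeneKG <- function() {
    KnowledgeGraph(
        terms = data.frame(curie = paste0("G:", 1:4),
                           label = paste("gene", 1:4), namespace = "G"),
        triples = data.frame(head = paste0("G:", 2:4),
                             relation = "subclass_of",
                             tail = paste0("G:", c(1, 1, 2))))
}

tinyDiseaseKG <- function() {
    KnowledgeGraph(
        terms = data.frame(curie = paste0("D:", 1:3),
                           label = paste("disease", 1:3), namespace = "D"),
        triples = data.frame(head = paste0("D:", 2:3),
                             relation = "subclass_of",
                             tail = paste0("D:", c(1, 2))))
}

tinyBridges <- function() {
    data.frame(gene_curie = c("G:2", "G:3"), disease_curie = c("D:2", "D:3"),
               support = c(5L, 2L), stringsAsFactors = FALSE)
}

tinyJointKG <- function() buildJointKG(tinyGeneKG(), tinyDiseaseKG(),
                                       tinyBridges())

# Random count table with heavy ties, for top-K selection tests.
randomCounts <- function(nPairs, seed, maxCount = 25L) {
    withr::with_seed(seed, {
        g <- sprintf("g%03d", sample.int(nPairs * 2, nPairs))
        d <- sprintf("d%03d", sample.int(nPairs * 2, nPairs))
        key <- paste(g, d)
        keep <- !duplicated(key)
        data.frame(gene_id = g[keep], disease_id = d[keep],
                   count = sample.int(maxCount, sum(keep), replace = TRUE),
                   stringsAsFactors = FALSE)
    })
}

# Model with random parameters respecting every family invariant, built
# directly (not via initModel) so scoring tests do not depend on init code.
randomModel <- function(family, nEnt = 6L, nRel = 2L, d = 3L, seed = 1L) {
    cfg <- kgeConfig(dim = as.integer(d), seed = 1L)
    ents <- paste0("E:", seq_len(nEnt))
    rels <- c("subclass_of", "associated")[seq_len(nRel)]
    withr::with_seed(seed, {
        rm <- function(n) matrix(stats::rnorm(n * d), n, d)
        params <- switch(family,
            UM = list(E = rm(nEnt)),
            TorusE = list(E = matrix(stats::runif(nEnt * d), nEnt, d),
                          R = matrix(stats::runif(nRel * d), nRel, d)),
            RotatE = list(Ere = rm(nEnt), Eim = rm(nEnt),
                          Rphase = matrix(stats::runif(nRel * d, 0, 2 * pi),
                                          nRel, d)),
            PairRE = {
                E <- rm(nEnt)
                list(E = E / sqrt(rowSums(E^2)), RH = rm(nRel), RT = rm(nRel))
            },
            ComplEx = list(Ere = rm(nEnt), Eim = rm(nEnt), Rre = rm(nRel),
                           Rim = rm(nRel)),
            SimplE = list(Eh = rm(nEnt), Et = rm(nEnt), R = rm(nRel),
                          Rinv = rm(nRel)),
            KG2E = list(Emu = rm(nEnt),
                        Ev = matrix(stats::runif(nEnt * d, 0.5, 2), nEnt, d),
                        Rmu = rm(nRel),
                        Rv = matrix(stats::runif(nRel * d, 0.5, 2), nRel, d)))
    })
    EmbeddingModel(family, ents, rels, params, cfg)
}

kgeFamilies <- c("UM", "TorusE", "RotatE", "PairRE", "ComplEx", "SimplE",
                 "KG2E")

# Small planted benchmark for quick training tests.
smallPlantedSpec <- function(seed = 5L)
    syntheticSpec(nGeneTerms = 12L, nDiseaseTerms = 12L, branching = 3L,
                  nSentences = 200L, nTruePairs = 30L, nBlocks = 2L,
                  testFraction = 0.2, seed = seed)
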