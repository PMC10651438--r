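## EmbeddingModel construction, initialization and checkpoint IO.

## Parameter matrices that have one row per entity, by family.
.entityParamNames <- function(family) {
    switch(family,
        UM = "E",
        TorusE = "E",
        RotatE = c("Ere", "Eim"),
        PairRE = "E",
        ComplEx = c("Ere", "Eim"),
        SimplE = c("Eh", "Et"),
        KG2E = c("Emu", "Ev"),
        stop("unknown family: ", family))
}

.relationParamNames <- function(family) {
    switch(family,
        UM = character(0),
        TorusE = "R",
        RotatE = "Rphase",
        PairRE = c("RH", "RT"),
        ComplEx = c("Rre", "Rim"),
        SimplE = c("R", "Rinv"),
        KG2E = c("Rmu", "Rv"))
}

#' Training configuration for KGE models
#'
#' Bundles every tunable of [initModel()] and [trainModel()]. Defaults:
#' dimension 100, margin 1, learning rate 0.01, 10 negatives per positive,
#' 200 epochs of plain mini-batch SGD in batches of 64 — conventional
#' mid-range values for the translational/bilinear families implemented
#' here, with TorusE's margin and learning rate resolved per family (see
#' below) to match the geometry of its compact embedding space.
#'
#' @param dim embedding dimension.
#' @param epochs number of training epochs.
#' @param batchSize positive triples per mini-batch.
#' @param lr SGD learning rate. `NULL` picks the family default: 0.001 for
#'   TorusE — its hinge gradient is a constant-magnitude sign vector on the
#'   compact torus, so steps an order of magnitude smaller than the Euclidean
#'   families' are needed, matching its original training regime — and 0.01
#'   otherwise.
#' @param margin margin gamma of the ranking loss (distance families).
#'   `NULL` picks the family default: `0.2 * dim` for TorusE, whose L1 torus
#'   distances grow linearly with dimension (a fixed small margin would be
#'   satisfied at initialization and nothing would train), and `1.0` for the
#'   other distance families.
#' @param nNegatives corrupted triples per positive.
#' @param lambda L2 penalty weight (logistic families ComplEx/SimplE).
#' @param seed integer seed fixing the full training trajectory.
#' @param cMin,cMax clamp interval for KG2E diagonal covariances.
#' @param loss `"margin"` or `"logistic"`; `NULL` picks the family
#'   convention (margin for UM/TorusE/RotatE/PairRE/KG2E, logistic for
#'   ComplEx/SimplE).
#' @return a named list of class `kgeConfig`.
#' @export
kgeConfig <- function(dim = 100L, epochs = 200L, batchSize = 64L, lr = NULL,
                      margin = NULL, nNegatives = 10L, lambda = 1e-4,
                      seed = 1L, cMin = 0.05, cMax = 5.0, loss = NULL) {
    cfg <- list(dim = as.integer(dim), epochs = as.integer(epochs),
                batchSize = as.integer(batchSize), lr = lr, margin = margin,
                nNegatives = as.integer(nNegatives), lambda = lambda,
                seed = as.integer(seed), cMin = cMin, cMax = cMax,
                loss = loss)
    stopifnot(cfg$dim >= 1L, cfg$epochs >= 0L, cfg$batchSize >= 1L,
              is.null(cfg$lr) || cfg$lr >= 0,
              is.null(cfg$margin) || cfg$margin > 0,
              cfg$nNegatives >= 1L,
              cfg$lambda >= 0, cfg$cMin > 0, cfg$cMax > cfg$cMin)
    class(cfg) <- "kgeConfig"
    cfg
}

.familyLoss <- function(family, config) {
    if (!is.null(config$loss)) return(config$loss)
    if (family %in% c("ComplEx", "SimplE")) "logistic" else "margin"
}

.familyMargin <- function(family, config) {
    if (!is.null(config$margin)) return(config$margin)
    if (family == "TorusE") 0.2 * config$dim else 1.0
}

.familyLr <- function(family, config) {
    if (!is.null(config$lr)) return(config$lr)
    if (family == "TorusE") 0.001 else 0.01
}

#' Construct an EmbeddingModel from explicit parameters
#'
#' Low-level constructor used by [initModel()] and by tests that need models
#' with hand-set parameters. All parameter matrices must have `config$dim`
#' columns and (for entity parameters) one row per entity.
#'
#' @param family scoring family name.
#' @param entities character vector of entity CURIEs.
#' @param relations character vector of relation names.
#' @param params named list of parameter matrices (layout per family, see
#'   [EmbeddingModel-class]).
#' @param config a [kgeConfig()].
#' @return an [EmbeddingModel-class].
#' @export
EmbeddingModel <- function(family, entities, relations, params,
                           config = kgeConfig()) {
    params <- lapply(params, function(m) {
        m <- as.matrix(m)
        dimnames(m) <- NULL
        m
    })
    new("EmbeddingModel", family = family, dim = config$dim,
        entities = as.character(entities), relations = as.character(relations),
        params = params, config = unclass(config))
}

#' @describeIn EmbeddingModel-class the scoring family name
#' @param x an `EmbeddingModel`.
#' @export
modelFamily <- function(x) x@family

#' @describeIn EmbeddingModel-class entity vocabulary (row order of entity
#'   parameter matrices)
#' @export
modelEntities <- function(x) x@entities

#' @describeIn EmbeddingModel-class relation vocabulary
#' @export
modelRelations <- function(x) x@relations

#' @describeIn EmbeddingModel-class the parameter list
#' @export
modelParams <- function(x) x@params

#' @describeIn EmbeddingModel-class replace the parameter list (validated)
#' @param value named list of parameter matrices.
#' @export
`modelParams<-` <- function(x, value) {
    x@params <- value
    validObject(x)
    x
}

#' @describeIn EmbeddingModel-class the training configuration list
#' @export
modelConfig <- function(x) x@config

setMethod("show", "EmbeddingModel", function(object) {
    cat("EmbeddingModel (", object@family, "), dim ", object@dim, "\n",
        sep = "")
    cat("  ", length(object@entities), " entities, ",
        length(object@relations), " relations\n", sep = "")
})

#' Initialize a KGE model for a knowledge graph
#'
#' Seeded parameter initialization: real coordinates uniform on
#' `[-1/sqrt(dim), 1/sqrt(dim)]`, RotatE phases uniform on `[0, 2*pi)`,
#' TorusE coordinates uniform on `[0, 1)`, KG2E variances at the midpoint of
#' the clamp interval. Bitwise-deterministic for a fixed `config$seed`.
#'
#' @param family one of `"UM"`, `"TorusE"`, `"RotatE"`, `"PairRE"`,
#'   `"ComplEx"`, `"SimplE"`, `"KG2E"`.
#' @param kg a [KnowledgeGraph-class]; its terms become the entity vocabulary
#'   and the distinct relations of its triples the relation vocabulary.
#' @param config a [kgeConfig()].
#' @return an [EmbeddingModel-class].
#' @export
initModel <- function(family, kg, config = kgeConfig()) {
    if (!(family %in% .KGE_FAMILIES))
        stop("unsupported family: ", family)
    if (!numTerms(kg)) stop("knowledge graph has no terms")
    entities <- entityNames(kg)
    relations <- unique(kgTriples(kg)$relation)
    if (!length(relations)) relations <- .KG_RELATIONS
    d <- config$dim
    ne <- length(entities)
    nr <- length(relations)
    s <- 1 / sqrt(d)
    params <- withr::with_seed(config$seed, {
        runifMat <- function(n, lo, hi)
            matrix(stats::runif(n * d, lo, hi), n, d)
        switch(family,
            UM = list(E = runifMat(ne, -s, s)),
            TorusE = list(E = runifMat(ne, 0, 1) %% 1,
                          R = runifMat(nr, 0, 1) %% 1),
            RotatE = list(Ere = runifMat(ne, -s, s),
                          Eim = runifMat(ne, -s, s),
                          Rphase = runifMat(nr, 0, 2 * pi)),
            PairRE = {
                E <- runifMat(ne, -s, s)
                list(E = E / sqrt(rowSums(E^2)),
                     RH = runifMat(nr, -s, s), RT = runifMat(nr, -s, s))
            },
            ComplEx = list(Ere = runifMat(ne, -s, s),
                           Eim = runifMat(ne, -s, s),
                           Rre = runifMat(nr, -s, s),
                           Rim = runifMat(nr, -s, s)),
            SimplE = list(Eh = runifMat(ne, -s, s), Et = runifMat(ne, -s, s),
                          R = runifMat(nr, -s, s),
                          Rinv = runifMat(nr, -s, s)),
            KG2E = {
                mid <- (config$cMin + config$cMax) / 2
                list(Emu = runifMat(ne, -s, s),
                     Ev = matrix(mid, ne, d),
                     Rmu = runifMat(nr, -s, s),
                     Rv = matrix(mid, nr, d))
            })
    })
    EmbeddingModel(family, entities, relations, params, config)
}

#' Save a model checkpoint as plain text files
#'
#' Writes each parameter matrix as a TSV (row names = entity or relation
#' names) plus a JSON manifest with family, dimension, vocabularies and
#' config.
#'
#' @param model an [EmbeddingModel-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [loadModel()], [exportEmbeddings()]
#' @export
saveModel <- function(model, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(model@params))
        utils::write.table(model@params[[nm]],
                           file.path(dir, paste0(nm, ".tsv")),
                           sep = "\t", col.names = FALSE, row.names = FALSE)
    manifest <- list(family = model@family, dim = model@dim,
                     entities = model@entities, relations = model@relations,
                     params = names(model@params), config = model@config)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(dir)
}

#' Load a model checkpoint written by [saveModel()]
#'
#' @param dir checkpoint directory.
#' @return an [EmbeddingModel-class].
#' @export
loadModel <- function(dir) {
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                    simplifyVector = TRUE)
    params <- lapply(manifest$params, function(nm)
        as.matrix(utils::read.table(file.path(dir, paste0(nm, ".tsv")),
                                    sep = "\t")))
    params <- lapply(params, function(m) { dimnames(m) <- NULL; m })
    names(params) <- manifest$params
    cfg <- manifest$config
    cfg$dim <- as.integer(cfg$dim)
    EmbeddingModel(manifest$family, manifest$entities, manifest$relations,
                   params, structure(cfg, class = "kgeConfig"))
}

#' Export entity embeddings as a TSV for downstream consumers
#'
#' One row per entity: the CURIE followed by its embedding coordinates.
#' Complex families export real parts then imaginary parts; KG2E exports the
#' mean vector; SimplE exports the concatenated head/tail role vectors.
#'
#' @param model an [EmbeddingModel-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
exportEmbeddings <- function(model, path) {
    p <- model@params
    emb <- switch(model@family,
        UM = , TorusE = , PairRE = p$E,
        RotatE = , ComplEx = cbind(p$Ere, p$Eim),
        SimplE = cbind(p$Eh, p$Et),
        KG2E = p$Emu)
    df <- data.frame(curie = model@entities, emb, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
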