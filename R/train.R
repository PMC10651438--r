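## Mini-batch SGD training with negative sampling.
##
## Loss convention: margin ranking loss max(0, gamma - s(pos) + s(neg)) for
## the distance families (UM, TorusE, RotatE, PairRE, KG2E); softplus
## logistic loss with L2 weight decay for the bilinear families (ComplEx,
## SimplE). Every sampled (positive, negative) pair contributes one
## full-weight gradient term, the convention of the translational originals.
## Plain SGD (no adaptive optimizer) keeps the trajectory
## bitwise-reproducible across platforms.

## Scale rows of the score gradient by the per-example loss gradient.
## dLds has one entry per row of the batch.
.scaleRows <- function(M, dLds) M * dLds

## Accumulate (possibly repeated) row gradients into a parameter matrix.
.applyUpdate <- function(P, idx, grad, lr) {
    if (!length(idx)) return(P)
    rs <- rowsum(grad, group = idx, reorder = FALSE)
    rows <- as.integer(rownames(rs))
    P[rows, ] <- P[rows, , drop = FALSE] - lr * rs
    P
}

## One SGD step on the weighted score sum(dLds_i * s_i): computes analytic
## gradients of each family's closed form and applies them in place.
.gradStep <- function(family, p, hIdx, rIdx, tIdx, dLds, lr) {
    switch(family,
        UM = {
            H <- .rowsAt(p$E, hIdx); T <- .rowsAt(p$E, tIdx)
            gH <- .scaleRows(-2 * (H - T), dLds)
            p$E <- .applyUpdate(p$E, c(hIdx, tIdx), rbind(gH, -gH), lr)
        },
        TorusE = {
            d0 <- (.rowsAt(p$E, hIdx) + .rowsAt(p$R, rIdx) -
                   .rowsAt(p$E, tIdx)) %% 1
            base <- .scaleRows(ifelse(d0 < 0.5, -1, 1), dLds)
            p$E <- .applyUpdate(p$E, c(hIdx, tIdx), rbind(base, -base), lr)
            p$R <- .applyUpdate(p$R, rIdx, base, lr)
        },
        RotatE = {
            th <- .rowsAt(p$Rphase, rIdx)
            cr <- cos(th); si <- sin(th)
            Hre <- .rowsAt(p$Ere, hIdx); Him <- .rowsAt(p$Eim, hIdx)
            rotr <- Hre * cr - Him * si
            roti <- Hre * si + Him * cr
            vr <- rotr - .rowsAt(p$Ere, tIdx)
            vi <- roti - .rowsAt(p$Eim, tIdx)
            nrm <- pmax(sqrt(rowSums(vr * vr + vi * vi)), 1e-12)
            gr <- .scaleRows(-vr / nrm, dLds)
            gi <- .scaleRows(-vi / nrm, dLds)
            p$Ere <- .applyUpdate(p$Ere, c(hIdx, tIdx),
                                  rbind(gr * cr + gi * si, -gr), lr)
            p$Eim <- .applyUpdate(p$Eim, c(hIdx, tIdx),
                                  rbind(-gr * si + gi * cr, -gi), lr)
            p$Rphase <- .applyUpdate(p$Rphase, rIdx,
                                     gr * (-roti) + gi * rotr, lr)
        },
        PairRE = {
            H <- .rowsAt(p$E, hIdx); T <- .rowsAt(p$E, tIdx)
            RH <- .rowsAt(p$RH, rIdx); RT <- .rowsAt(p$RT, rIdx)
            gU <- .scaleRows(-sign(H * RH - T * RT), dLds)
            p$E <- .applyUpdate(p$E, c(hIdx, tIdx),
                                rbind(gU * RH, -gU * RT), lr)
            p$RH <- .applyUpdate(p$RH, rIdx, gU * H, lr)
            p$RT <- .applyUpdate(p$RT, rIdx, -gU * T, lr)
        },
        ComplEx = {
            Hre <- .rowsAt(p$Ere, hIdx); Him <- .rowsAt(p$Eim, hIdx)
            Tre <- .rowsAt(p$Ere, tIdx); Tim <- .rowsAt(p$Eim, tIdx)
            Rre <- .rowsAt(p$Rre, rIdx); Rim <- .rowsAt(p$Rim, rIdx)
            gHre <- .scaleRows(Rre * Tre + Rim * Tim, dLds)
            gHim <- .scaleRows(Rre * Tim - Rim * Tre, dLds)
            gTre <- .scaleRows(Hre * Rre - Him * Rim, dLds)
            gTim <- .scaleRows(Hre * Rim + Him * Rre, dLds)
            p$Ere <- .applyUpdate(p$Ere, c(hIdx, tIdx), rbind(gHre, gTre), lr)
            p$Eim <- .applyUpdate(p$Eim, c(hIdx, tIdx), rbind(gHim, gTim), lr)
            p$Rre <- .applyUpdate(p$Rre, rIdx,
                                  .scaleRows(Hre * Tre + Him * Tim, dLds), lr)
            p$Rim <- .applyUpdate(p$Rim, rIdx,
                                  .scaleRows(Hre * Tim - Him * Tre, dLds), lr)
        },
        SimplE = {
            A <- .rowsAt(p$Eh, hIdx); C <- .rowsAt(p$Et, tIdx)
            A2 <- .rowsAt(p$Eh, tIdx); C2 <- .rowsAt(p$Et, hIdx)
            B1 <- .rowsAt(p$R, rIdx); B2 <- .rowsAt(p$Rinv, rIdx)
            p$Eh <- .applyUpdate(p$Eh, c(hIdx, tIdx),
                                 rbind(.scaleRows(0.5 * B1 * C, dLds),
                                       .scaleRows(0.5 * B2 * C2, dLds)), lr)
            p$Et <- .applyUpdate(p$Et, c(tIdx, hIdx),
                                 rbind(.scaleRows(0.5 * A * B1, dLds),
                                       .scaleRows(0.5 * A2 * B2, dLds)), lr)
            p$R <- .applyUpdate(p$R, rIdx, .scaleRows(0.5 * A * C, dLds), lr)
            p$Rinv <- .applyUpdate(p$Rinv, rIdx,
                                   .scaleRows(0.5 * A2 * C2, dLds), lr)
        },
        KG2E = {
            mu0 <- .rowsAt(p$Emu, hIdx) - .rowsAt(p$Emu, tIdx)
            v0 <- .rowsAt(p$Ev, hIdx) + .rowsAt(p$Ev, tIdx)
            mu1 <- .rowsAt(p$Rmu, rIdx)
            v1 <- .rowsAt(p$Rv, rIdx)
            dm <- mu1 - mu0
            gMu0 <- .scaleRows(dm / v1, dLds)          # ds/dmu0
            gV0 <- .scaleRows(-0.5 * (1 / v1 - 1 / v0), dLds)
            gV1 <- .scaleRows(0.5 * (v0 / (v1 * v1) + dm * dm / (v1 * v1) -
                                     1 / v1), dLds)
            p$Emu <- .applyUpdate(p$Emu, c(hIdx, tIdx), rbind(gMu0, -gMu0), lr)
            p$Ev <- .applyUpdate(p$Ev, c(hIdx, tIdx), rbind(gV0, gV0), lr)
            p$Rmu <- .applyUpdate(p$Rmu, rIdx, -gMu0, lr)
            p$Rv <- .applyUpdate(p$Rv, rIdx, gV1, lr)
        },
        stop("unknown family: ", family))
    p
}

## Scale rows with L2 norm above 1 back onto the unit ball.
.ballProject <- function(M) {
    nrm <- sqrt(rowSums(M * M))
    over <- nrm > 1
    if (any(over)) M[over, ] <- M[over, , drop = FALSE] / nrm[over]
    M
}

## Re-impose the family's parameter-space invariants after an update. UM and
## KG2E constrain embeddings to the unit ball as in the original methods;
## without it the repulsive part of the ranking loss inflates norms until the
## hinge saturates and learning freezes.
.projectParams <- function(family, p, cfg) {
    switch(family,
        UM = {
            p$E <- .ballProject(p$E)
        },
        TorusE = {
            p$E <- p$E %% 1
            p$R <- p$R %% 1
        },
        RotatE = {
            p$Rphase <- p$Rphase %% (2 * pi)
        },
        PairRE = {
            nrm <- sqrt(rowSums(p$E * p$E))
            ## idempotent: leave rows already on the unit sphere untouched
            off <- abs(nrm - 1) > 1e-14 & nrm > 1e-12
            if (any(off))
                p$E[off, ] <- p$E[off, , drop = FALSE] / nrm[off]
        },
        KG2E = {
            p$Emu <- .ballProject(p$Emu)
            p$Rmu <- .ballProject(p$Rmu)
            p$Ev <- pmin(pmax(p$Ev, cfg$cMin), cfg$cMax)
            p$Rv <- pmin(pmax(p$Rv, cfg$cMin), cfg$cMax)
        },
        NULL)
    p
}

## Numeric key uniquely identifying (h, r, t) index triples.
.idxKey <- function(hIdx, rIdx, tIdx, nEnt, nRel)
    ((hIdx - 1) * nRel + (rIdx - 1)) * nEnt + tIdx

## Draw corrupted triples for each row of (hIdx, rIdx, tIdx): fair coin for
## the corrupted slot, uniform replacement entity, resampled while the
## corruption reproduces a known triple or the original entity. Uses the
## current RNG stream.
.negSampleIdx <- function(hIdx, rIdx, tIdx, nEnt, nRel, knownKeys, n) {
    m <- length(hIdx) * n
    H <- rep(hIdx, each = n); R <- rep(rIdx, each = n)
    T <- rep(tIdx, each = n)
    corruptHead <- stats::runif(m) < 0.5
    orig <- ifelse(corruptHead, H, T)
    repl <- sample.int(nEnt, m, replace = TRUE)
    done <- FALSE
    for (iter in 1:1000) {
        cH <- ifelse(corruptHead, repl, H)
        cT <- ifelse(corruptHead, T, repl)
        bad <- repl == orig |
            .idxKey(cH, R, cT, nEnt, nRel) %in% knownKeys
        if (!any(bad)) { done <- TRUE; break }
        repl[bad] <- sample.int(nEnt, sum(bad), replace = TRUE)
    }
    if (!done)
        stop("negative sampling exhausted: the graph leaves no ",
             "corrupted triples to draw")
    list(h = ifelse(corruptHead, repl, H), r = R,
         t = ifelse(corruptHead, T, repl), corruptHead = corruptHead)
}

#' Draw corrupted (negative) triples for a training triple
#'
#' Each negative corrupts the head or the tail (fair coin) with a uniformly
#' drawn replacement entity, resampling while the corruption reproduces a
#' triple of `kg` or leaves the entity unchanged.
#'
#' @param triple character vector `c(head, relation, tail)` or a one-row
#'   data.frame with those columns.
#' @param kg the training [KnowledgeGraph-class].
#' @param n number of negatives.
#' @param seed integer seed.
#' @return data.frame of `n` corrupted triples (columns `head`, `relation`,
#'   `tail`).
#' @export
negativeSample <- function(triple, kg, n, seed) {
    if (is.data.frame(triple))
        triple <- c(triple$head[1L], triple$relation[1L], triple$tail[1L])
    ents <- entityNames(kg)
    tr <- kgTriples(kg)
    rels <- unique(tr$relation)
    hIdx <- match(triple[1L], ents); rIdx <- match(triple[2L], rels)
    tIdx <- match(triple[3L], ents)
    if (anyNA(c(hIdx, rIdx, tIdx)))
        stop("triple not expressible over the graph vocabulary")
    known <- .idxKey(match(tr$head, ents), match(tr$relation, rels),
                     match(tr$tail, ents), length(ents), length(rels))
    neg <- withr::with_seed(seed,
        .negSampleIdx(hIdx, rIdx, tIdx, length(ents), length(rels), known,
                      as.integer(n)))
    data.frame(head = ents[neg$h], relation = rels[neg$r], tail = ents[neg$t],
               stringsAsFactors = FALSE)
}

#' Train a KGE model by mini-batch SGD with negative sampling
#'
#' Runs `config$epochs` epochs of seeded mini-batch SGD over the triples of
#' `kg`. Each positive triple is contrasted with `config$nNegatives`
#' corrupted triples; the loss is the family's convention (margin ranking for
#' the distance families, softplus logistic with L2 weight decay for
#' ComplEx/SimplE; see [kgeConfig()]). Parameter-space invariants (torus
#' wrap, phase wrap, unit entity norms, covariance clamps) are re-imposed
#' after every batch. The full trajectory is deterministic for a fixed
#' `config$seed`.
#'
#' @param model an [EmbeddingModel-class], typically from [initModel()].
#' @param kg the training [KnowledgeGraph-class].
#' @param config a [kgeConfig()]; defaults to the model's own config.
#' @return list with `model` (the trained [EmbeddingModel-class]) and `loss`
#'   (numeric vector, mean loss per epoch).
#' @export
trainModel <- function(model, kg, config = NULL) {
    cfg <- if (is.null(config)) model@config else unclass(config)
    fam <- model@family
    lossKind <- .familyLoss(fam, cfg)
    gamma <- .familyMargin(fam, cfg)
    lrate <- .familyLr(fam, cfg)
    ents <- model@entities
    rels <- model@relations
    tr <- kgTriples(kg)
    if (!nrow(tr)) stop("training graph has no triples")
    hIdx <- match(tr$head, ents); tIdx <- match(tr$tail, ents)
    rIdx <- match(tr$relation, rels)
    if (anyNA(hIdx) || anyNA(tIdx) || anyNA(rIdx))
        stop("training graph contains entities/relations unknown to model")
    nEnt <- length(ents); nRel <- length(rels)
    known <- .idxKey(hIdx, rIdx, tIdx, nEnt, nRel)
    nTr <- nrow(tr)
    nNeg <- cfg$nNegatives
    p <- model@params
    lossTrace <- numeric(cfg$epochs)
    decay <- 1 - lrate * cfg$lambda
    withr::with_seed(cfg$seed, {
        for (ep in seq_len(cfg$epochs)) {
            perm <- sample.int(nTr)
            epochLoss <- 0
            nLossTerms <- 0L
            for (start in seq(1L, nTr, by = cfg$batchSize)) {
                b <- perm[start:min(start + cfg$batchSize - 1L, nTr)]
                bh <- hIdx[b]; br <- rIdx[b]; bt <- tIdx[b]
                neg <- .negSampleIdx(bh, br, bt, nEnt, nRel, known, nNeg)
                sPos <- .scoreIdx(fam, p, bh, br, bt)
                sNeg <- .scoreIdx(fam, p, neg$h, neg$r, neg$t)
                if (lossKind == "margin") {
                    ## one full-weight hinge term per (positive, negative)
                    ## pair, the convention of the translational originals
                    L <- pmax(0, gamma - rep(sPos, each = nNeg) + sNeg)
                    act <- as.numeric(L > 0)
                    ## d(loss)/d(sPos) pools its active negatives
                    dPos <- -rowsum(act, group = rep(seq_along(b),
                                                     each = nNeg))[, 1L]
                    dLds <- c(dPos, act)
                    epochLoss <- epochLoss + sum(L)
                    nLossTerms <- nLossTerms + length(L)
                } else {
                    ## one softplus term per sampled example, full weight
                    y <- c(rep(1, length(b)), rep(-1, length(neg$h)))
                    s <- c(sPos, sNeg)
                    z <- -y * s
                    L <- ifelse(z > 30, z, log1p(exp(z)))
                    dLds <- -y / (1 + exp(y * s))
                    epochLoss <- epochLoss + sum(L)
                    nLossTerms <- nLossTerms + length(s)
                }
                if (!all(is.finite(dLds)) || !is.finite(epochLoss))
                    stop("non-finite loss at epoch ", ep,
                         "; lower the learning rate")
                allH <- c(bh, neg$h); allR <- c(br, neg$r)
                allT <- c(bt, neg$t)
                p <- .gradStep(fam, p, allH, allR, allT, dLds, lrate)
                if (lossKind == "logistic" && cfg$lambda > 0 && lrate > 0) {
                    for (nm in names(p)) p[[nm]] <- p[[nm]] * decay
                }
                p <- .projectParams(fam, p, cfg)
            }
            lossTrace[ep] <- epochLoss / nLossTerms
        }
    })
    model@params <- p
    validObject(model)
    list(model = model, loss = lossTrace)
}
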