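## Scoring functions for the seven KGE families. Higher score = more
## plausible triple. All functions are vectorized over triples; the internal
## entry points take integer indices into the model's entity/relation
## vocabularies so the evaluation loop never re-matches names.

.rowsAt <- function(M, idx) M[idx, , drop = FALSE]

.scoreIdx <- function(family, p, hIdx, rIdx, tIdx) {
    switch(family,
        UM = {
            diff <- .rowsAt(p$E, hIdx) - .rowsAt(p$E, tIdx)
            -rowSums(diff * diff)
        },
        TorusE = {
            d0 <- (.rowsAt(p$E, hIdx) + .rowsAt(p$R, rIdx) -
                   .rowsAt(p$E, tIdx)) %% 1
            -rowSums(pmin(d0, 1 - d0))
        },
        RotatE = {
            th <- .rowsAt(p$Rphase, rIdx)
            cr <- cos(th); si <- sin(th)
            Hre <- .rowsAt(p$Ere, hIdx); Him <- .rowsAt(p$Eim, hIdx)
            vr <- Hre * cr - Him * si - .rowsAt(p$Ere, tIdx)
            vi <- Hre * si + Him * cr - .rowsAt(p$Eim, tIdx)
            -sqrt(rowSums(vr * vr + vi * vi))
        },
        PairRE = {
            u <- .rowsAt(p$E, hIdx) * .rowsAt(p$RH, rIdx) -
                 .rowsAt(p$E, tIdx) * .rowsAt(p$RT, rIdx)
            -rowSums(abs(u))
        },
        ComplEx = {
            Hre <- .rowsAt(p$Ere, hIdx); Him <- .rowsAt(p$Eim, hIdx)
            Tre <- .rowsAt(p$Ere, tIdx); Tim <- .rowsAt(p$Eim, tIdx)
            Rre <- .rowsAt(p$Rre, rIdx); Rim <- .rowsAt(p$Rim, rIdx)
            rowSums(Hre * Rre * Tre + Hre * Rim * Tim +
                    Him * Rre * Tim - Him * Rim * Tre)
        },
        SimplE = {
            a1 <- .rowsAt(p$Eh, hIdx) * .rowsAt(p$R, rIdx) *
                  .rowsAt(p$Et, tIdx)
            a2 <- .rowsAt(p$Eh, tIdx) * .rowsAt(p$Rinv, rIdx) *
                  .rowsAt(p$Et, hIdx)
            0.5 * (rowSums(a1) + rowSums(a2))
        },
        KG2E = {
            mu0 <- .rowsAt(p$Emu, hIdx) - .rowsAt(p$Emu, tIdx)
            v0 <- .rowsAt(p$Ev, hIdx) + .rowsAt(p$Ev, tIdx)
            mu1 <- .rowsAt(p$Rmu, rIdx)
            v1 <- .rowsAt(p$Rv, rIdx)
            dm <- mu1 - mu0
            -0.5 * rowSums(v0 / v1 + dm * dm / v1 - 1 + log(v1 / v0))
        },
        stop("unknown family: ", family))
}

.entityIdx <- function(model, x) {
    idx <- match(x, model@entities)
    if (anyNA(idx))
        stop("unknown entity: ", x[which(is.na(idx))[1L]])
    idx
}

.relationIdx <- function(model, x) {
    idx <- match(x, model@relations)
    if (anyNA(idx))
        stop("unknown relation: ", x[which(is.na(idx))[1L]])
    idx
}

#' Score triples under a KGE model
#'
#' Evaluates the model family's scoring function on `(h, r, t)` triples.
#' Higher scores mean more plausible triples. The closed forms are, with
#' entity/relation parameters as in [EmbeddingModel-class]:
#' \describe{
#'   \item{UM}{`-||e_h - e_t||_2^2` (relation-blind, the unstructured model).}
#'   \item{TorusE}{`-sum_i min(d_i, 1 - d_i)` with
#'     `d_i = frac(h_i + r_i - t_i)`: L1 distance on the unit torus.}
#'   \item{RotatE}{`-||e_h o exp(i theta_r) - e_t||_2`, complex entities
#'     rotated elementwise by unit-modulus relation phases.}
#'   \item{PairRE}{`-||e_h o r^H - e_t o r^T||_1` with paired relation
#'     vectors and unit-norm entities.}
#'   \item{ComplEx}{`Re(sum_i e_{h,i} w_{r,i} conj(e_{t,i}))`.}
#'   \item{SimplE}{mean of the two triple products
#'     `<head(h), w_r, tail(t)>` and `<head(t), w_{r^-1}, tail(h)>`.}
#'   \item{KG2E}{negative KL divergence
#'     `-KL(N(mu_h - mu_t, S_h + S_t) || N(mu_r, S_r))` between diagonal
#'     Gaussians (closed form).}
#' }
#'
#' @param model an [EmbeddingModel-class].
#' @param h,r,t character vectors of head entities, relations, tail entities
#'   (recycled to a common length).
#' @return numeric vector of scores.
#' @examples
#' cfg <- kgeConfig(dim = 2L)
#' m <- EmbeddingModel("UM", c("a", "b"), "associated",
#'                     list(E = rbind(c(0, 0), c(3, 4))), cfg)
#' scoreTriples(m, "a", "associated", "b")  # -25
#' @export
scoreTriples <- function(model, h, r, t) {
    n <- max(length(h), length(r), length(t))
    hIdx <- .entityIdx(model, rep_len(h, n))
    tIdx <- .entityIdx(model, rep_len(t, n))
    rIdx <- if (model@family == "UM")
        rep_len(1L, n)  # UM is relation-blind by definition
    else .relationIdx(model, rep_len(r, n))
    if (model@family == "TorusE") {
        p <- model@params
        if (any(p$E < 0 | p$E >= 1) || any(p$R < 0 | p$R >= 1))
            stop("TorusE coordinates outside [0,1)")
    }
    if (model@family == "KG2E") {
        p <- model@params
        if (any(p$Ev <= 0) || any(p$Rv <= 0))
            stop("KG2E covariance at or below 0")
    }
    .scoreIdx(model@family, model@params, hIdx, rIdx, tIdx)
}
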