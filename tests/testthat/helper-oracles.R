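# Independent brute-force oracles. These re-derive every scoring formula
# with scalar loops and R's native complex arithmetic, deliberately sharing
# no code with the package internals, so agreement is evidence of
# correctness rather than of shared bugs.

oracleScore <- function(model, h, r, t) {
    p <- modelParams(model)
    ents <- modelEntities(model)
    rels <- modelRelations(model)
    hi <- match(h, ents); ti <- match(t, ents)
    ri <- match(r, rels)
    d <- ncol(p[[1]])
    fam <- modelFamily(model)
    if (fam == "UM") {
        acc <- 0
        for (i in seq_len(d)) acc <- acc + (p$E[hi, i] - p$E[ti, i])^2
        return(-acc)
    }
    if (fam == "TorusE") {
        acc <- 0
        for (i in seq_len(d)) {
            x <- p$E[hi, i] + p$R[ri, i] - p$E[ti, i]
            frac <- x - floor(x)
            acc <- acc + min(frac, 1 - frac)
        }
        return(-acc)
    }
    if (fam == "RotatE") {
        eh <- complex(real = p$Ere[hi, ], imaginary = p$Eim[hi, ])
        et <- complex(real = p$Ere[ti, ], imaginary = p$Eim[ti, ])
        v <- eh * exp(1i * p$Rphase[ri, ]) - et
        return(-sqrt(sum(Mod(v)^2)))
    }
    if (fam == "PairRE") {
        acc <- 0
        for (i in seq_len(d))
            acc <- acc + abs(p$E[hi, i] * p$RH[ri, i] -
                             p$E[ti, i] * p$RT[ri, i])
        return(-acc)
    }
    if (fam == "ComplEx") {
        eh <- complex(real = p$Ere[hi, ], imaginary = p$Eim[hi, ])
        et <- complex(real = p$Ere[ti, ], imaginary = p$Eim[ti, ])
        w <- complex(real = p$Rre[ri, ], imaginary = p$Rim[ri, ])
        return(Re(sum(eh * w * Conj(et))))
    }
    if (fam == "SimplE") {
        s1 <- 0; s2 <- 0
        for (i in seq_len(d)) {
            s1 <- s1 + p$Eh[hi, i] * p$R[ri, i] * p$Et[ti, i]
            s2 <- s2 + p$Eh[ti, i] * p$Rinv[ri, i] * p$Et[hi, i]
        }
        return(0.5 * (s1 + s2))
    }
    if (fam == "KG2E") {
        kl <- 0
        for (i in seq_len(d)) {
            m0 <- p$Emu[hi, i] - p$Emu[ti, i]
            v0 <- p$Ev[hi, i] + p$Ev[ti, i]
            m1 <- p$Rmu[ri, i]
            v1 <- p$Rv[ri, i]
            kl <- kl + 0.5 * (v0 / v1 + (m1 - m0)^2 / v1 - 1 + log(v1 / v0))
        }
        return(-kl)
    }
    stop("no oracle for ", fam)
}

# KL(N(m0, v0) || N(m1, v1)) for 1-dim Gaussians by numeric quadrature.
oracleKLQuad <- function(m0, v0, m1, v1) {
    f <- function(x) {
        p0 <- stats::dnorm(x, m0, sqrt(v0))
        p0 * (stats::dnorm(x, m0, sqrt(v0), log = TRUE) -
              stats::dnorm(x, m1, sqrt(v1), log = TRUE))
    }
    stats::integrate(f, m0 - 12 * sqrt(v0), m0 + 12 * sqrt(v0),
                     rel.tol = 1e-9)$value
}

# Full-sort rank of the true candidate among all candidate scores
# (average tie policy), via base R's rank().
oracleRank <- function(scores, trueIdx)
    rank(-scores, ties.method = "average")[trueIdx]

# Full-sort top-K selection with the (support desc, gene asc, disease asc)
# tie-break, written as an explicit sort over the whole table.
oracleTopK <- function(counts, k) {
    ord <- order(-counts$count, counts$gene_id, counts$disease_id,
                 method = "radix")
    sorted <- counts[ord, , drop = FALSE]
    head(sorted, min(k, nrow(sorted)))
}
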