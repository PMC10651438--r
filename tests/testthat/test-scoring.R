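mkModel <- function(family, params, d, ents = c("a", "b"), rels = "associated")
    EmbeddingModel(family, ents, rels, params, kgeConfig(dim = as.integer(d)))

test_that("closed-form unit cases score exactly", {
    # UM: e_h = (0,0), e_t = (3,4) -> -(9 + 16)
    m <- mkModel("UM", list(E = rbind(c(0, 0), c(3, 4))), 2)
    expect_identical(scoreTriples(m, "a", "associated", "b"), -25)
    expect_identical(scoreTriples(m, "a", "associated", "a"), 0)

    # TorusE: exact wrap to zero, and min(0.4, 0.6)
    m <- mkModel("TorusE", list(E = rbind(0.9, 0.1), R = rbind(0.2)), 1)
    expect_equal(scoreTriples(m, "a", "associated", "b"), 0)
    m <- mkModel("TorusE", list(E = rbind(0.0, 0.6), R = rbind(0.0)), 1)
    expect_equal(scoreTriples(m, "a", "associated", "b"), -0.4)

    # RotatE: identity rotation of identical entities; half-turn onto -1
    m <- mkModel("RotatE", list(Ere = rbind(1, 1), Eim = rbind(0, 0),
                                Rphase = rbind(0)), 1)
    expect_equal(scoreTriples(m, "a", "associated", "a"), 0)
    m <- mkModel("RotatE", list(Ere = rbind(1, -1), Eim = rbind(0, 0),
                                Rphase = rbind(pi)), 1)
    expect_equal(scoreTriples(m, "a", "associated", "b"), 0,
                 tolerance = 1e-12)

    # PairRE: matched elementwise products cancel
    m <- mkModel("PairRE", list(E = rbind(c(1, 0), c(1, 0)),
                                RH = rbind(c(1, 1)), RT = rbind(c(1, 1))), 2)
    expect_identical(scoreTriples(m, "a", "associated", "b"), 0)

    # ComplEx: real triple product 1; purely imaginary relation -> Re = 0
    m <- mkModel("ComplEx", list(Ere = rbind(1, 1), Eim = rbind(0, 0),
                                 Rre = rbind(1), Rim = rbind(0)), 1)
    expect_identical(scoreTriples(m, "a", "associated", "b"), 1)
    m <- mkModel("ComplEx", list(Ere = rbind(1, 1), Eim = rbind(0, 0),
                                 Rre = rbind(0), Rim = rbind(1)), 1)
    expect_identical(scoreTriples(m, "a", "associated", "b"), 0)

    # SimplE worked arithmetic: (2*3*4 + 1*5*1) / 2
    m <- mkModel("SimplE", list(Eh = rbind(2, 1), Et = rbind(1, 4),
                                R = rbind(3), Rinv = rbind(5)), 1)
    expect_identical(scoreTriples(m, "a", "associated", "b"), 14.5)

    # KG2E: identical distributions -> KL = 0; N(0,1) vs N(1,1) -> KL = 1/2
    m <- mkModel("KG2E", list(Emu = rbind(0.5, 0.5), Ev = rbind(0.5, 0.5),
                              Rmu = rbind(0), Rv = rbind(1)), 1)
    expect_identical(scoreTriples(m, "a", "associated", "b"), 0)
    m <- mkModel("KG2E", list(Emu = rbind(0, 0), Ev = rbind(0.5, 0.5),
                              Rmu = rbind(1), Rv = rbind(1)), 1)
    expect_identical(scoreTriples(m, "a", "associated", "b"), -0.5)
})

test_that("every family matches its brute-force oracle on random models", {
    cases <- 0L
    for (family in kgeFamilies) {
        for (seed in 1:25) {
            d <- 1L + (seed %% 4L)
            m <- randomModel(family, nEnt = 6, nRel = 2, d = d, seed = seed)
            withr::with_seed(seed * 31L, {
                h <- sample(modelEntities(m), 8, replace = TRUE)
                t <- sample(modelEntities(m), 8, replace = TRUE)
                r <- sample(modelRelations(m), 8, replace = TRUE)
            })
            got <- scoreTriples(m, h, r, t)
            want <- vapply(1:8, function(i)
                oracleScore(m, h[i], r[i], t[i]), numeric(1))
            expect_equal(got, want, tolerance = 1e-12)
            cases <- cases + 8L
        }
    }
    expect_gte(cases, 7L * 100L)
})

test_that("UM scores are relation-blind", {
    m <- randomModel("UM", nEnt = 5, nRel = 2, d = 3, seed = 11)
    expect_identical(scoreTriples(m, "E:1", "subclass_of", "E:3"),
                     scoreTriples(m, "E:1", "associated", "E:3"))
})

test_that("torus scores are invariant to integer shifts before wrapping", {
    for (seed in 1:20) {
        m <- randomModel("TorusE", nEnt = 5, nRel = 2, d = 4, seed = seed)
        p <- modelParams(m)
        withr::with_seed(seed, {
            shift <- matrix(sample(-3:3, length(p$E), replace = TRUE),
                            nrow(p$E))
        })
        m2 <- m
        modelParams(m2) <- list(E = (p$E + shift) %% 1, R = p$R)
        expect_equal(scoreTriples(m2, "E:1", "associated", "E:4"),
                     scoreTriples(m, "E:1", "associated", "E:4"),
                     tolerance = 1e-9)
    }
})

test_that("the KG2E closed form agrees with numeric-integration KL", {
    for (seed in 1:15) {
        m <- randomModel("KG2E", nEnt = 4, nRel = 2, d = 1, seed = seed)
        p <- modelParams(m)
        s <- scoreTriples(m, "E:1", "associated", "E:2")
        kl <- oracleKLQuad(p$Emu[1, 1] - p$Emu[2, 1], p$Ev[1, 1] + p$Ev[2, 1],
                           p$Rmu[2, 1], p$Rv[2, 1])
        expect_equal(s, -kl, tolerance = 1e-4)
    }
})

test_that("symmetry structure of the bilinear forms holds", {
    # ComplEx with a purely real relation is a symmetric form
    m <- randomModel("ComplEx", nEnt = 6, nRel = 2, d = 3, seed = 21)
    p <- modelParams(m)
    p$Rim[] <- 0
    modelParams(m) <- p
    expect_equal(scoreTriples(m, "E:2", "associated", "E:5"),
                 scoreTriples(m, "E:5", "associated", "E:2"),
                 tolerance = 1e-12)

    # SimplE with tied role vectors and w_rinv = w_r is forced symmetric
    m <- randomModel("SimplE", nEnt = 6, nRel = 2, d = 3, seed = 22)
    p <- modelParams(m)
    p$Et <- p$Eh
    p$Rinv <- p$R
    modelParams(m) <- p
    expect_equal(scoreTriples(m, "E:1", "associated", "E:4"),
                 scoreTriples(m, "E:4", "associated", "E:1"),
                 tolerance = 1e-12)
})

test_that("scoring rejects unknown vocabulary and invariant violations", {
    m <- randomModel("RotatE", seed = 1)
    expect_error(scoreTriples(m, "nope", "associated", "E:1"),
                 "unknown entity")
    expect_error(scoreTriples(m, "E:1", "regulates", "E:2"),
                 "unknown relation")
    m <- randomModel("TorusE", seed = 2)
    p <- modelParams(m)
    p$E[1, 1] <- 1.4
    m@params <- p   # bypass setter validation to exercise the score guard
    expect_error(scoreTriples(m, "E:1", "associated", "E:2"), "outside")
})
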