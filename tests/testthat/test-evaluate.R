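test_that("rank ties resolve by policy and filtering removes known positives", {
    # head fixed at 0; candidate tails at distances giving a controlled order
    m <- EmbeddingModel("UM", c("h", "t1", "t2", "t3"), "associated",
                        list(E = rbind(0, 1, 1, 3)), kgeConfig(dim = 1L))
    # t1 ties t2 at the top; average policy -> (1 + 2) / 2
    rk <- rankTriple(m, c("h", "associated", "t1"), side = "tail",
                     candidates = c("t1", "t2", "t3"))
    expect_equal(unname(rk["raw"]), 1.5)
    rk <- rankTriple(m, c("h", "associated", "t1"), side = "tail",
                     candidates = c("t1", "t2", "t3"),
                     tiePolicy = "optimistic")
    expect_equal(unname(rk["raw"]), 1)
    rk <- rankTriple(m, c("h", "associated", "t1"), side = "tail",
                     candidates = c("t1", "t2", "t3"),
                     tiePolicy = "pessimistic")
    expect_equal(unname(rk["raw"]), 2)

    # filtering drops the tied known positive, never the true entity
    filt <- data.frame(head = "h", relation = "associated", tail = "t2")
    rk <- rankTriple(m, c("h", "associated", "t1"), side = "tail",
                     candidates = c("t1", "t2", "t3"), filterSet = filt)
    expect_equal(unname(rk["filtered"]), 1)
    expect_equal(unname(rk["raw"]), 1.5)

    expect_error(rankTriple(m, c("h", "associated", "t1"), side = "tail",
                            candidates = c("t2", "t3")),
                 "not among candidates")
})

test_that("ranks agree with the full-sort oracle and filtered <= raw", {
    for (seed in 1:40) {
        family <- kgeFamilies[1L + (seed %% 7L)]
        m <- randomModel(family, nEnt = 20, nRel = 2, d = 3, seed = seed)
        ents <- modelEntities(m)
        withr::with_seed(seed * 7L, {
            tri <- c(sample(ents, 1), "associated", sample(ents, 1))
            filt <- data.frame(
                head = sample(ents, 15, replace = TRUE),
                relation = "associated",
                tail = sample(ents, 15, replace = TRUE))
        })
        rk <- rankTriple(m, tri, side = "tail", candidates = ents,
                         filterSet = filt)
        scores <- scoreTriples(m, rep(tri[1], 20), tri[2], ents)
        expect_equal(unname(rk["raw"]),
                     oracleRank(scores, match(tri[3], ents)))
        expect_lte(rk["filtered"], rk["raw"])
    }
})

test_that("pooled metrics follow the worked arithmetic", {
    met <- rankingMetrics(c(1, 2, 10))
    expect_equal(met$mr, 13 / 3)
    expect_equal(met$mrr, (1 + 0.5 + 0.1) / 3)
    expect_equal(unname(met$hits), c(1 / 3, 2 / 3, 2 / 3))
})

test_that("a perfect scorer attains MR 1 and full hits", {
    # ComplEx with e_g = 1, e_d = i, w = i: s(g, d) = 1, s(d, g) = -1 and
    # every other candidate (including the self-replacement) scores <= 0,
    # so the true entity is the unique maximum on both corruption sides
    ents <- c("G:1", "D:1", "G:2", "D:2", "G:3", "D:3")
    m <- EmbeddingModel("ComplEx", ents, "associated",
                        list(Ere = rbind(1, 0, 0, 0, 0, 0),
                             Eim = rbind(0, 1, 0, 0, 0, 0),
                             Rre = rbind(0), Rim = rbind(1)),
                        kgeConfig(dim = 1L))
    trainKG <- KnowledgeGraph(
        terms = data.frame(curie = ents),
        triples = data.frame(head = "G:2", relation = "associated",
                             tail = "D:2"))
    test <- data.frame(head = "G:1", relation = "associated", tail = "D:1")
    rep <- evaluateRanking(m, test, trainKG)
    expect_s4_class(rep, "RankingReport")
    met <- reportMetrics(rep)
    expect_equal(met$mr, 1)
    expect_equal(met$mrr, 1)
    expect_equal(met$hits5, 1)
    expect_equal(met$n, 2L)   # both corruption sides pooled
})

test_that("evaluation is invariant to test-triple order and errors on empty input", {
    pl <- genPlantedKG(smallPlantedSpec())
    m <- initModel("SimplE", pl$train, kgeConfig(dim = 4L, seed = 2L))
    r1 <- evaluateRanking(m, pl$test, pl$train)
    shuffled <- pl$test[withr::with_seed(1, sample.int(nrow(pl$test))), ]
    r2 <- evaluateRanking(m, shuffled, pl$train)
    expect_equal(reportMetrics(r1)[, c("mr", "mrr", "hits1", "hits3",
                                       "hits5")],
                 reportMetrics(r2)[, c("mr", "mrr", "hits1", "hits3",
                                       "hits5")])
    expect_error(evaluateRanking(m, pl$test[0, ], pl$train), "empty")
})

test_that("type-constrained candidates never worsen the mean rank", {
    pl <- genPlantedKG(smallPlantedSpec())
    for (family in c("UM", "RotatE", "ComplEx")) {
        m <- initModel(family, pl$train, kgeConfig(dim = 4L, seed = 9L))
        mrAll <- reportMetrics(
            evaluateRanking(m, pl$test, pl$train,
                            evalConfig("all-entities")))$mr
        mrType <- reportMetrics(
            evaluateRanking(m, pl$test, pl$train,
                            evalConfig("type-constrained")))$mr
        expect_lte(mrType, mrAll)
    }
})

test_that("filtered evaluation never reports a worse mean rank than raw", {
    pl <- genPlantedKG(smallPlantedSpec())
    m <- initModel("PairRE", pl$train, kgeConfig(dim = 4L, seed = 13L))
    mrFilt <- reportMetrics(
        evaluateRanking(m, pl$test, pl$train,
                        evalConfig(protocol = "filtered")))$mr
    mrRaw <- reportMetrics(
        evaluateRanking(m, pl$test, pl$train,
                        evalConfig(protocol = "raw")))$mr
    expect_lte(mrFilt, mrRaw)
})

test_that("report tables render one row per method", {
    pl <- genPlantedKG(smallPlantedSpec())
    m <- initModel("UM", pl$train, kgeConfig(dim = 4L, seed = 1L))
    rep <- evaluateRanking(m, pl$test, pl$train)
    out <- reportTable(list(UM = rep))
    expect_length(out, 2L)
    expect_match(out[1], "Hits@1")
    expect_match(out[2], "^UM")
})
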