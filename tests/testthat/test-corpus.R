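writeJsonlFixture <- function(lines) {
    f <- withr::local_tempfile(fileext = ".jsonl",
                               .local_envir = parent.frame())
    writeLines(lines, f)
    f
}

test_that("JSONL corpora read in file order with label normalization", {
    f <- writeJsonlFixture(c(
        '{"text":"s1","h":{"id":"7157","name":"TP53"},"t":{"id":"C0006142","name":"breast cancer"},"relation":"Biomarker"}',
        '{"text":"s2","h":{"id":"7157","name":"TP53"},"t":{"id":"C0006142","name":"breast cancer"},"relation":"biomarker"}',
        '{"text":"s3","h":{"id":"1","name":"g"},"t":{"id":"C1","name":"d"},"relation":"NA"}'))
    corp <- readCorpus(f)
    expect_equal(nrow(corp), 3L)
    expect_equal(corp$text, c("s1", "s2", "s3"))
    expect_equal(corp$label, c("biomarker", "biomarker", "NA"))
    expect_equal(corp$gene_id[1], "7157")
    expect_equal(corp$disease_name[1], "breast cancer")
})

test_that("corpus records missing fields or with unknown labels error with line numbers", {
    f <- writeJsonlFixture(c(
        '{"text":"ok","h":{"id":"1","name":"g"},"t":{"id":"C1","name":"d"},"relation":"genomic"}',
        '{"text":"bad","t":{"id":"C1","name":"d"},"relation":"genomic"}'))
    expect_error(readCorpus(f), "line 2")
    f2 <- writeJsonlFixture(
        '{"text":"bad","h":{"id":"1","name":"g"},"t":{"id":"C1","name":"d"},"relation":"causal"}')
    expect_error(readCorpus(f2), "unknown corpus label")
})

test_that("generated corpora round-trip through JSONL write/read", {
    corp <- genCorpus(syntheticSpec(nGeneTerms = 8, nDiseaseTerms = 8,
                                    nSentences = 60, nTruePairs = 10,
                                    seed = 4))$instances
    f <- withr::local_tempfile(fileext = ".jsonl")
    writeCorpus(corp, f)
    expect_equal(readCorpus(f), corp)
})

test_that("binarization collapses the three associated classes and preserves order", {
    corp <- data.frame(text = c("a", "b", "c"), gene_id = "1",
                       gene_name = "g", disease_id = "C1", disease_name = "d",
                       label = c("NA", "genomic", "therapeutic"))
    out <- binarizeLabels(corp)
    expect_equal(out$assoc, c(FALSE, TRUE, TRUE))
    expect_equal(out$text, corp$text)

    allNA <- corp; allNA$label <- "NA"
    expect_false(any(binarizeLabels(allNA)$assoc))

    for (seed in 1:5) {
        corp <- genCorpus(syntheticSpec(nGeneTerms = 6, nDiseaseTerms = 6,
                                        nSentences = 80, nTruePairs = 8,
                                        naFraction = 0.4,
                                        seed = seed))$instances
        expect_equal(sum(binarizeLabels(corp)$assoc),
                     sum(corp$label != "NA"))
    }
})

test_that("balancing downsamples the majority class to the target ratio", {
    mk <- function(nNeg, nPos) {
        data.frame(text = "s", gene_id = "1", gene_name = "g",
                   disease_id = "C1", disease_name = "d",
                   label = rep(c("NA", "genomic"), c(nNeg, nPos)),
                   assoc = rep(c(FALSE, TRUE), c(nNeg, nPos)))
    }
    out <- balanceDataset(mk(10, 4), 0.5, seed = 1)
    expect_equal(sum(out$assoc), 4L)
    expect_equal(sum(!out$assoc), 4L)

    bal <- mk(4, 4)
    expect_equal(balanceDataset(bal, 0.5, seed = 1), bal)

    out <- balanceDataset(mk(500, 100), 0.5, seed = 7)
    ratio <- mean(out$assoc)
    expect_gte(ratio, 0.49)
    expect_lte(ratio, 0.51)
    expect_equal(sum(out$assoc), 100L)   # minority fully retained

    expect_equal(balanceDataset(mk(500, 100), 0.5, seed = 7), out)
    expect_error(balanceDataset(mk(10, 0), 0.5, seed = 1), "empty")
})

test_that("pair datasets sample never-associated negatives without duplicates", {
    withr::with_seed(42, {
        pairs <- unique(data.frame(
            gene_id = sample(sprintf("g%d", 1:20), 100, replace = TRUE),
            disease_id = sample(sprintf("d%d", 1:20), 100, replace = TRUE)))
    })
    n <- nrow(pairs)
    out <- samplePairDataset(pairs, 0.05, seed = 3)
    expect_equal(nrow(out$positives), ceiling(0.05 * n))
    expect_equal(nrow(out$negatives), nrow(out$positives))
    pk <- paste(pairs$gene_id, pairs$disease_id)
    nk <- paste(out$negatives$gene_id, out$negatives$disease_id)
    expect_length(intersect(nk, pk), 0L)
    expect_false(anyDuplicated(nk) > 0)

    # complete bipartite pair set leaves no negatives to draw
    full <- expand.grid(gene_id = c("g1", "g2"), disease_id = c("d1", "d2"),
                        stringsAsFactors = FALSE)
    expect_error(samplePairDataset(full, 1.0, seed = 1), "never-associated")

    for (seed in 1:1000) {
        out <- samplePairDataset(pairs, 0.1, seed = seed)
        nk <- paste(out$negatives$gene_id, out$negatives$disease_id)
        expect_length(intersect(nk, pk), 0L)
    }
})

test_that("prompt rendering uses the fixed question template", {
    expect_equal(
        makePrompts(data.frame(gene_name = "TP53",
                               disease_name = "breast cancer")),
        "Is breast cancer related to TP53?")
    expect_equal(makePrompts(data.frame(gene_name = "g", disease_name = "d")),
                 "Is d related to g?")
    pairs <- data.frame(gene_name = sprintf("g%d", 1:17),
                        disease_name = sprintf("d%d", 1:17))
    expect_length(makePrompts(pairs), 17L)
    expect_error(makePrompts(data.frame(gene_name = "", disease_name = "d")),
                 "empty")
})

test_that("association counting ignores NA sentences and instance order", {
    corp <- data.frame(
        text = "s", gene_id = c("g1", "g1", "g1"), gene_name = "g",
        disease_id = c("d1", "d1", "d1"), disease_name = "d",
        label = c("genomic", "genomic", "NA"))
    counts <- countAssociations(corp)
    expect_equal(counts$count, 2L)

    allNA <- corp; allNA$label <- "NA"
    expect_equal(nrow(countAssociations(allNA)), 0L)

    corp <- genCorpus(syntheticSpec(nGeneTerms = 10, nDiseaseTerms = 10,
                                    nSentences = 150, nTruePairs = 20,
                                    seed = 9))$instances
    shuffled <- corp[withr::with_seed(1, sample.int(nrow(corp))), ]
    expect_equal(countAssociations(shuffled), countAssociations(corp))
})
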