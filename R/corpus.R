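## Sentence-level gene-disease corpus handling.
##
## A corpus is represented as a data.frame with one row per sentence and
## columns text, gene_id, gene_name, disease_id, disease_name, label. Each
## sentence mentions exactly one gene and one disease; the label is one of the
## four classes "NA" (no asserted association), "therapeutic", "biomarker",
## "genomic". Note the string "NA", not the R missing value.

.CORPUS_LABELS <- c("NA", "therapeutic", "biomarker", "genomic")
.CORPUS_COLS <- c("text", "gene_id", "gene_name", "disease_id",
                  "disease_name", "label")

.normalizeLabel <- function(x, line = NULL) {
    idx <- match(tolower(x), tolower(.CORPUS_LABELS))
    if (anyNA(idx)) {
        bad <- which(is.na(idx))[1L]
        where <- if (!is.null(line)) paste0(" at line ", line[bad]) else ""
        stop("unknown corpus label '", x[bad], "'", where)
    }
    .CORPUS_LABELS[idx]
}

.validateCorpus <- function(instances) {
    if (!all(.CORPUS_COLS %in% names(instances)))
        stop("corpus must have columns ",
             paste(.CORPUS_COLS, collapse = ", "))
    if (nrow(instances) && !all(instances$label %in% .CORPUS_LABELS))
        stop("corpus labels outside the four-class vocabulary")
    invisible(instances)
}

#' Read a JSON-lines gene-disease sentence corpus
#'
#' One JSON record per line with fields `text`, `h` (`{id, name}`, the gene),
#' `t` (`{id, name}`, the disease) and `relation` (one of `NA`, `therapeutic`,
#' `biomarker`, `genomic`, matched case-insensitively). This is the common
#' relation-extraction JSONL shape; other dialects can be adapted by renaming
#' fields upstream.
#'
#' @param path JSONL file path.
#' @return data.frame with columns `text`, `gene_id`, `gene_name`,
#'   `disease_id`, `disease_name`, `label`, in file order.
#' @seealso [writeCorpus()], [binarizeLabels()], [countAssociations()]
#' @export
readCorpus <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                        error = function(e)
                            stop("corpus line ", i, ": invalid JSON (",
                                 conditionMessage(e), ")", call. = FALSE))
        for (fld in c("text", "h", "t", "relation"))
            if (is.null(rec[[fld]]))
                stop("corpus line ", i, ": missing field '", fld, "'")
        if (is.null(rec$h$id) || is.null(rec$t$id))
            stop("corpus line ", i, ": entity without id")
        recs[[i]] <- data.frame(
            text = as.character(rec$text),
            gene_id = as.character(rec$h$id),
            gene_name = as.character(rec$h$name %||% ""),
            disease_id = as.character(rec$t$id),
            disease_name = as.character(rec$t$name %||% ""),
            label = .normalizeLabel(as.character(rec$relation), i),
            stringsAsFactors = FALSE)
    }
    out <- if (length(recs)) do.call(rbind, recs) else
        stats::setNames(as.data.frame(matrix(character(0), 0, 6)),
                        .CORPUS_COLS)
    rownames(out) <- NULL
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a corpus as JSON-lines
#'
#' Inverse of [readCorpus()].
#'
#' @param instances corpus data.frame (see [readCorpus()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(instances, path) {
    .validateCorpus(instances)
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(instances))) {
        rec <- list(text = instances$text[i],
                    h = list(id = instances$gene_id[i],
                             name = instances$gene_name[i]),
                    t = list(id = instances$disease_id[i],
                             name = instances$disease_name[i]),
                    relation = instances$label[i])
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
    invisible(path)
}

#' Collapse four-class labels to a binary association label
#'
#' The three associated classes (`therapeutic`, `biomarker`, `genomic`) are
#' combined into one positive class; `NA` becomes the negative class. Order is
#' preserved.
#'
#' @param instances corpus data.frame.
#' @return the same data.frame with a logical column `assoc` appended.
#' @export
binarizeLabels <- function(instances) {
    .validateCorpus(instances)
    instances$assoc <- instances$label != "NA"
    instances
}

#' Balance a binary-labeled corpus by downsampling the majority class
#'
#' Downsamples the majority class without replacement (seeded, uniform) so
#' that the positive fraction is within one sample of `targetRatio`. All
#' minority-class instances are retained. Deterministic for a fixed seed.
#'
#' @param instances data.frame with logical column `assoc`
#'   (see [binarizeLabels()]).
#' @param targetRatio desired positive fraction, in (0, 1). Default 0.5.
#' @param seed integer seed.
#' @return the balanced data.frame (original row order among kept rows).
#' @export
balanceDataset <- function(instances, targetRatio = 0.5, seed) {
    if (!"assoc" %in% names(instances))
        stop("instances must carry a logical 'assoc' column")
    if (targetRatio <= 0 || targetRatio >= 1)
        stop("targetRatio must be in (0, 1)")
    pos <- which(instances$assoc)
    neg <- which(!instances$assoc)
    if (!length(pos) || !length(neg))
        stop("balanceDataset: one class is empty")
    minority <- if (length(pos) <= length(neg)) pos else neg
    majority <- if (length(pos) <= length(neg)) neg else pos
    ## fraction targeted for the minority class
    minRatio <- if (length(pos) <= length(neg)) targetRatio else 1 - targetRatio
    nMaj <- round(length(minority) * (1 - minRatio) / minRatio)
    nMaj <- min(nMaj, length(majority))
    kept <- if (nMaj == length(majority)) majority else
        withr::with_seed(seed, sample(majority, nMaj))
    out <- instances[sort(c(minority, kept)), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Sample a positive/negative gene-disease pair dataset
#'
#' Draws a seeded uniform sample of `ceiling(fraction * N)` pairs as positives
#' from a table of associated pairs, and an equal number of negative pairs
#' from the Cartesian product of the genes and diseases occurring in the
#' table, rejecting any pair present in the table (negatives have never been
#' observed as associated) and any duplicate negative.
#'
#' @param pairs data.frame with columns `gene_id`, `disease_id` (duplicates
#'   collapsed).
#' @param fraction positive sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return list with data.frames `positives` and `negatives` (columns
#'   `gene_id`, `disease_id`).
#' @export
samplePairDataset <- function(pairs, fraction, seed) {
    if (!nrow(pairs)) stop("pair set is empty")
    if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
    key <- paste(pairs$gene_id, pairs$disease_id, sep = "\r")
    pairs <- pairs[!duplicated(key), c("gene_id", "disease_id"), drop = FALSE]
    rownames(pairs) <- NULL
    n <- nrow(pairs)
    nPos <- ceiling(fraction * n)
    genes <- unique(pairs$gene_id)
    diseases <- unique(pairs$disease_id)
    nComplement <- length(genes) * length(diseases) - n
    if (nComplement < nPos)
        stop("cannot draw ", nPos, " negatives: only ", nComplement,
             " never-associated pairs exist in the gene x disease universe")
    posKeys <- paste(pairs$gene_id, pairs$disease_id, sep = "\r")
    withr::with_seed(seed, {
        positives <- pairs[sample(n, nPos), , drop = FALSE]
        negG <- character(0); negD <- character(0)
        tries <- 0L
        while (length(negG) < nPos) {
            m <- 2L * (nPos - length(negG)) + 8L
            g <- sample(genes, m, replace = TRUE)
            d <- sample(diseases, m, replace = TRUE)
            k <- paste(g, d, sep = "\r")
            ok <- !(k %in% posKeys) &
                  !(k %in% paste(negG, negD, sep = "\r")) & !duplicated(k)
            negG <- c(negG, g[ok]); negD <- c(negD, d[ok])
            tries <- tries + 1L
            if (tries > 10000L)
                stop("negative sampling failed to find enough ",
                     "never-associated pairs")
        }
    })
    negatives <- data.frame(gene_id = negG[seq_len(nPos)],
                            disease_id = negD[seq_len(nPos)],
                            stringsAsFactors = FALSE)
    rownames(positives) <- NULL
    list(positives = positives, negatives = negatives)
}

#' Render gene-disease pairs as question prompts
#'
#' Each pair is rendered with the fixed template
#' `"Is {DISEASE} related to {GENE}?"`, the prompt shape used to recast plain
#' pair tables as a sentence-classification dataset.
#'
#' @param pairs data.frame with columns `gene_name`, `disease_name`.
#' @return character vector of prompts, one per row.
#' @examples
#' makePrompts(data.frame(gene_name = "TP53", disease_name = "breast cancer"))
#' @export
makePrompts <- function(pairs) {
    g <- as.character(pairs$gene_name)
    d <- as.character(pairs$disease_name)
    if (any(!nzchar(g)) || any(!nzchar(d)) || anyNA(g) || anyNA(d))
        stop("empty gene or disease name")
    sprintf("Is %s related to %s?", d, g)
}

#' Count non-NA association mentions per gene-disease pair
#'
#' Counts, for every `(gene_id, disease_id)` pair, the number of sentences
#' whose label asserts an association (anything but `NA`). Pairs co-mentioned
#' only in `NA` sentences do not appear. The result is sorted by
#' `(gene_id, disease_id)` so it is invariant to instance order.
#'
#' @param instances corpus data.frame with four-class labels.
#' @return data.frame with columns `gene_id`, `disease_id`, `count`
#'   (all counts >= 1).
#' @seealso [selectBridges()]
#' @export
countAssociations <- function(instances) {
    .validateCorpus(instances)
    keep <- instances$label != "NA"
    if (!any(keep))
        return(data.frame(gene_id = character(0), disease_id = character(0),
                          count = integer(0), stringsAsFactors = FALSE))
    tab <- stats::aggregate(
        list(count = rep(1L, sum(keep))),
        by = list(gene_id = instances$gene_id[keep],
                  disease_id = instances$disease_id[keep]),
        FUN = sum)
    tab <- tab[order(tab$gene_id, tab$disease_id), , drop = FALSE]
    rownames(tab) <- NULL
    tab
}
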