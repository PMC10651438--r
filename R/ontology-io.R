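#' Parse an OBO flat file into a subclass-hierarchy knowledge graph
#'
#' Reads an OBO 1.2/1.4 flat file and extracts one term per non-obsolete
#' `[Term]` stanza and one `subclass_of` triple per `is_a` line. A term's
#' namespace is its CURIE prefix. Obsolete terms are skipped together with
#' their edges (and edges pointing at them); a message reports how many.
#' OBO relationship types other than `is_a` are ignored (messaged), since the
#' hierarchy content used downstream is the subclass relation alone.
#'
#' @param path path to an OBO file.
#' @return a [KnowledgeGraph-class].
#' @details Underscore-form identifiers are normalized to `PREFIX:LOCAL`
#'   CURIEs via [normalizeCurie()]. A malformed stanza line (no `key: value`
#'   shape) raises an error naming the line number.
#' @seealso [writeOBO()], [parseEdgeList()]
#' @export
parseOBO <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    inTerm <- FALSE
    cur <- NULL
    stanzas <- list()
    nOther <- 0L
    flush <- function() if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <<- cur
    for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln) || startsWith(ln, "!")) next
        if (startsWith(ln, "[")) {
            flush(); cur <- NULL
            inTerm <- identical(ln, "[Term]")
            if (inTerm) cur <- list(id = NA_character_, name = "",
                                    is_a = character(0), obsolete = FALSE)
            next
        }
        if (!inTerm) next
        m <- regexpr(":", ln, fixed = TRUE)
        if (m < 0)
            stop("malformed stanza line ", i, " in ", path, ": ", ln)
        key <- substr(ln, 1L, m - 1L)
        val <- trimws(substr(ln, m + 1L, nchar(ln)))
        val <- sub("\\s*!.*$", "", val)  # trailing OBO comment
        if (key == "id") {
            cur$id <- normalizeCurie(val)
        } else if (key == "name") {
            cur$name <- val
        } else if (key == "is_a") {
            cur$is_a <- c(cur$is_a, normalizeCurie(strsplit(val, "\\s+")[[1L]][1L]))
        } else if (key == "is_obsolete") {
            cur$obsolete <- tolower(val) == "true"
        } else if (key == "relationship") {
            nOther <- nOther + 1L
        }
    }
    flush()
    if (!length(stanzas))
        return(KnowledgeGraph())
    obs <- vapply(stanzas, `[[`, logical(1), "obsolete")
    if (any(obs))
        message("parseOBO: skipped ", sum(obs), " obsolete term(s)")
    if (nOther)
        message("parseOBO: ignored ", nOther,
                " non-is_a relationship line(s)")
    keep <- stanzas[!obs]
    ids <- vapply(keep, `[[`, character(1), "id")
    if (anyNA(ids)) stop("[Term] stanza without id in ", path)
    terms <- data.frame(curie = ids,
                        label = vapply(keep, `[[`, character(1), "name"),
                        namespace = .curiePrefix(ids),
                        stringsAsFactors = FALSE)
    heads <- rep(ids, lengths(lapply(keep, `[[`, "is_a")))
    tails <- unlist(lapply(keep, `[[`, "is_a"), use.names = FALSE)
    if (is.null(tails)) tails <- character(0)
    ok <- tails %in% ids
    if (any(!ok))
        message("parseOBO: dropped ", sum(!ok),
                " is_a edge(s) to missing/obsolete terms")
    triples <- data.frame(head = heads[ok],
                          relation = rep("subclass_of", sum(ok)),
                          tail = tails[ok], stringsAsFactors = FALSE)
    KnowledgeGraph(terms, triples)
}

#' Write a subclass hierarchy as an OBO flat file
#'
#' Inverse of [parseOBO()] for hierarchy content: one `[Term]` stanza per
#' term with its `is_a` lines. Only `subclass_of` triples are serialized
#' (OBO has no cross-ontology association axiom in this dialect).
#'
#' @param kg a [KnowledgeGraph-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(kg, path) {
    tr <- subclassTriples(kg)
    parents <- split(tr$tail, tr$head)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("format-version: 1.2", ""), con)
    tm <- kgTerms(kg)
    for (i in seq_len(nrow(tm))) {
        writeLines("[Term]", con)
        writeLines(paste0("id: ", tm$curie[i]), con)
        if (nzchar(tm$label[i]))
            writeLines(paste0("name: ", tm$label[i]), con)
        for (p in parents[[tm$curie[i]]])
            writeLines(paste0("is_a: ", p), con)
        writeLines("", con)
    }
    invisible(path)
}

#' Parse a two-column child-parent edge list
#'
#' Reads a delimited file whose rows are `child<TAB>parent` term identifiers
#' and returns the subclass hierarchy as a knowledge graph. Terms are inferred
#' from both columns; duplicate rows collapse to a single triple.
#'
#' @param path path to the edge list.
#' @param namespace namespace recorded for all inferred terms (identifiers are
#'   still CURIE-normalized; the namespace is informative when identifiers
#'   lack a prefix, in which case `namespace:` is prepended).
#' @param sep field separator (default tab).
#' @return a [KnowledgeGraph-class].
#' @export
parseEdgeList <- function(path, namespace, sep = "\t") {
    if (!file.exists(path)) stop("file not found: ", path)
    .assertScalarString(namespace, "namespace")
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, sep, fixed = TRUE)
    for (i in seq_along(parts)) {
        p <- trimws(parts[[i]])
        if (length(p) < 2L || !nzchar(p[1L]) || !nzchar(p[2L]))
            stop("edge list row ", i, " lacks two columns in ", path)
        parts[[i]] <- p[1:2]
    }
    child <- vapply(parts, `[`, character(1), 1L)
    parent <- vapply(parts, `[`, character(1), 2L)
    fix <- function(x) {
        x <- normalizeCurie(x)
        noPrefix <- !grepl(":", x, fixed = TRUE)
        x[noPrefix] <- paste0(namespace, ":", x[noPrefix])
        x
    }
    child <- fix(child); parent <- fix(parent)
    ids <- unique(c(child, parent))
    terms <- data.frame(curie = ids, label = "",
                        namespace = .curiePrefix(ids),
                        stringsAsFactors = FALSE)
    KnowledgeGraph(terms,
                   data.frame(head = child, relation = "subclass_of",
                              tail = parent, stringsAsFactors = FALSE))
}

#' Write a knowledge graph as an (h, r, t) CSV triple file
#'
#' Serializes the triple set as CSV with header `h,r,t`, one row per triple in
#' insertion order. Relations are written as `"SubclassOf"` and
#' `"Associated"`, the exchange vocabulary understood by common KGE toolkits.
#'
#' @param kg a [KnowledgeGraph-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @seealso [readTriples()]
#' @export
writeTriples <- function(kg, path) {
    tr <- kgTriples(kg)
    relOut <- c(subclass_of = "SubclassOf", associated = "Associated")
    out <- data.frame(h = tr$head, r = unname(relOut[tr$relation]),
                      t = tr$tail, stringsAsFactors = FALSE)
    ok <- tryCatch({
        utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write triples to ", path, ": ",
                          conditionMessage(ok))
    invisible(path)
}

#' Read an (h, r, t) CSV triple file into a knowledge graph
#'
#' Inverse of [writeTriples()]. Terms are inferred from the triple endpoints
#' (namespace from the CURIE prefix, empty labels), so
#' `readTriples(writeTriples(kg))` is the identity on the triple set and on
#' the terms referenced by it.
#'
#' @param path CSV path with header `h,r,t`.
#' @return a [KnowledgeGraph-class].
#' @export
readTriples <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("h", "r", "t") %in% names(df)))
        stop("triple CSV must have header h,r,t: ", path)
    relIn <- c(SubclassOf = "subclass_of", Associated = "associated")
    if (nrow(df) && !all(df$r %in% names(relIn)))
        stop("unknown relation label in ", path)
    ids <- unique(c(df$h, df$t))
    terms <- data.frame(curie = ids, label = "",
                        namespace = .curiePrefix(ids),
                        stringsAsFactors = FALSE)
    KnowledgeGraph(terms,
                   data.frame(head = df$h, relation = unname(relIn[df$r]),
                              tail = df$t, stringsAsFactors = FALSE))
}
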