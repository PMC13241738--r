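#' @importFrom utils read.delim write.table read.csv write.csv
NULL

#' Read and write GMT and directed-GMT gene-set files
#'
#' The GMT dialect is tab-separated: set name, description, then member
#' tokens. The directed dialect annotates members as \code{"GENE|+1"} or
#' \code{"GENE|-1"}; a plain token carries no direction. Key regulators are
#' stored in the description field as \code{"keyRegulators=A,B"} so a
#' collection round-trips identically. Malformed direction tokens raise a
#' parse error naming the line.
#'
#' @param path file path.
#' @param collection a \linkS4class{DirectedGeneSetCollection}.
#' @return \code{readGmt}: a DirectedGeneSetCollection. \code{writeGmt}:
#'   the path, invisibly.
#' @export
writeGmt <- function(collection, path) {
    lines <- vapply(as.list(collection), function(s) {
        dirs <- memberDirections(s)
        tok <- vapply(memberIds(s), function(m) {
            if (m %in% names(dirs))
                paste0(m, "|", ifelse(dirs[[m]] > 0, "+1", "-1"))
            else m
        }, character(1))
        desc <- if (length(keyRegulators(s)))
            paste0("keyRegulators=", paste(keyRegulators(s), collapse = ","))
        else "na"
        paste(c(setName(s), desc, tok), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeGmt
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    sets <- lapply(seq_along(lines), function(i) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3)
            stop("GMT parse error at line ", i, ": need name, description ",
                 "and at least one member")
        tok <- f[-(1:2)]
        hasDir <- grepl("|", tok, fixed = TRUE)
        members <- tok; dirs <- integer(0)
        if (any(hasDir)) {
            parts <- strsplit(tok[hasDir], "|", fixed = TRUE)
            bad <- vapply(parts, function(p)
                length(p) != 2 || !p[2] %in% c("+1", "-1"), logical(1))
            if (any(bad))
                stop("GMT parse error at line ", i, ": malformed direction ",
                     "token '", tok[hasDir][which(bad)[1]], "'")
            members[hasDir] <- vapply(parts, `[`, "", 1)
            dirs <- structure(
                as.integer(vapply(parts, `[`, "", 2)),
                names = members[hasDir])
        }
        key <- character(0)
        if (startsWith(f[2], "keyRegulators="))
            key <- strsplit(sub("^keyRegulators=", "", f[2]), ",")[[1]]
        DirectedGeneSet(f[1], members, directions = dirs,
                        keyRegulators = key)
    })
    DirectedGeneSetCollection(sets)
}

#' Read and write two-column ranking (.rnk) files
#'
#' @param ranked named numeric vector (see \code{\link{rankStatistic}}).
#' @param path file path.
#' @return \code{readRnk}: named numeric vector sorted decreasing.
#' @export
writeRnk <- function(ranked, path) {
    write.table(data.frame(id = names(ranked), stat = unname(ranked)),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' @rdname writeRnk
#' @export
readRnk <- function(path) {
    d <- read.delim(path, header = FALSE,
                    colClasses = c("character", "numeric"))
    r <- structure(d[[2]], names = d[[1]])
    r[order(-r, names(r), method = "radix")]
}

#' Read and write the abundance matrix as TSV pairs
#'
#' The intensity table is written proteins x samples with a
#' \code{uniquePeptides} column; sample annotations go to a companion
#' metadata TSV (sample, region, genotype, age_months, replicate).
#'
#' @param se a SummarizedExperiment.
#' @param path intensity TSV path; metadata path derives as
#'   \code{<path>.meta.tsv} unless given.
#' @param metaPath optional metadata path.
#' @return \code{readAbundance}: the reconstructed SummarizedExperiment.
#' @export
writeAbundance <- function(se, path, metaPath = paste0(path, ".meta.tsv")) {
    m <- assay(se, "intensity")
    d <- data.frame(protein = rownames(m),
                    uniquePeptides = rowData(se)$uniquePeptides,
                    m, check.names = FALSE)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    cd <- as.data.frame(colData(se))
    cd <- data.frame(sample = rownames(cd), cd)
    write.table(cd, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeAbundance
#' @export
readAbundance <- function(path, metaPath = paste0(path, ".meta.tsv")) {
    d <- read.delim(path, check.names = FALSE)
    meta <- read.delim(metaPath)
    m <- as.matrix(d[, meta$sample, drop = FALSE])
    rownames(m) <- d$protein
    SummarizedExperiment(
        assays = list(intensity = m),
        rowData = S4Vectors::DataFrame(uniquePeptides = d$uniquePeptides,
                                       row.names = d$protein),
        colData = S4Vectors::DataFrame(
            meta[, setdiff(names(meta), "sample"), drop = FALSE],
            row.names = meta$sample))
}

#' Read and write the long-format neurochemical table
#'
#' Columns: analyte, region, genotype, age_months, replicate,
#' value_ng_per_mg, below_lod. Per-analyte detection limits travel as a
#' commented header line so the table round-trips with its \code{lod}
#' attribute.
#'
#' @param table the long-format data.frame.
#' @param path CSV path.
#' @return \code{readNeurochem}: the data.frame with \code{lod} attribute.
#' @export
writeNeurochem <- function(table, path) {
    con <- file(path, "w")
    on.exit(close(con))
    lods <- attr(table, "lod")
    if (!is.null(lods))
        writeLines(paste0("# lod ", paste(names(lods), lods, sep = "=",
                                          collapse = ";")), con)
    write.csv(table, con, row.names = FALSE)
    invisible(path)
}

#' @rdname writeNeurochem
#' @export
readNeurochem <- function(path) {
    first <- readLines(path, n = 1)
    lods <- NULL
    if (startsWith(first, "# lod ")) {
        kv <- strsplit(strsplit(sub("^# lod ", "", first), ";")[[1]], "=")
        lods <- structure(as.numeric(vapply(kv, `[`, "", 2)),
                          names = vapply(kv, `[`, "", 1))
    }
    tab <- read.csv(path, comment.char = "#",
                    colClasses = c(analyte = "character",
                                   region = "character"))
    attr(tab, "lod") <- lods
    tab
}

#' Write ground truth as JSON
#' @param truth a GroundTruth list.
#' @param path JSON path.
#' @export
writeGroundTruth <- function(truth, path) {
    jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Verify that a package-written artifact round-trips identically
#'
#' Reads the file, writes it back through the package writer, and re-reads;
#' TRUE iff the two in-memory representations are identical.
#'
#' @param path artifact path.
#' @param type one of \code{"gmt"}, \code{"rnk"}, \code{"neurochem"},
#'   \code{"abundance"}.
#' @return TRUE or FALSE.
#' @export
validateRoundtrip <- function(path,
                              type = c("gmt", "rnk", "neurochem",
                                       "abundance")) {
    type <- match.arg(type)
    tmp <- tempfile()
    on.exit(unlink(c(tmp, paste0(tmp, ".meta.tsv"))))
    ok <- switch(type,
        gmt = {
            a <- readGmt(path); writeGmt(a, tmp); b <- readGmt(tmp)
            isTRUE(all.equal(as.list(a), as.list(b)))
        },
        rnk = {
            a <- readRnk(path); writeRnk(a, tmp); b <- readRnk(tmp)
            isTRUE(all.equal(a, b))
        },
        neurochem = {
            a <- readNeurochem(path); writeNeurochem(a, tmp)
            b <- readNeurochem(tmp)
            isTRUE(all.equal(a, b, check.attributes = TRUE))
        },
        abundance = {
            a <- readAbundance(path); writeAbundance(a, tmp)
            b <- readAbundance(tmp)
            isTRUE(all.equal(assay(a), assay(b))) &&
                isTRUE(all.equal(as.data.frame(colData(a)),
                                 as.data.frame(colData(b))))
        })
    ok
}
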