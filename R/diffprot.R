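#' @importFrom SummarizedExperiment assay rowData colData assays
#' @importFrom SummarizedExperiment assay<-
#' @importFrom stats pt
NULL

#' Total-intensity normalization
#'
#' Rescales each sample column so every column sum equals the across-sample
#' mean of the original column sums (total peptide-amount normalization).
#' Within-sample ratios, and hence within-sample protein rank order, are
#' preserved.
#'
#' @param se a SummarizedExperiment with assay \code{"intensity"}.
#' @return The SummarizedExperiment with normalized intensities.
#' @export
normalizeTotal <- function(se) {
    m <- assay(se, "intensity")
    sums <- colSums(m)
    if (any(sums <= 0))
        stop("sample(s) with non-positive total intensity: ",
             paste(colnames(m)[sums <= 0], collapse = ", "))
    target <- mean(sums)
    assay(se, "intensity") <- sweep(m, 2, target / sums, `*`)
    se
}

#' Minimum unique-peptide filter
#'
#' Retains proteins identified by at least \code{minUnique} unique peptides
#' (default 2, the high-confidence identification rule); row order is
#' preserved.
#'
#' @param se a SummarizedExperiment whose rowData has
#'   \code{uniquePeptides}.
#' @param minUnique minimum unique-peptide count.
#' @return The filtered SummarizedExperiment.
#' @export
filterMinPeptides <- function(se, minUnique = 2) {
    pep <- rowData(se)$uniquePeptides
    if (is.null(pep)) stop("rowData must carry 'uniquePeptides'")
    se[pep >= minUnique, ]
}

# Resolve a sample selector (names, logical, integer, or a named list of
# colData conditions) into column indices.
resolveSamples <- function(se, sel) {
    if (is.list(sel)) {
        keep <- rep(TRUE, ncol(se))
        cd <- colData(se)
        for (f in names(sel)) keep <- keep & cd[[f]] %in% sel[[f]]
        return(which(keep))
    }
    if (is.character(sel)) return(match(sel, colnames(se)))
    if (is.logical(sel)) return(which(sel))
    as.integer(sel)
}

#' Two-group differential abundance test
#'
#' Per-protein unpaired two-tailed t-test on log2-transformed (normalized)
#' intensities, reporting \code{log2fc} = mean(log2 group B) - mean(log2
#' group A), raw p, BH-adjusted q across all tested proteins, and the signed
#' ranking statistic \eqn{r = sign(log2FC) \times -log10(p)}. Zero
#' intensities are replaced by half the smallest positive value in the
#' matrix before the log transform. Proteins with zero variance in both
#' groups and equal means are assigned p = 1 (constant-data convention).
#'
#' @param se a SummarizedExperiment (normalize and filter first).
#' @param groupA,groupB disjoint sample selectors: column names, logical or
#'   integer vectors, or named lists of colData conditions, each selecting
#'   >= 2 samples.
#' @param varianceMode \code{"welch"} (default; unequal variances,
#'   Satterthwaite df) or \code{"pooled"}.
#' @return data.frame with columns protein, log2fc, p, q, rankStat.
#' @export
differentialTest <- function(se, groupA, groupB,
                             varianceMode = c("welch", "pooled")) {
    varianceMode <- match.arg(varianceMode)
    ia <- resolveSamples(se, groupA)
    ib <- resolveSamples(se, groupB)
    if (anyNA(ia) || anyNA(ib)) stop("unknown sample in group selector")
    if (length(intersect(ia, ib))) stop("groups must be disjoint")
    if (length(ia) < 2 || length(ib) < 2)
        stop("each group needs at least 2 samples")

    m <- assay(se, "intensity")
    if (any(m < 0)) stop("intensities must be non-negative")
    if (any(m == 0)) {
        floorVal <- min(m[m > 0]) / 2
        m[m == 0] <- floorVal
    }
    lm2 <- log2(m)
    a <- lm2[, ia, drop = FALSE]; b <- lm2[, ib, drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- rowSums((a - ma)^2) / (na - 1)
    vb <- rowSums((b - mb)^2) / (nb - 1)
    lfc <- mb - ma

    if (varianceMode == "welch") {
        sesq <- va / na + vb / nb
        tt <- lfc / sqrt(sesq)
        df <- sesq^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    } else {
        sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
        tt <- lfc / sqrt(sp2 * (1 / na + 1 / nb))
        df <- rep(na + nb - 2, length(tt))
    }
    p <- 2 * pt(-abs(tt), df)
    # zero variance in both groups: equal means -> p = 1; unequal -> p at floor
    degen <- va == 0 & vb == 0
    p[degen & lfc == 0] <- 1
    p[degen & lfc != 0] <- 1e-300
    p <- pmin(pmax(p, 1e-300), 1)

    res <- data.frame(protein = rownames(m), log2fc = lfc, p = p,
                      q = bhAdjust(p), row.names = NULL)
    res$rankStat <- sign(res$log2fc) * -log10(pmax(res$p, 1e-300))
    res
}

#' Signed ranking statistic, ordered for preranked enrichment
#'
#' Computes \eqn{r = sign(log2FC) \times -log10(p)} (p floored at 1e-300)
#' and returns the list sorted by decreasing r; ties are broken by protein
#' accession (stable, deterministic permutations downstream).
#'
#' @param result a \code{\link{differentialTest}} data.frame.
#' @return Named numeric vector of r, names = protein accessions, sorted
#'   descending.
#' @export
rankStatistic <- function(result) {
    if (!nrow(result)) stop("empty differential result")
    r <- sign(result$log2fc) * -log10(pmax(result$p, 1e-300))
    ord <- order(-r, result$protein, method = "radix")
    structure(r[ord], names = result$protein[ord])
}

#' Volcano-style significance labels
#'
#' Labels each protein \code{"up"} (p below the p cutoff and log2FC at or
#' above the fold cutoff), \code{"down"} (p below cutoff, log2FC at or below
#' minus the fold cutoff) or \code{"ns"}.
#'
#' @param result a \code{\link{differentialTest}} data.frame.
#' @param pCut raw-p threshold (default 0.05).
#' @param fcCut absolute log2 fold-change threshold (default 0.58, i.e.
#'   1.5-fold).
#' @return The result data.frame with a \code{label} column added.
#' @export
volcanoClassify <- function(result, pCut = 0.05, fcCut = 0.58) {
    stopifnot(pCut > 0, fcCut > 0)
    lab <- rep("ns", nrow(result))
    lab[result$p < pCut & result$log2fc >= fcCut] <- "up"
    lab[result$p < pCut & result$log2fc <= -fcCut] <- "down"
    result$label <- lab
    result
}
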