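#' @importFrom stats phyper
NULL

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list accumulating \eqn{P_{hit} - P_{miss}}: each in-set
#' member adds its \eqn{|r|^{weight}} normalized over the in-set total, each
#' non-member adds \eqn{1/(N - N_{hit})}. The enrichment score is the
#' running-sum value of maximum absolute deviation from zero, signed; when
#' the maximum positive and negative deviations tie (within 1e-9), the
#' positive one is reported, a deterministic rule independent of summation
#' order.
#'
#' @param ranked named numeric vector of ranking statistics, sorted in
#'   decreasing order (as returned by \code{\link{rankStatistic}}); names
#'   are unique identifiers.
#' @param set a \linkS4class{DirectedGeneSet} or character vector of
#'   members.
#' @param weight exponent on \eqn{|r|}; 0 gives the classic
#'   Kolmogorov-Smirnov statistic, 1 (default) the weighted form.
#' @return list with \code{es}, \code{runningSum} (length N), and
#'   \code{hitIndices}.
#' @export
enrichmentScore <- function(ranked, set, weight = 1) {
    members <- if (is(set, "DirectedGeneSet")) memberIds(set) else set
    if (anyDuplicated(names(ranked))) stop("ranked ids must be unique")
    N <- length(ranked)
    hit <- names(ranked) %in% members
    k <- sum(hit)
    if (k == 0) {
        warning("set has no overlap with the ranked list; skipped")
        return(list(es = NA_real_, runningSum = numeric(0),
                    hitIndices = integer(0)))
    }
    w <- abs(ranked)^weight
    w[!hit] <- 0
    tot <- sum(w)
    if (tot == 0) { # all in-set statistics are zero: fall back to equal mass
        w[hit] <- 1
        tot <- k
    }
    inc <- w / tot
    missInc <- if (N > k) 1 / (N - k) else 0
    inc[!hit] <- -missInc
    run <- unname(cumsum(inc))
    maxPos <- max(run); maxNeg <- -min(run)
    es <- if (maxPos + 1e-9 >= maxNeg) maxPos else -maxNeg
    list(es = es, runningSum = run, hitIndices = which(hit))
}

# ES from sorted hit indices only, O(k); used for permutation nulls.
# Candidate extrema sit just before and just after each hit; the same
# positive-on-tie rule as the full scan applies.
esFromHits <- function(hitIdx, absw, N) {
    k <- length(hitIdx)
    wh <- absw[hitIdx]
    tot <- sum(wh)
    if (tot == 0) { wh <- rep(1, k); tot <- k }
    cumhit <- cumsum(wh) / tot
    missInc <- if (N > k) 1 / (N - k) else 0
    m <- (hitIdx - seq_len(k)) * missInc
    after <- cumhit - m
    before <- c(0, cumhit[-k]) - m
    maxPos <- max(after, 0); maxNeg <- -min(before, 0)
    if (maxPos + 1e-9 >= maxNeg) maxPos else -maxNeg
}

#' Preranked gene-set enrichment with permutation NES and FDR
#'
#' For each set passing the size filters, computes the observed enrichment
#' score, a null distribution of scores from random same-size member draws
#' out of the ranked universe (gene-set permutation, the only scheme
#' available to preranked input), the normalized enrichment score (observed
#' ES divided by the mean absolute same-sign null ES), a one-sided
#' permutation p-value with add-one correction, and a sign-stratified FDR
#' q-value computed from the pooled null NES distribution. Significance
#' tiers are assigned at q < 0.25 and q < 0.05.
#'
#' @param ranked named numeric vector, sorted decreasing (see
#'   \code{\link{rankStatistic}}).
#' @param collection a \linkS4class{DirectedGeneSetCollection}.
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param weight running-sum exponent (default 1).
#' @param seed integer seed for the permutation stream.
#' @param minSize,maxSize set-size filters applied after intersection with
#'   the ranked universe (defaults 3 and 500).
#' @return data.frame with columns set, size, es, nes, pPerm, fdrQ, tier.
#'   Sets with no overlap are dropped with a warning.
#' @export
gseaPreranked <- function(ranked, collection, nPerm = 1000, weight = 1,
                          seed = 1, minSize = 3, maxSize = 500) {
    if (nPerm < 100) stop("nPerm must be at least 100")
    if (!length(collection)) stop("empty gene-set collection")
    N <- length(ranked)
    absw <- abs(ranked)^weight
    ids <- names(ranked)

    sizes <- integer(0); obsEs <- numeric(0); keepNames <- character(0)
    hitList <- list()
    for (nm in names(collection)) {
        members <- intersect(memberIds(collection[[nm]]), ids)
        k <- length(members)
        if (k == 0) { warning("set '", nm, "' has no overlap; skipped"); next }
        if (k < minSize || k > maxSize) next
        hitIdx <- sort(match(members, ids))
        keepNames <- c(keepNames, nm)
        sizes <- c(sizes, k)
        hitList[[nm]] <- hitIdx
        obsEs <- c(obsEs, esFromHits(hitIdx, absw, N))
    }
    if (!length(keepNames))
        return(data.frame(set = character(0), size = integer(0),
                          es = numeric(0), nes = numeric(0),
                          pPerm = numeric(0), fdrQ = numeric(0),
                          tier = character(0)))

    # one shared null per distinct set size (draws are exchangeable in size)
    set.seed(childSeed(seed, "gsea-permutations"))
    uSizes <- sort(unique(sizes))
    nullEs <- lapply(uSizes, function(k) {
        vapply(seq_len(nPerm),
               function(i) esFromHits(sort(sample.int(N, k)), absw, N),
               numeric(1))
    })
    names(nullEs) <- as.character(uSizes)

    nes <- pPerm <- rep(NA_real_, length(keepNames))
    nullNesPool <- list()
    for (i in seq_along(keepNames)) {
        nv <- nullEs[[as.character(sizes[i])]]
        pos <- nv[nv >= 0]; neg <- nv[nv < 0]
        mPos <- if (length(pos)) mean(abs(pos)) else NA_real_
        mNeg <- if (length(neg)) mean(abs(neg)) else NA_real_
        # per-size null NES pool (computed once per size)
        key <- as.character(sizes[i])
        if (is.null(nullNesPool[[key]])) {
            nn <- nv
            if (!is.na(mPos) && mPos > 0) nn[nv >= 0] <- nv[nv >= 0] / mPos
            if (!is.na(mNeg) && mNeg > 0) nn[nv < 0] <- nv[nv < 0] / mNeg
            nullNesPool[[key]] <- nn
        }
        sameSign <- if (obsEs[i] >= 0) pos else neg
        norm <- if (obsEs[i] >= 0) mPos else mNeg
        if (is.na(norm) || norm == 0) {
            nes[i] <- NA_real_
            pPerm[i] <- 1
        } else {
            nes[i] <- obsEs[i] / norm
            pPerm[i] <- (1 + sum(abs(sameSign) >= abs(obsEs[i]))) /
                (1 + length(sameSign))
        }
    }

    # sign-stratified FDR on the pooled null NES
    pool <- unlist(nullNesPool, use.names = FALSE)
    fdrQ <- rep(NA_real_, length(keepNames))
    obsNes <- nes
    for (i in seq_along(keepNames)) {
        if (is.na(obsNes[i])) { fdrQ[i] <- 1; next }
        if (obsNes[i] >= 0) {
            nullFrac <- sum(pool >= obsNes[i]) / max(1, sum(pool >= 0))
            obsFrac <- sum(obsNes >= obsNes[i], na.rm = TRUE) /
                max(1, sum(obsNes >= 0, na.rm = TRUE))
        } else {
            nullFrac <- sum(pool <= obsNes[i]) / max(1, sum(pool < 0))
            obsFrac <- sum(obsNes <= obsNes[i], na.rm = TRUE) /
                max(1, sum(obsNes < 0, na.rm = TRUE))
        }
        fdrQ[i] <- min(1, nullFrac / max(obsFrac, .Machine$double.eps))
    }
    # step-up monotone enforcement within each sign: a more extreme NES
    # never has a larger q than a less extreme one, so traverse from least
    # to most extreme taking running minima
    for (sgn in c(1, -1)) {
        idx <- which(!is.na(obsNes) &
                     (sign(obsNes) == sgn | (sgn == 1 & obsNes == 0)))
        if (length(idx) > 1) {
            ord <- idx[order(abs(obsNes[idx]))]
            fdrQ[ord] <- cummin(fdrQ[ord])
        }
    }
    tier <- ifelse(is.na(fdrQ) | fdrQ >= 0.25, "ns",
                   ifelse(fdrQ < 0.05, "q<0.05", "q<0.25"))
    data.frame(set = keepNames, size = sizes, es = obsEs, nes = nes,
               pPerm = pPerm, fdrQ = fdrQ, tier = tier, row.names = NULL)
}

#' Right-tailed Fisher over-representation test
#'
#' Hypergeometric upper-tail probability of observing at least the realized
#' overlap between a hit list and a gene set inside a background universe.
#'
#' @param hits character vector of significant identifiers (subset of
#'   \code{background}).
#' @param set a \linkS4class{DirectedGeneSet} or character vector.
#' @param background character vector, the tested universe.
#' @return The right-tailed p-value.
#' @export
fisherOverrepresentation <- function(hits, set, background) {
    if (!length(background)) stop("empty background universe")
    members <- if (is(set, "DirectedGeneSet")) memberIds(set) else set
    if (!all(hits %in% background))
        stop("hits must be a subset of the background")
    K <- length(intersect(members, background))
    n <- length(unique(hits))
    k <- length(intersect(hits, members))
    N <- length(unique(background))
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Direction-aware pathway activation z-score
#'
#' Over the set members that pass the significance rule and carry a
#' direction annotation, counts members whose observed fold-change sign
#' matches the annotation (consistent) versus not (inconsistent) and scores
#' \eqn{z = (n_{consistent} - n_{inconsistent}) / \sqrt{n_{consistent} +
#' n_{inconsistent}}}. Also reports the right-tailed over-representation p
#' of significant members in the set, and a state assigned by
#' \code{\link{classifyPathway}} under the requested preset.
#'
#' @param result a \code{\link{differentialTest}} data.frame.
#' @param set a \linkS4class{DirectedGeneSet} with direction annotations.
#' @param sigRule significance rule (see \code{\link{activationZscore}}
#'   details): a \code{function(result)} returning a logical, or
#'   \code{list(alpha=, on=)} with \code{on} \code{"p"} or \code{"q"}.
#'   Default raw p < 0.05.
#' @param preset classification preset passed to
#'   \code{\link{classifyPathway}}.
#' @return One-row data.frame: set, overlap, fisherP, nConsistent,
#'   nInconsistent, z, degenerate, state.
#' @export
activationZscore <- function(result, set, sigRule = list(alpha = 0.05, on = "p"),
                             preset = "strict") {
    dirs <- memberDirections(set)
    if (!length(dirs))
        stop("set '", setName(set), "' has no direction annotations")
    sig <- evalSigRule(result, sigRule)
    hits <- result$protein[sig]
    fisherP <- fisherOverrepresentation(hits, set, result$protein)
    overlap <- length(intersect(hits, memberIds(set)))

    idx <- match(names(dirs), result$protein)
    present <- !is.na(idx)
    sigAnn <- present & sig[idx] & result$log2fc[idx] != 0
    obsSign <- sign(result$log2fc[idx])
    nCons <- sum(sigAnn & obsSign == dirs, na.rm = TRUE)
    nIncons <- sum(sigAnn & obsSign == -dirs, na.rm = TRUE)
    nTot <- nCons + nIncons
    degenerate <- nTot == 0
    z <- if (degenerate) 0 else (nCons - nIncons) / sqrt(nTot)
    data.frame(set = setName(set), overlap = overlap, fisherP = fisherP,
               nConsistent = nCons, nInconsistent = nIncons, z = z,
               degenerate = degenerate,
               state = classifyPathway(z, fisherP, preset = preset),
               row.names = NULL)
}

#' Pathway activation state at a z / significance cutoff profile
#'
#' \code{"activated"} iff z at or above the z cutoff and \eqn{-log10(p)}
#' above the significance gate; \code{"inhibited"} for z at or below minus
#' the cutoff with the same gate; otherwise \code{"ns"}. Two named presets
#' ship: \code{"strict"} (z cutoff 2.0, -log10 p gate 1.3) for primary
#' pathway calls and \code{"comparative"} (z cutoff 0.5, same gate) for
#' cross-region comparative profiles.
#'
#' @param z activation z-score(s).
#' @param fisherP over-representation p-value(s).
#' @param zCut,logpCut explicit positive cutoffs (override the preset).
#' @param preset \code{"strict"} or \code{"comparative"}.
#' @return Character vector of states.
#' @export
classifyPathway <- function(z, fisherP, zCut = NULL, logpCut = NULL,
                            preset = c("strict", "comparative")) {
    if (is.null(zCut) || is.null(logpCut)) {
        preset <- match.arg(preset)
        cuts <- switch(preset,
                       strict = c(2.0, 1.3),
                       comparative = c(0.5, 1.3))
        if (is.null(zCut)) zCut <- cuts[1]
        if (is.null(logpCut)) logpCut <- cuts[2]
    }
    stopifnot(zCut > 0, logpCut > 0)
    logp <- -log10(pmax(fisherP, 1e-300))
    ifelse(logp > logpCut & z >= zCut, "activated",
           ifelse(logp > logpCut & z <= -zCut, "inhibited", "ns"))
}
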