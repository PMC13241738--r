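# Independent oracles, written from the definitions, never from package code.

# Literal running-sum enrichment score: walk the list, accumulate hit mass
# |r|^w / (total in-set |r|^w) and miss mass 1/(N - Nhit); return the value
# of maximum absolute deviation (positive deviation wins ties within 1e-9).
bruteEs <- function(r, members, weight) {
    N <- length(r)
    hit <- names(r) %in% members
    Nh <- sum(hit); Nm <- N - Nh
    sumw <- sum(abs(r[hit])^weight)
    run <- numeric(N); cur <- 0
    for (i in seq_len(N)) {
        if (hit[i]) {
            cur <- cur + if (sumw > 0) abs(r[i])^weight / sumw else 1 / Nh
        } else {
            cur <- cur - 1 / Nm
        }
        run[i] <- cur
    }
    maxPos <- max(run)
    maxNeg <- -min(run)
    if (maxPos + 1e-9 >= maxNeg) maxPos else -maxNeg
}

# Step-up BH from the definition: q_(i) = min_{j >= i} m * p_(j) / j.
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in m:1) {
        prev <- min(prev, m * p[o[i]] / i)
        q[o[i]] <- prev
    }
    q
}

# Hypergeometric upper tail by direct summation of point masses.
bruteHyperTail <- function(k, K, n, N) {
    jj <- k:min(n, K)
    sum(choose(K, jj) * choose(N - K, n - jj)) / choose(N, n)
}

# A null ranking: standard normal statistics, sorted decreasing.
nullRanking <- function(n, seed) {
    set.seed(seed)
    r <- sort(rnorm(n), decreasing = TRUE)
    names(r) <- sprintf("g%05d", seq_len(n))
    r
}

randomCollection <- function(ids, nSets, sizeRange, seed) {
    set.seed(seed)
    DirectedGeneSetCollection(lapply(seq_len(nSets), function(i)
        DirectedGeneSet(sprintf("RS%03d", i),
                        sample(ids, sample(sizeRange[1]:sizeRange[2], 1)))))
}

# Long-format null neurochemical table for one analyte/genotype:
# regions x ages x replicates of pure noise around a common mean.
nullChemTable <- function(nRep = 4, regions = brainRegions(), mean = 5,
                          sd = 1) {
    grid <- expand.grid(replicate = seq_len(nRep), age_months = c(4, 7),
                        region = regions, stringsAsFactors = FALSE)
    data.frame(analyte = "DA", region = grid$region, genotype = "TG",
               age_months = grid$age_months, replicate = grid$replicate,
               value_ng_per_mg = rnorm(nrow(grid), mean, sd),
               below_lod = FALSE)
}
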