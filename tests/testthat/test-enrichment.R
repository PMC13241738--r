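test_that("enrichment score handles the canonical boundary cases", {
    r <- structure(seq(10, 1), names = LETTERS[1:10])
    # single member at rank 1: full hit mass before any miss mass
    for (w in c(0, 1))
        expect_equal(enrichmentScore(r, "A", weight = w)$es, 1)
    expect_warning(es <- enrichmentScore(r, "nope")$es, "no overlap")
    expect_true(is.na(es))
})

test_that("enrichment score equals the literal running-sum definition", {
    set.seed(17)
    r <- sort(rnorm(12, sd = 2), decreasing = TRUE)
    names(r) <- letters[1:12]
    for (w in c(0, 1)) {
        for (k in 1:4) {
            for (rep in 1:20) {
                members <- sample(names(r), k)
                expect_equal(enrichmentScore(r, members, weight = w)$es,
                             bruteEs(r, members, w), tolerance = 1e-12)
            }
        }
    }
})

test_that("reversing a weight-0 ranking negates the enrichment score", {
    set.seed(23)
    r <- sort(rnorm(11), decreasing = TRUE)
    names(r) <- letters[1:11]
    rev <- sort(-r, decreasing = TRUE)
    for (rep in 1:25) {
        members <- sample(names(r), 3)
        esF <- enrichmentScore(r, members, weight = 0)$es
        esR <- enrichmentScore(rev, members, weight = 0)$es
        # the reversed path is the negated mirror: magnitudes always agree,
        # and the oracle agrees exactly; the sign flips except on a
        # positive/negative maximum tie, which the tie rule sends positive
        expect_equal(abs(esR), abs(esF), tolerance = 1e-9)
        expect_equal(esR, bruteEs(rev, members, 0), tolerance = 1e-12)
    }
})

test_that("the permutation fast path agrees with the full running sum", {
    set.seed(31)
    r <- sort(rnorm(500), decreasing = TRUE)
    names(r) <- sprintf("g%03d", 1:500)
    absw <- abs(r)
    for (rep in 1:40) {
        members <- sample(names(r), sample(3:60, 1))
        hitIdx <- sort(match(members, names(r)))
        expect_equal(ProteoNT:::esFromHits(hitIdx, absw, 500),
                     enrichmentScore(r, members, weight = 1)$es,
                     tolerance = 1e-12)
    }
})

test_that("enrichment scores match the fgsea implementation", {
    set.seed(47)
    r <- sort(rnorm(300), decreasing = TRUE)
    names(r) <- sprintf("g%03d", 1:300)
    for (rep in 1:15) {
        members <- sample(names(r), sample(5:40, 1))
        ours <- enrichmentScore(r, members, weight = 1)$es
        ref <- fgsea::calcGseaStat(r, selectedStats = match(members, names(r)),
                                   gseaParam = 1)
        expect_equal(ours, ref, tolerance = 1e-10)
    }
})

test_that("preranked enrichment recovers a planted top-decile set", {
    r <- nullRanking(2000, seed = 3)
    planted <- sample(names(r)[1:200], 25)
    col <- DirectedGeneSetCollection(c(
        list(DirectedGeneSet("planted", planted)),
        as.list(randomCollection(names(r), 10, c(10, 30), seed = 4))))
    g <- gseaPreranked(r, col, nPerm = 500, seed = 5)
    row <- g[g$set == "planted", ]
    expect_gt(row$nes, 0)
    expect_identical(row$tier, "q<0.05")
    expect_true(all(g$pPerm >= 1 / 501 & g$pPerm <= 1))
    g2 <- gseaPreranked(r, col, nPerm = 500, seed = 5)
    expect_identical(g, g2)
    expect_error(gseaPreranked(r, col, nPerm = 50), "at least 100")
    expect_error(gseaPreranked(r, DirectedGeneSetCollection(list())), "empty")
})

test_that("Fisher over-representation equals the brute-force tail sum", {
    # 3 hits, set of 3, background 10, overlap 3 -> 1/C(10,3)
    bg <- letters[1:10]
    expect_equal(fisherOverrepresentation(letters[1:3], letters[1:3], bg),
                 1 / choose(10, 3), tolerance = 1e-12)
    # zero overlap: whole distribution
    expect_equal(fisherOverrepresentation(letters[1:3], letters[8:10],
                                          bg[1:7]), 1)
    set.seed(12)
    for (rep in 1:30) {
        N <- sample(10:40, 1)
        bg <- sprintf("x%02d", 1:N)
        hits <- sample(bg, sample(1:N, 1))
        setm <- sample(bg, sample(1:N, 1))
        k <- length(intersect(hits, setm))
        expect_equal(fisherOverrepresentation(hits, setm, bg),
                     bruteHyperTail(k, length(setm), length(hits), N),
                     tolerance = 1e-12)
    }
    expect_error(fisherOverrepresentation("a", "a", character(0)), "empty")
    # monotone non-increasing in overlap at fixed margins
    ps <- vapply(0:5, function(k) bruteHyperTail(k, 5, 5, 20), numeric(1))
    expect_true(all(diff(ps) <= 0))
})

test_that("BH adjustment equals brute-force step-up on all small permutations", {
    expect_equal(bhAdjust(0.04), 0.04)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.5, 0)), "\\(0, 1\\]")

    set.seed(6)
    base <- list(0.013, c(0.4, 0.04), c(0.001, 0.02, 0.02, 0.9),
                 runif(5), runif(6))
    for (p in base) {
        idx <- replicate(10, sample(length(p)), simplify = FALSE)
        for (o in idx)
            expect_equal(bhAdjust(p[o]), bruteBH(p[o]), tolerance = 1e-12)
    }
    # monotonicity: raising one p never lowers its q
    p <- c(0.01, 0.2, 0.5)
    expect_true(bhAdjust(c(0.05, 0.2, 0.5))[1] >= bhAdjust(p)[1])
})

test_that("activation z-score follows the consistency formula and flips sign", {
    mk <- function(lfc, p) data.frame(protein = sprintf("m%d", seq_along(lfc)),
                                      log2fc = lfc, p = p,
                                      q = bhAdjust(p))
    set4 <- DirectedGeneSet("s", sprintf("m%d", 1:4),
                            directions = structure(rep(1L, 4),
                                                   names = sprintf("m%d", 1:4)))
    res <- mk(c(1, 2, 0.5, 1.5), rep(0.001, 4))
    a <- activationZscore(res, set4)
    expect_equal(a$z, 2)                      # 4/sqrt(4)
    expect_equal(a$nConsistent, 4)

    res2 <- mk(c(1, 1, -1, -1), rep(0.001, 4))
    expect_equal(activationZscore(res2, set4)$z, 0)

    set9 <- DirectedGeneSet("s9", sprintf("m%d", 1:9),
                            directions = structure(rep(1L, 9),
                                                   names = sprintf("m%d", 1:9)))
    res3 <- mk(rep(-1, 9), rep(0.001, 9))
    expect_equal(activationZscore(res3, set9)$z, -3)  # -9/sqrt(9)

    # antisymmetry under global fold-change negation
    set.seed(33)
    res4 <- mk(rnorm(9), runif(9, 0.001, 0.2))
    flip <- res4; flip$log2fc <- -flip$log2fc
    expect_equal(activationZscore(flip, set9)$z,
                 -activationZscore(res4, set9)$z)

    # no annotated significant member: degenerate z = 0
    resNone <- mk(rep(1, 4), rep(0.9, 4))
    d <- activationZscore(resNone, set4)
    expect_true(d$degenerate)
    expect_equal(d$z, 0)
    undirected <- DirectedGeneSet("u", "m1")
    expect_error(activationZscore(res, undirected), "direction annotations")
})

test_that("pathway classification respects both preset profiles", {
    expect_identical(classifyPathway(2.4, 0.01, preset = "strict"),
                     "activated")
    expect_identical(classifyPathway(1.0, 0.01, preset = "strict"), "ns")
    expect_identical(classifyPathway(1.0, 0.01, preset = "comparative"),
                     "activated")
    expect_identical(classifyPathway(-0.6, 0.1, preset = "comparative"),
                     "ns")   # fails the -log10 p > 1.3 gate
    expect_identical(classifyPathway(-2.5, 0.001, preset = "strict"),
                     "inhibited")
})
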