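test_that("peak-area quantification inverts any affine calibration", {
    expect_equal(as.numeric(quantifyFromPeaks(50, 100, 20)), 10)
    expect_equal(as.numeric(quantifyFromPeaks(100, c(0, 100), c(0, 20))), 20)
    # 5-point noiseless line with known slope/intercept
    concs <- c(1, 2, 5, 10, 20)
    areas <- 7.5 * concs + 3
    got <- quantifyFromPeaks(7.5 * 8.2 + 3, areas, concs)
    expect_equal(as.numeric(got), 8.2, tolerance = 1e-9)
    expect_false(attr(got, "extrapolated"))
    expect_warning(out <- quantifyFromPeaks(1000, areas, concs),
                   "extrapolat")
    expect_true(attr(out, "extrapolated"))
    expect_error(quantifyFromPeaks(-1, 100, 20), "positive")
})

test_that("protein normalization is a plain scale-invariant ratio", {
    expect_equal(normalizeToProtein(10, 2), 5)
    expect_equal(normalizeToProtein(0, 2), 0)
    expect_equal(normalizeToProtein(10, 2), normalizeToProtein(20, 4))
    expect_error(normalizeToProtein(1, 0), "positive")
})

test_that("censoring status partitions cells correctly", {
    tab <- data.frame(analyte = "DA", region = "STR", genotype = "TG",
                      age_months = rep(c(4, 7), each = 4),
                      replicate = rep(1:4, 2),
                      value_ng_per_mg = 1,
                      below_lod = c(rep(TRUE, 4), TRUE, TRUE, FALSE, FALSE))
    cell4 <- list(analyte = "DA", region = "STR", genotype = "TG",
                  age_months = 4)
    cell7 <- cell4; cell7$age_months <- 7
    expect_identical(censorSummary(tab, cell4), "undetected")
    expect_identical(censorSummary(tab, cell7), "partially_censored")
    tab$below_lod <- FALSE
    expect_identical(censorSummary(tab, cell4), "quantified")
    expect_error(censorSummary(tab, list(analyte = "NE", region = "STR",
                                         genotype = "TG", age_months = 4)),
                 "empty cell")
})

test_that("Sidak adjustment matches its closed form and is monotone", {
    expect_equal(sidakAdjust(0.04, m = 1), 0.04)
    expect_equal(sidakAdjust(0.01, m = 3), 1 - 0.99^3)
    expect_equal(sidakAdjust(0.01, m = 3), 0.029701, tolerance = 1e-9)
    p <- seq(0.01, 0.5, by = 0.01)
    for (m in c(2, 7, 20)) {
        adj <- sidakAdjust(p, m = m)
        expect_true(all(diff(adj) >= 0))
        expect_true(all(adj >= p & adj <= 1))
    }
    expect_true(all(sidakAdjust(0.2, m = 7) >= sidakAdjust(0.2, m = 3)))
    expect_error(sidakAdjust(0), "\\(0, 1\\]")
})

test_that("two-way ANOVA reproduces the hand-computed decomposition", {
    # balanced 2x2, n = 3 per cell, values chosen so sums of squares are
    # computable by hand from the cell-means identity
    vals <- c(10, 11, 12, 20, 21, 22, 30, 31, 32, 44, 45, 46)
    tab <- data.frame(analyte = "DA",
                      region = rep(c("STR", "Hip"), each = 6),
                      genotype = "TG",
                      age_months = rep(rep(c(4, 7), each = 3), 2),
                      replicate = rep(1:3, 4),
                      value_ng_per_mg = vals, below_lod = FALSE)
    res <- twoWayAnovaSidak(tab, "DA")
    an <- res$anova
    gm <- mean(vals)
    cellMeans <- tapply(vals, list(tab$region, tab$age_months), mean)
    rowM <- rowMeans(cellMeans); colM <- colMeans(cellMeans)
    ssA <- 6 * sum((rowM - gm)^2)
    ssB <- 6 * sum((colM - gm)^2)
    ssCells <- 3 * sum((cellMeans - gm)^2)
    ssAB <- ssCells - ssA - ssB
    ssE <- sum((vals - ave(vals, tab$region, tab$age_months))^2)
    expect_equal(sum(an[["Sum Sq"]][1:3]), ssA + ssB + ssAB,
                 tolerance = 1e-10)
    expect_equal(an["Residuals", "Sum Sq"], ssE, tolerance = 1e-10)
    expect_equal(res$mse, ssE / 8, tolerance = 1e-10)

    # simple-effect contrasts against the pooled error, Sidak m = 2
    cc <- res$contrasts
    for (lev in c("STR", "Hip")) {
        y4 <- vals[tab$region == lev & tab$age_months == 4]
        y7 <- vals[tab$region == lev & tab$age_months == 7]
        eff <- mean(y7) - mean(y4)
        tt <- eff / sqrt(res$mse * (2 / 3))
        praw <- 2 * pt(-abs(tt), 8)
        row <- cc[cc$level == lev, ]
        expect_equal(row$effect, eff, tolerance = 1e-10)
        expect_equal(row$pRaw, praw, tolerance = 1e-10)
        expect_equal(row$pAdj, 1 - (1 - praw)^2, tolerance = 1e-10)
    }
})

test_that("wholly censored cells leave the model and propagate undetected", {
    set.seed(61)
    tab <- nullChemTable(nRep = 4, regions = c("STR", "Hip", "CB"))
    tab$below_lod[tab$region == "CB"] <- TRUE
    res <- twoWayAnovaSidak(tab, "DA", lod = 0.1)
    cc <- directionCall(res$contrasts)
    expect_identical(cc$direction[cc$level == "CB"], "undetected")
    expect_true(is.na(cc$pAdj[cc$level == "CB"]))
    expect_true(all(cc$status[cc$level != "CB"] == "tested"))
    # family size is the number of tested contrasts
    expect_equal(cc$pAdj[cc$level == "STR"],
                 1 - (1 - cc$pRaw[cc$level == "STR"])^2, tolerance = 1e-12)

    tabAll <- nullChemTable(nRep = 4)
    tabAll$below_lod <- TRUE
    resAll <- twoWayAnovaSidak(tabAll, "DA", lod = 0.1)
    expect_true(all(resAll$contrasts$status == "undetected"))
    expect_null(resAll$anova)
})

test_that("direction calls obey the alpha gate and are antisymmetric", {
    cc <- data.frame(analyte = "DA", level = c("a", "b", "c"),
                     effect = c(3.2, 3.2, -1), t = 1, df = 8,
                     pRaw = c(0.001, 0.3, 0.001),
                     pAdj = c(0.001, 0.30, 0.004), status = "tested")
    out <- directionCall(cc)
    expect_identical(out$direction, c("up", "flat", "down"))
    neg <- cc; neg$effect <- -neg$effect
    outN <- directionCall(neg)
    expect_identical(outN$direction, c("down", "flat", "up"))
})

test_that("Sidak-adjusted contrast family controls the family-wise error", {
    set.seed(71)
    nRep <- 2000
    hits <- 0L
    for (i in seq_len(nRep)) {
        tab <- nullChemTable(nRep = 4, regions = c("OB", "Ctx", "STR", "Hip",
                                                   "Tha", "SN", "CB"))
        cc <- twoWayAnovaSidak(tab, "DA", lod = 0)$contrasts
        if (any(cc$pAdj < 0.05, na.rm = TRUE)) hits <- hits + 1L
    }
    fwer <- hits / nRep
    # nominal 0.05 plus three binomial standard errors of Monte-Carlo slack
    expect_lte(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / nRep))
})
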