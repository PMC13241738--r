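test_that("the default analyte-module map encodes the polarity convention", {
    map <- defaultAnalyteModuleMap()
    da <- map[map$analyte == "DA", ]
    expect_setequal(da$module, c("DA receptor signaling",
                                 "DA degradation signaling"))
    expect_equal(da$polarity[da$module == "DA receptor signaling"], 1L)
    expect_equal(da$polarity[da$module == "DA degradation signaling"], -1L)
    ht <- map[map$analyte == "5HT", ]
    expect_setequal(ht$module, c("5-HT receptor signaling",
                                 "5-HT degradation signaling"))
    expect_equal(nrow(map[map$analyte == "GABA", ]), 0)
    # metabolites report their producing degradation module positively
    expect_equal(map$polarity[map$analyte %in%
                                  c("DOPAC", "HVA", "3MT", "5HIAA")],
                 rep(1L, 4))
})

test_that("concordance applies the sign-product rule", {
    # degradation up explains transmitter down
    expect_identical(concordance("down", "activated", -1), "concordant")
    expect_identical(concordance("down", "activated", 1), "discordant")
    expect_identical(concordance("flat", "activated", 1), "not_evaluable")
    expect_identical(concordance("undetected", "inhibited", 1),
                     "not_evaluable")
    expect_identical(concordance("up", "ns", 1), "not_evaluable")
    expect_identical(concordance("up", "activated", 1), "concordant")
    expect_identical(concordance("up", "inhibited", -1), "concordant")
    expect_error(concordance("up", "activated", 0), "polarity")
})

test_that("key-regulator evidence respects the threshold k", {
    mod <- DirectedGeneSet("DA degradation signaling",
                           c("Maoa", "Maob", "Comt", "X1"),
                           keyRegulators = c("Maoa", "Maob", "Comt"))
    res <- data.frame(protein = c("Maoa", "Maob", "Comt", "X1"),
                      log2fc = c(1.4, 0.1, -0.2, 2),
                      p = c(0.001, 0.4, 0.6, 0.001),
                      q = c(0.01, 0.5, 0.7, 0.01))
    chk <- keyRegulatorCheck(mod, res)
    expect_true(chk$pass)
    expect_identical(chk$evidence$protein, "Maoa")
    expect_false(keyRegulatorCheck(mod, res, k = 2)$pass)

    resNone <- res; resNone$p <- 0.9
    chk0 <- keyRegulatorCheck(mod, resNone)
    expect_false(chk0$pass)
    expect_equal(nrow(chk0$evidence), 0)

    orphan <- DirectedGeneSet("m", "Zzz", keyRegulators = "Zzz")
    expect_warning(out <- keyRegulatorCheck(orphan, res), "no key regulator")
    expect_false(out$pass)
})

test_that("mRNA-protein concordance classifies every pairing", {
    mrna <- data.frame(target = c("A", "B", "C", "D"),
                       region = "Hip",
                       direction = c("up", "flat", "down", "flat"))
    prot <- data.frame(target = c("A", "B", "C", "D"),
                       region = "Hip",
                       direction = c("up", "up", "up", "flat"))
    out <- mrnaProteinConcordance(mrna, prot)
    expect_identical(out$category[match(c("A", "B", "C", "D"), out$target)],
                     c("concordant", "protein_only", "discordant",
                       "neither"))
    dup <- rbind(mrna, mrna[1, ])
    expect_error(mrnaProteinConcordance(dup, prot), "duplicate")
})

test_that("module selection joins the three layers and flags mismatches", {
    col <- DirectedGeneSetCollection(
        DirectedGeneSet("DA receptor signaling", c("Drd1", "Drd2"),
                        directions = c(Drd1 = 1L, Drd2 = 1L),
                        keyRegulators = "Drd1"),
        DirectedGeneSet("DA degradation signaling", c("Maoa", "Comt"),
                        directions = c(Maoa = 1L, Comt = 1L),
                        keyRegulators = "Maoa"))
    calls <- data.frame(analyte = c("DA", "DA"), region = c("Hip", "Hip"),
                        genotype = "TG", direction = c("up", "up"),
                        effect = 1, adjusted_p = 0.01)[1, ]
    act <- data.frame(region = "Hip", set = "DA receptor signaling",
                      state = "activated", z = 2.5)
    res <- data.frame(protein = c("Drd1", "Drd2", "Maoa", "Comt"),
                      log2fc = c(1, 1, 0, 0), p = c(0.001, 0.01, 0.9, 0.9),
                      q = c(0.01, 0.05, 0.95, 0.95))
    map <- defaultAnalyteModuleMap()
    map <- map[map$module %in% names(col), ]
    out <- selectModules(calls, act, list(Hip = res), col, map = map)
    rec <- out[out$module == "DA receptor signaling", ]
    expect_true(rec$selected)
    expect_identical(rec$concordant, "concordant")
    # DA maps to degradation too; that module is ns -> retained, not selected
    deg <- out[out$module == "DA degradation signaling", ]
    expect_identical(deg$concordant, "not_evaluable")
    expect_false(deg$selected)

    badAct <- act; badAct$region <- "CB"
    expect_error(selectModules(calls, badAct, list(Hip = res), col,
                               map = map),
                 "region mismatch")
})

test_that("all-flat analytes select nothing", {
    col <- DirectedGeneSetCollection(
        DirectedGeneSet("DA receptor signaling", "Drd1",
                        directions = c(Drd1 = 1L), keyRegulators = "Drd1"))
    calls <- data.frame(analyte = "DA", region = "Hip", genotype = "TG",
                        direction = "flat", effect = 0, adjusted_p = 0.9)
    act <- data.frame(region = "Hip", set = "DA receptor signaling",
                      state = "activated", z = 3)
    res <- data.frame(protein = "Drd1", log2fc = 1, p = 0.001, q = 0.01)
    map <- defaultAnalyteModuleMap()
    map <- map[map$module %in% names(col), ]
    out <- selectModules(calls, act, list(Hip = res), col, map = map)
    expect_false(any(out$selected))
})
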