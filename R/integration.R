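#' Default analyte-to-module map with concordance polarity
#'
#' Maps each neurotransmitter or metabolite to the signaling modules it
#' reports on, with a polarity: +1 means an analyte increase is concordant
#' with module activation; -1 the reverse. Transmitters map to their
#' receptor-signaling module with polarity +1 (more transmitter, more
#' receptor signaling) and to their degradation module with polarity -1
#' (an activated degradation pathway depletes its substrate), while acid
#' metabolites map to the degradation module that produces them with
#' polarity +1. Fully overridable.
#'
#' @return data.frame with columns analyte, module, polarity.
#' @export
defaultAnalyteModuleMap <- function() {
    data.frame(
        analyte = c("DA", "DA", "5HT", "5HT", "DOPAC", "HVA", "3MT",
                    "5HIAA"),
        module = c("DA receptor signaling", "DA degradation signaling",
                   "5-HT receptor signaling", "5-HT degradation signaling",
                   "DA degradation signaling", "DA degradation signaling",
                   "DA degradation signaling", "5-HT degradation signaling"),
        polarity = c(1L, -1L, 1L, -1L, 1L, 1L, 1L, 1L))
}

#' Directional concordance between an analyte call and a module state
#'
#' Encoding up/activated as +1 and down/inhibited as -1, a pair is
#' \code{"concordant"} iff sign(analyte) x polarity = sign(module); a flat
#' or undetected analyte, or a non-significant module, is
#' \code{"not_evaluable"}; everything else is \code{"discordant"}.
#'
#' @param analyteDirection \code{"up"}, \code{"down"}, \code{"flat"} or
#'   \code{"undetected"} (vectorized).
#' @param moduleState \code{"activated"}, \code{"inhibited"} or
#'   \code{"ns"}.
#' @param polarity +1 or -1.
#' @return Character vector of concordance categories.
#' @export
concordance <- function(analyteDirection, moduleState, polarity) {
    if (!all(polarity %in% c(-1, 1))) stop("polarity must be +1 or -1")
    aSign <- ifelse(analyteDirection == "up", 1,
                    ifelse(analyteDirection == "down", -1, NA))
    mSign <- ifelse(moduleState == "activated", 1,
                    ifelse(moduleState == "inhibited", -1, NA))
    out <- ifelse(is.na(aSign) | is.na(mSign), "not_evaluable",
                  ifelse(aSign * polarity == mSign, "concordant",
                         "discordant"))
    out
}

#' Key-regulator evidence for a module
#'
#' TRUE iff at least \code{k} of the module's declared key regulators pass
#' the significance rule in the differential result; the evidence lists
#' each passing regulator with its fold change and p-value. A module whose
#' key regulators are all absent from the result fails vacuously with a
#' warning.
#'
#' @param module a \linkS4class{DirectedGeneSet} with key regulators.
#' @param result a \code{\link{differentialTest}} data.frame.
#' @param sigRule significance rule (function or \code{list(alpha=, on=)}).
#' @param k minimum number of passing key regulators (default 1).
#' @return list(pass = logical, evidence = data.frame(protein, log2fc, p)).
#' @export
keyRegulatorCheck <- function(module, result,
                              sigRule = list(alpha = 0.05, on = "p"),
                              k = 1) {
    kr <- keyRegulators(module)
    idx <- match(kr, result$protein)
    if (!length(kr) || all(is.na(idx))) {
        warning("module '", setName(module),
                "' has no key regulator present in the result")
        return(list(pass = FALSE,
                    evidence = data.frame(protein = character(0),
                                          log2fc = numeric(0),
                                          p = numeric(0))))
    }
    present <- result[idx[!is.na(idx)], , drop = FALSE]
    sig <- evalSigRule(present, sigRule)
    ev <- present[sig, c("protein", "log2fc", "p"), drop = FALSE]
    rownames(ev) <- NULL
    list(pass = nrow(ev) >= k, evidence = ev)
}

#' Select concordant signaling modules across regions
#'
#' Produces one record per (region, mapped analyte, module): the analyte
#' direction call, the module activation state and z, the concordance
#' category, the key-regulator evidence, and the selection flag
#' (selected = concordant AND key-regulator criterion met). Records that
#' are not evaluable are retained for audit, never dropped.
#'
#' @param directionCalls data.frame from
#'   \code{\link{neurochemDirectionCalls}} (analyte, region, direction).
#' @param activations data.frame with columns region, set, state, z (rbind
#'   of per-region \code{\link{activationZscore}} rows).
#' @param diffResults named list (by region) of
#'   \code{\link{differentialTest}} data.frames.
#' @param collection the \linkS4class{DirectedGeneSetCollection} holding
#'   the modules (for key regulators).
#' @param map analyte-module polarity map (default
#'   \code{\link{defaultAnalyteModuleMap}}).
#' @param sigRule significance rule for key regulators.
#' @param k minimum passing key regulators.
#' @return data.frame module-call matrix: region, module, analyte,
#'   analyte_direction, module_state, module_z, concordant, key_regulator,
#'   n_key_evidence, selected.
#' @export
selectModules <- function(directionCalls, activations, diffResults,
                          collection, map = defaultAnalyteModuleMap(),
                          sigRule = list(alpha = 0.05, on = "p"), k = 1) {
    regionsD <- sort(unique(directionCalls$region))
    regionsA <- sort(unique(activations$region))
    regionsR <- sort(names(diffResults))
    if (!identical(regionsD, regionsA) || !identical(regionsD, regionsR))
        stop("region mismatch between inputs: direction calls have {",
             paste(regionsD, collapse = ","), "}, activations {",
             paste(regionsA, collapse = ","), "}, differential results {",
             paste(regionsR, collapse = ","), "}")
    if (!all(map$module %in% names(collection)))
        stop("map references modules absent from the collection: ",
             paste(setdiff(map$module, names(collection)), collapse = ", "))

    rows <- list()
    for (region in regionsD) {
        krCache <- list()
        for (i in seq_len(nrow(map))) {
            analyte <- map$analyte[i]; module <- map$module[i]
            pol <- map$polarity[i]
            dRow <- directionCalls[directionCalls$region == region &
                                   directionCalls$analyte == analyte, ]
            if (!nrow(dRow)) next
            aRow <- activations[activations$region == region &
                                activations$set == module, ]
            state <- if (nrow(aRow)) aRow$state[1] else "ns"
            zz <- if (nrow(aRow)) aRow$z[1] else NA_real_
            conc <- concordance(dRow$direction[1], state, pol)
            if (is.null(krCache[[module]]))
                krCache[[module]] <- keyRegulatorCheck(
                    collection[[module]], diffResults[[region]],
                    sigRule = sigRule, k = k)
            kr <- krCache[[module]]
            rows[[length(rows) + 1L]] <- data.frame(
                region = region, module = module, analyte = analyte,
                analyte_direction = dRow$direction[1],
                module_state = state, module_z = zz,
                concordant = conc, key_regulator = kr$pass,
                n_key_evidence = nrow(kr$evidence),
                selected = conc == "concordant" && kr$pass)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Qualitative mRNA-protein directional concordance
#'
#' Joins per-(target, region) direction calls from the transcript and
#' protein layers and classifies each pair: \code{"concordant"} (both
#' significant, same sign), \code{"discordant"} (both significant, opposite
#' signs), \code{"protein_only"} / \code{"mrna_only"} (one layer
#' significant), or \code{"neither"}.
#'
#' @param mrna,protein data.frames with columns target, region, direction
#'   (\code{"up"/"down"/"flat"}); keys must be unique within each table.
#' @return data.frame: target, region, mrna_direction, protein_direction,
#'   category.
#' @export
mrnaProteinConcordance <- function(mrna, protein) {
    keyM <- paste(mrna$target, mrna$region, sep = "\r")
    keyP <- paste(protein$target, protein$region, sep = "\r")
    if (anyDuplicated(keyM) || anyDuplicated(keyP))
        stop("duplicate (target, region) keys")
    keys <- union(keyM, keyP)
    md <- mrna$direction[match(keys, keyM)]
    pd <- protein$direction[match(keys, keyP)]
    md[is.na(md)] <- "flat"; pd[is.na(pd)] <- "flat"
    sigM <- md %in% c("up", "down"); sigP <- pd %in% c("up", "down")
    category <- ifelse(sigM & sigP & md == pd, "concordant",
                ifelse(sigM & sigP, "discordant",
                ifelse(sigP, "protein_only",
                ifelse(sigM, "mrna_only", "neither"))))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(target = vapply(parts, `[`, "", 1),
               region = vapply(parts, `[`, "", 2),
               mrna_direction = md, protein_direction = pd,
               category = category)
}
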