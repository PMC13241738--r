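#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom stats rnorm rlnorm rpois runif
NULL

# Hand-curated directed signaling modules for the four neurotransmitter
# pathways, with expected member directions under pathway activation and the
# key regulators whose differential evidence anchors module selection.
# Receptor modules carry a few negative-direction members (phosphatases,
# RGS/PDE brakes, vesicular sequestration) so direction-aware scoring is
# exercised with mixed annotations.
canonicalModuleDefs <- function() {
    list(
        "DA receptor signaling" = list(
            up  = c("Drd1", "Drd2", "Drd3", "Drd4", "Drd5", "Adcy5", "Adcy1",
                    "Gnal", "Prkaca", "Ppp1r1b", "Camk2a", "Arpp21"),
            down = c("Ppp2ca", "Pde1b"),
            key = c("Drd1", "Drd2", "Drd3", "Drd4", "Drd5", "Adcy5")),
        "DA degradation signaling" = list(
            up  = c("Maoa", "Maob", "Comt", "Aldh1a1", "Adh5", "Slc6a3",
                    "Dbh"),
            down = c("Slc18a2", "Th"),
            key = c("Maoa", "Maob", "Comt")),
        "5-HT receptor signaling" = list(
            up  = c("Htr1a", "Htr1b", "Htr2a", "Htr4", "Htr7", "Arrb1",
                    "Arrb2", "Gnaq", "Plcb1", "Prkcb"),
            down = c("Rgs4", "Pde10a"),
            key = c("Htr1a", "Arrb1")),
        "5-HT degradation signaling" = list(
            up  = c("Aldh2", "Aldh1b1", "Aldh9a1", "Maoa", "Slc6a4"),
            down = c("Ddc"),
            key = c("Aldh2")))
}

canonicalModuleMembers <- function() {
    defs <- canonicalModuleDefs()
    unique(unlist(lapply(defs, function(d) c(d$up, d$down)), use.names = FALSE))
}

#' Deterministic protein universe for a simulation configuration
#'
#' The universe places the curated signaling-module proteins first, followed
#' by synthetic filler accessions, so gene-set collections and simulated
#' abundance matrices always share identifiers.
#'
#' @param config a \code{\link{simConfig}}.
#' @return Character vector of \code{config$nProteins} identifiers.
#' @export
proteinUniverse <- function(config) {
    canon <- canonicalModuleMembers()
    nFill <- config$nProteins - length(canon)
    if (nFill < 0)
        stop("nProteins smaller than the curated module vocabulary (",
             length(canon), ")")
    c(canon, sprintf("PROT%05d", seq_len(nFill)))
}

defaultAnalyteBaseline <- function() {
    c(VMA = 2, NE = 8, Epi = 1.5, DOPAC = 3, DA = 12, `5HIAA` = 4,
      HVA = 5, `3MT` = 1.2, `5HT` = 6, TRP = 20, TYR = 25)
}

#' Simulation configuration for the synthetic study
#'
#' Validates and normalizes all knobs of the synthetic-data generator, which
#' emulates the tauopathy study design: a WT/TG x 4/7-month factorial over
#' seven brain regions, with 3 proteomic and 4 neurochemical replicates per
#' group per region, log-normal abundance noise, planted coordinated pathway
#' shifts (applied to the TG 7-month group, so the disease-progression
#' contrast TG 7 vs TG 4 recovers them), planted analyte fold changes, and
#' per-analyte detection limits producing left-censored records.
#'
#' @param nProteins number of proteins in the universe.
#' @param nRepProt proteomic biological replicates per group (default 3).
#' @param nRepChem neurochemical replicates per group (default 4).
#' @param regions brain-region labels (default the seven-region panel).
#' @param noiseSd log2-scale abundance noise standard deviation (default
#'   0.25, a realistic label-free MS1 replicate CV of about 19\%).
#' @param baselineMean,baselineSd mean and sd of per-protein baseline
#'   log2 intensity.
#' @param fracSinglePeptide fraction of filler proteins assigned exactly one
#'   unique peptide, to exercise the two-peptide identification filter.
#'   Curated module members are always assigned >= 2 peptides: they emulate
#'   proteins the study quantified confidently.
#' @param plantedSets list of planted coordinated shifts; each element a list
#'   with \code{name}, and optionally \code{size}, \code{members},
#'   \code{fracShifted} (default 0.8), \code{effect} (log2 units, default 1),
#'   \code{regions} (where the shift is planted), \code{direction} (+1
#'   activation / -1 inhibition, scalar or named by region), \code{directed}
#'   (emit direction annotations, default TRUE). A name matching a curated
#'   module uses its members, directions and key regulators.
#' @param plantedAnalyteEffects data.frame with columns analyte, region,
#'   genotype, direction (+1/-1), fold (>1) applied to the 7-month group.
#' @param analyteBaseline named vector of true concentrations (ng/mg).
#' @param lod named (or scalar) per-analyte detection limit, ng/mg.
#' @param absentAnalytes analytes with true level zero everywhere (all
#'   records below LOD), e.g. serotonin in this model.
#' @param chemCv log-normal coefficient of variation of analyte
#'   measurements (default 0.15).
#' @param seed master seed; all stage streams derive from it.
#' @return A validated \code{SimConfig} list.
#' @export
simConfig <- function(nProteins = 2000,
                      nRepProt = 3,
                      nRepChem = 4,
                      regions = brainRegions(),
                      noiseSd = 0.25,
                      baselineMean = 23,
                      baselineSd = 1.5,
                      fracSinglePeptide = 0.1,
                      plantedSets = list(),
                      plantedAnalyteEffects = NULL,
                      analyteBaseline = defaultAnalyteBaseline(),
                      lod = 0.1,
                      absentAnalytes = character(0),
                      chemCv = 0.15,
                      seed = 1) {
    stopifnot(nProteins >= 1, nRepProt >= 2, nRepChem >= 2,
              length(regions) >= 1)
    if (noiseSd <= 0) stop("noiseSd must be positive")
    panel <- analytePanel()
    base <- defaultAnalyteBaseline()
    base[names(analyteBaseline)] <- analyteBaseline
    base[absentAnalytes] <- 0
    if (length(lod) == 1L) lod <- structure(rep(lod, length(panel)),
                                            names = panel)
    if (any(lod < 0)) stop("detection limits must be non-negative")
    if (!all(panel %in% names(lod))) stop("lod must cover the analyte panel")

    cfg <- list(nProteins = as.integer(nProteins),
                nRepProt = as.integer(nRepProt),
                nRepChem = as.integer(nRepChem),
                regions = regions,
                genotypes = genotypeLevels(), ages = ageLevels(),
                noiseSd = noiseSd, baselineMean = baselineMean,
                baselineSd = baselineSd,
                fracSinglePeptide = fracSinglePeptide,
                plantedAnalyteEffects = plantedAnalyteEffects,
                analyteBaseline = base[panel], lod = lod[panel],
                absentAnalytes = absentAnalytes,
                chemCv = chemCv, seed = as.integer(seed))

    universe <- proteinUniverse(cfg)
    canon <- canonicalModuleDefs()
    used <- character(0)
    norm <- list()
    nms <- vapply(plantedSets, function(e) e$name, character(1))
    if (anyDuplicated(nms)) stop("duplicate planted set names")
    set.seed(childSeed(seed, "planted-set-members"))
    for (entry in plantedSets) {
        e <- entry
        e$fracShifted <- e$fracShifted %||% 0.8
        e$effect <- e$effect %||% 1
        e$directed <- e$directed %||% TRUE
        e$direction <- e$direction %||% 1
        e$regions <- e$regions %||% regions[1]
        if (e$fracShifted <= 0 || e$fracShifted > 1)
            stop("fracShifted must lie in (0, 1]")
        if (!all(e$regions %in% regions))
            stop("planted set '", e$name, "' names an unknown region")
        if (e$name %in% names(canon)) {
            def <- canon[[e$name]]
            e$members <- c(def$up, def$down)
            e$annotation <- structure(c(rep(1L, length(def$up)),
                                        rep(-1L, length(def$down))),
                                      names = e$members)
            e$keyRegulators <- def$key
        } else if (is.null(e$members)) {
            if (is.null(e$size)) stop("planted set '", e$name,
                                      "' needs a size or explicit members")
            if (e$size > cfg$nProteins)
                stop("planted set '", e$name,
                     "' is larger than the protein universe")
            pool <- setdiff(universe, c(canonicalModuleMembers(), used))
            e$members <- sample(pool, e$size)
            e$annotation <- structure(rep(as.integer(sign(e$direction[1])),
                                          e$size), names = e$members)
            e$keyRegulators <- e$keyRegulators %||% character(0)
        } else {
            e$annotation <- e$annotation %||%
                structure(rep(1L, length(e$members)), names = e$members)
            e$keyRegulators <- e$keyRegulators %||% character(0)
        }
        if (!all(e$members %in% universe))
            stop("planted set '", e$name, "' has members outside the universe")
        e$size <- length(e$members)
        nShift <- max(1L, ceiling(e$fracShifted * e$size))
        first <- intersect(e$keyRegulators, e$members)
        extra <- sample(setdiff(e$members, first))
        e$shifted <- c(first, extra)[seq_len(nShift)]
        used <- union(used, e$members)
        norm[[e$name]] <- e
    }
    cfg$plantedSets <- norm

    if (!is.null(plantedAnalyteEffects)) {
        pae <- plantedAnalyteEffects
        if (is.list(pae) && !is.data.frame(pae))  # YAML: list of records
            pae <- do.call(rbind, lapply(pae, as.data.frame))
        pae <- as.data.frame(pae)
        need <- c("analyte", "region", "genotype", "direction", "fold")
        if (!all(need %in% names(pae)))
            stop("plantedAnalyteEffects needs columns: ",
                 paste(need, collapse = ", "))
        if (!all(pae$analyte %in% panel)) stop("unknown analyte in planted effects")
        if (!all(pae$region %in% regions)) stop("unknown region in planted effects")
        if (!all(pae$direction %in% c(-1, 1))) stop("directions must be +1/-1")
        if (any(pae$fold <= 1)) stop("fold changes must exceed 1")
        cfg$plantedAnalyteEffects <- pae
    }
    class(cfg) <- "SimConfig"
    cfg
}

#' @export
print.SimConfig <- function(x, ...) {
    cat("SimConfig:", x$nProteins, "proteins,",
        length(x$regions), "regions,",
        x$nRepProt, "proteomic /", x$nRepChem, "neurochemical replicates\n")
    cat("  planted sets:", length(x$plantedSets),
        "| planted analyte effects:",
        if (is.null(x$plantedAnalyteEffects)) 0
        else nrow(x$plantedAnalyteEffects), "\n")
    invisible(x)
}

#' Simulate a multi-region label-free proteome with known ground truth
#'
#' Draws per-protein baseline log2 intensities, adds log-normal replicate
#' noise, and applies every planted coordinated shift to the TG 7-month
#' group of its designated regions (member shift = module direction x member
#' annotation x effect, in log2 units). Unique-peptide counts are attached
#' per protein with a configurable single-peptide fraction among filler
#' proteins.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A list with \code{se}, a
#'   \link[SummarizedExperiment]{SummarizedExperiment} (assay
#'   \code{"intensity"}; rowData \code{uniquePeptides}; colData region,
#'   genotype, age_months, replicate), and \code{truth}, the ground-truth
#'   record (planted protein effects per region, true modules, planted set
#'   membership).
#' @export
simulateProteome <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    universe <- proteinUniverse(config)
    n <- config$nProteins

    set.seed(childSeed(config$seed, "proteome-baseline"))
    baseline <- rnorm(n, config$baselineMean, config$baselineSd)
    names(baseline) <- universe

    # peptide evidence: abundance-linked, curated members always >= 2
    canon <- canonicalModuleMembers()
    fill <- setdiff(universe, canon)
    nSingle <- round(config$fracSinglePeptide * length(fill))
    singles <- fill[order(baseline[fill])][seq_len(nSingle)]
    pep <- 2L + rpois(n, lambda = pmax(0.5, (baseline - config$baselineMean)/
                                                config$baselineSd + 3))
    names(pep) <- universe
    pep[singles] <- 1L

    groups <- expand.grid(replicate = seq_len(config$nRepProt),
                          age_months = config$ages,
                          genotype = config$genotypes,
                          region = config$regions,
                          stringsAsFactors = FALSE)
    groups <- groups[, c("region", "genotype", "age_months", "replicate")]
    sampleIds <- with(groups, paste(region, genotype, age_months, replicate,
                                    sep = "_"))

    # planted log2 effects per (protein, region), applied to TG at 7 months
    effects <- matrix(0, n, length(config$regions),
                      dimnames = list(universe, config$regions))
    trueModules <- list(); planted <- list()
    for (e in config$plantedSets) {
        dirByRegion <- e$direction
        if (is.null(names(dirByRegion)))
            dirByRegion <- structure(rep(dirByRegion[1], length(e$regions)),
                                     names = e$regions)
        for (r in e$regions) {
            d <- as.integer(sign(dirByRegion[[r]]))
            effects[e$shifted, r] <- d * e$annotation[e$shifted] * e$effect
            trueModules[[length(trueModules) + 1L]] <-
                data.frame(region = r, module = e$name, direction = d)
        }
        planted[[e$name]] <- list(members = e$members,
                                  annotation = e$annotation,
                                  shifted = e$shifted,
                                  keyRegulators = e$keyRegulators)
    }

    set.seed(childSeed(config$seed, "proteome-noise"))
    log2mat <- matrix(rnorm(n * nrow(groups), sd = config$noiseSd),
                      nrow = n) + baseline
    tg7 <- groups$genotype == "TG" & groups$age_months == max(config$ages)
    for (j in which(tg7))
        log2mat[, j] <- log2mat[, j] + effects[, groups$region[j]]

    intens <- 2^log2mat
    dimnames(intens) <- list(universe, sampleIds)

    se <- SummarizedExperiment(
        assays = list(intensity = intens),
        rowData = S4Vectors::DataFrame(uniquePeptides = pep,
                                       row.names = universe),
        colData = S4Vectors::DataFrame(groups, row.names = sampleIds))

    eff <- which(effects != 0, arr.ind = TRUE)
    proteinEffects <- data.frame(
        protein = universe[eff[, 1]],
        region = config$regions[eff[, 2]],
        effect = effects[eff])
    truth <- structure(list(
        proteinEffects = proteinEffects,
        trueModules = if (length(trueModules)) do.call(rbind, trueModules)
                      else data.frame(region = character(0),
                                      module = character(0),
                                      direction = integer(0)),
        plantedSets = planted), class = "GroundTruth")
    list(se = se, truth = truth)
}

#' Simulate the HPLC-ECD neurochemical panel with censoring
#'
#' Generates the long-format analyte table over the full
#' analyte x region x genotype x age x replicate factorial, with log-normal
#' measurement noise, planted fold changes applied to the 7-month group, and
#' left-censoring at each analyte's detection limit. An analyte with true
#' level zero (an "absent" analyte) yields all-flagged records in every
#' region, emulating a transmitter undetectable across the brain.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A list with \code{table}, the long-format data.frame (analyte,
#'   region, genotype, age_months, replicate, value_ng_per_mg, below_lod;
#'   attribute \code{lod} carries the per-analyte limits), and \code{truth}
#'   (true analyte directions and undetected cells).
#' @export
simulateNeurochem <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    panel <- analytePanel()
    grid <- expand.grid(replicate = seq_len(config$nRepChem),
                        age_months = config$ages,
                        genotype = config$genotypes,
                        region = config$regions,
                        analyte = panel,
                        stringsAsFactors = FALSE)
    grid <- grid[, c("analyte", "region", "genotype", "age_months",
                     "replicate")]

    level <- unname(config$analyteBaseline[grid$analyte])
    pae <- config$plantedAnalyteEffects
    trueAnalytes <- NULL
    if (!is.null(pae) && nrow(pae)) {
        for (i in seq_len(nrow(pae))) {
            hit <- grid$analyte == pae$analyte[i] &
                grid$region == pae$region[i] &
                grid$genotype == pae$genotype[i] &
                grid$age_months == max(config$ages)
            level[hit] <- level[hit] * pae$fold[i]^pae$direction[i]
        }
        trueAnalytes <- pae[, c("region", "analyte", "genotype", "direction")]
    }

    set.seed(childSeed(config$seed, "neurochem-noise"))
    value <- level * rlnorm(nrow(grid), meanlog = 0, sdlog = config$chemCv)
    value[level == 0] <- 0
    below <- value < unname(config$lod[grid$analyte])

    tab <- data.frame(grid, value_ng_per_mg = value, below_lod = below)
    attr(tab, "lod") <- config$lod

    und <- unique(tab[tab$analyte %in% config$absentAnalytes,
                      c("region", "analyte")])
    rownames(und) <- NULL
    truth <- structure(list(
        trueAnalytes = if (is.null(trueAnalytes))
            data.frame(region = character(0), analyte = character(0),
                       genotype = character(0), direction = integer(0))
        else trueAnalytes,
        undetectedAnalytes = und), class = "GroundTruth")
    list(table = tab, truth = truth)
}

#' Build a gene-set collection matching a simulation configuration
#'
#' Emits the four curated directed signaling modules (dopamine/serotonin
#' receptor signaling and degradation, with their key regulators), one
#' DirectedGeneSet per planted set in the configuration, and random
#' undirected hallmark-like filler sets drawn from the protein universe.
#'
#' @param config a \code{\link{simConfig}}.
#' @param nFiller number of random undirected filler sets.
#' @param sizeRange inclusive size range of filler sets.
#' @return A \linkS4class{DirectedGeneSetCollection}.
#' @export
makeGeneSets <- function(config, nFiller = 10, sizeRange = c(10, 40)) {
    stopifnot(inherits(config, "SimConfig"), sizeRange[1] >= 2)
    universe <- proteinUniverse(config)
    sets <- list()
    for (nm in names(canonicalModuleDefs())) {
        def <- canonicalModuleDefs()[[nm]]
        members <- c(def$up, def$down)
        sets[[nm]] <- DirectedGeneSet(
            nm, members,
            directions = structure(c(rep(1L, length(def$up)),
                                     rep(-1L, length(def$down))),
                                   names = members),
            keyRegulators = def$key)
    }
    for (e in config$plantedSets) {
        if (e$name %in% names(sets)) next
        sets[[e$name]] <- DirectedGeneSet(
            e$name, e$members,
            directions = if (e$directed) e$annotation else integer(0),
            keyRegulators = e$keyRegulators)
    }
    set.seed(childSeed(config$seed, "filler-sets"))
    for (i in seq_len(nFiller)) {
        size <- min(config$nProteins,
                    sample(seq(sizeRange[1], sizeRange[2]), 1))
        nm <- sprintf("RANDOM_SET_%02d", i)
        sets[[nm]] <- DirectedGeneSet(nm, sample(universe, size))
    }
    DirectedGeneSetCollection(sets)
}

#' Derive an mRNA direction table from proteomic ground truth
#'
#' Copies per-(target, region) direction calls from the planted protein
#' effects, then corrupts a stated fraction: flipped in sign
#' (\code{mode = "flip"}) or set to no significant change
#' (\code{mode = "drop"}). Supports qualitative mRNA-protein concordance
#' assessment against a transcript layer.
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{simulateProteome}}.
#' @param flipFraction fraction of pairs corrupted, in [0, 1].
#' @param seed integer seed.
#' @param mode \code{"flip"} or \code{"drop"}.
#' @return data.frame with columns target, region, direction
#'   (\code{"up"/"down"/"flat"}).
#' @export
makeMrnaTable <- function(truth, flipFraction = 0, seed = 1,
                          mode = c("flip", "drop")) {
    mode <- match.arg(mode)
    if (flipFraction < 0 || flipFraction > 1)
        stop("flipFraction must lie in [0, 1]")
    pe <- truth$proteinEffects
    tab <- data.frame(target = pe$protein, region = pe$region,
                      direction = ifelse(pe$effect > 0, "up", "down"))
    set.seed(childSeed(seed, "mrna-flips"))
    nFlip <- round(flipFraction * nrow(tab))
    idx <- sample(nrow(tab), nFlip)
    if (mode == "flip") {
        tab$direction[idx] <- ifelse(tab$direction[idx] == "up", "down", "up")
    } else {
        tab$direction[idx] <- "flat"
    }
    attr(tab, "flipped") <- sort(idx)
    tab
}

#' Planted multi-region signaling-module scenario
#'
#' A ready-made configuration planting the qualitative regional pattern of
#' coordinated neurotransmitter and pathway change used for end-to-end
#' recovery testing: hippocampus carries dopamine receptor signaling
#' activation (dopamine up) plus serotonin degradation activation (5HIAA
#' up); cortex carries serotonin degradation activation only; cerebellum
#' carries dopamine degradation activation (DOPAC up) and serotonin
#' degradation activation. Serotonin itself is configured absent (all
#' records below the detection limit in every region), so
#' serotonin-receptor concordance is never evaluable.
#'
#' @param seed master seed.
#' @param nProteins protein universe size.
#' @return A \code{\link{simConfig}}; its planted truth is recovered by
#'   \code{\link{runPipeline}} at default settings.
#' @export
signalingModuleScenario <- function(seed = 1, nProteins = 2000) {
    simConfig(
        nProteins = nProteins,
        seed = seed,
        plantedSets = list(
            list(name = "DA receptor signaling", regions = "Hip",
                 direction = 1),
            list(name = "DA degradation signaling", regions = "CB",
                 direction = 1),
            list(name = "5-HT degradation signaling",
                 regions = c("Hip", "Ctx", "CB"), direction = 1)),
        plantedAnalyteEffects = data.frame(
            analyte = c("DA", "5HIAA", "5HIAA", "5HIAA", "DOPAC"),
            region = c("Hip", "Hip", "Ctx", "CB", "CB"),
            genotype = "TG",
            direction = 1,
            fold = 2),
        absentAnalytes = "5HT")
}
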