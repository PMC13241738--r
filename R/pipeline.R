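#' Assemble and validate a pipeline configuration
#'
#' One structured configuration drives the whole run: the simulation block
#' (a \code{\link{simConfig}} or its argument list), the
#' disease-progression contrast, enrichment settings, neurochemistry
#' settings and integration settings. A YAML file with the same structure
#' is accepted via \code{readPipelineConfig}.
#'
#' @param simulation a \code{SimConfig}, or a list of
#'   \code{\link{simConfig}} arguments.
#' @param contrast list: \code{genotype} (default \code{"TG"}),
#'   \code{ageA} (4) and \code{ageB} (7); the per-region differential
#'   contrast is ageB vs ageA within the genotype.
#' @param enrichment list: \code{nPerm} (1000), \code{weight} (1),
#'   \code{preset} (\code{"strict"}), \code{minSize} (3), \code{maxSize}
#'   (500).
#' @param neurochem list: \code{genotype} (\code{"TG"}), \code{alpha}
#'   (0.05).
#' @param integration list: \code{k} (1), \code{sigRule}
#'   (\code{list(alpha = 0.05, on = "p")}), \code{map} (default analyte
#'   map).
#' @param seed master seed; overrides the simulation block's seed so all
#'   randomness flows from one place.
#' @return A validated \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(simulation, contrast = list(),
                           enrichment = list(), neurochem = list(),
                           integration = list(), seed = 1) {
    if (!inherits(simulation, "SimConfig")) {
        if (!is.list(simulation))
            stop("config field 'simulation' must be a SimConfig or a list")
        simulation$seed <- seed
        simulation <- do.call(simConfig, simulation)
    } else {
        simulation$seed <- as.integer(seed)
    }
    merge <- function(defaults, given) {
        for (nm in names(given)) defaults[[nm]] <- given[[nm]]
        defaults
    }
    cfg <- list(
        simulation = simulation,
        contrast = merge(list(genotype = "TG", ageA = 4, ageB = 7), contrast),
        enrichment = merge(list(nPerm = 1000, weight = 1, preset = "strict",
                                minSize = 3, maxSize = 500), enrichment),
        neurochem = merge(list(genotype = "TG", alpha = 0.05), neurochem),
        integration = merge(list(k = 1,
                                 sigRule = list(alpha = 0.05, on = "p"),
                                 map = defaultAnalyteModuleMap()),
                            integration),
        seed = as.integer(seed))
    if (!cfg$contrast$genotype %in% genotypeLevels())
        stop("config field 'contrast$genotype' must be WT or TG")
    if (cfg$enrichment$nPerm < 100)
        stop("config field 'enrichment$nPerm' must be >= 100")
    class(cfg) <- "PipelineConfig"
    cfg
}

#' @rdname pipelineConfig
#' @param path YAML file with top-level keys simulation, contrast,
#'   enrichment, neurochem, integration, seed.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (is.null(y$simulation))
        stop("pipeline config is missing required field 'simulation'")
    pipelineConfig(simulation = y$simulation,
                   contrast = y$contrast %||% list(),
                   enrichment = y$enrichment %||% list(),
                   neurochem = y$neurochem %||% list(),
                   integration = y$integration %||% list(),
                   seed = y$seed %||% 1)
}

#' Run the end-to-end signaling-module pipeline
#'
#' Executes simulate -> normalize/filter -> per-region differential tests
#' -> preranked enrichment and direction-aware activation scoring ->
#' neurotransmitter direction calls -> concordance-based module selection,
#' writing every intermediate artifact plus a machine-readable run report
#' into \code{outdir}. Deterministic for a fixed configuration and seed.
#'
#' @param config a \code{\link{pipelineConfig}} (or YAML path).
#' @param outdir output directory, created if needed. \code{NULL} skips
#'   file output.
#' @return Invisibly, a list with \code{report} (per-stage counts,
#'   thresholds and seeds), \code{moduleCalls}, \code{gsea},
#'   \code{activations}, \code{directionCalls}, \code{diffResults} and the
#'   simulated \code{truth}.
#' @export
runPipeline <- function(config, outdir = NULL) {
    if (is.character(config)) config <- readPipelineConfig(config)
    stopifnot(inherits(config, "PipelineConfig"))
    if (!is.null(outdir) && !dir.exists(outdir))
        dir.create(outdir, recursive = TRUE)
    outfile <- function(name) file.path(outdir, name)

    sc <- config$simulation
    prot <- simulateProteome(sc)
    chem <- simulateNeurochem(sc)
    collection <- makeGeneSets(sc)

    se <- normalizeTotal(prot$se)
    nBefore <- nrow(se)
    se <- filterMinPeptides(se)
    nAfter <- nrow(se)

    ct <- config$contrast
    en <- config$enrichment
    diffResults <- list(); gseaTabs <- list(); actTabs <- list()
    directed <- names(collection)[vapply(as.list(collection), function(s)
        length(memberDirections(s)) > 0, logical(1))]
    for (region in sc$regions) {
        groupA <- list(region = region, genotype = ct$genotype,
                       age_months = ct$ageA)
        groupB <- list(region = region, genotype = ct$genotype,
                       age_months = ct$ageB)
        res <- differentialTest(se, groupA, groupB)
        diffResults[[region]] <- res
        ranked <- rankStatistic(res)
        g <- gseaPreranked(ranked, collection, nPerm = en$nPerm,
                           weight = en$weight,
                           seed = childSeed(config$seed, region),
                           minSize = en$minSize, maxSize = en$maxSize)
        gseaTabs[[region]] <- data.frame(region = region, g)
        act <- do.call(rbind, lapply(directed, function(nm)
            activationZscore(res, collection[[nm]],
                             sigRule = config$integration$sigRule,
                             preset = en$preset)))
        actTabs[[region]] <- data.frame(region = region, act)
        if (!is.null(outdir))
            writeRnk(ranked, outfile(paste0("ranked_", region, ".rnk")))
    }
    gseaTab <- do.call(rbind, gseaTabs); rownames(gseaTab) <- NULL
    actTab <- do.call(rbind, actTabs); rownames(actTab) <- NULL

    calls <- neurochemDirectionCalls(chem$table,
                                     genotype = config$neurochem$genotype,
                                     alpha = config$neurochem$alpha)

    moduleCalls <- selectModules(calls, actTab, diffResults, collection,
                                 map = config$integration$map,
                                 sigRule = config$integration$sigRule,
                                 k = config$integration$k)

    report <- list(
        seed = config$seed,
        stages = list(
            simulate = list(proteins = sc$nProteins,
                            samples = ncol(prot$se),
                            neurochemRecords = nrow(chem$table)),
            filter = list(input = nBefore, retained = nAfter,
                          removed = nBefore - nAfter),
            differential = list(regions = length(sc$regions),
                                testedPerRegion = nAfter),
            enrichment = list(sets = length(collection),
                              scored = nrow(gseaTab),
                              nPerm = en$nPerm, weight = en$weight,
                              preset = en$preset),
            neurochem = list(calls = nrow(calls),
                             alpha = config$neurochem$alpha),
            integration = list(records = nrow(moduleCalls),
                               selected = sum(moduleCalls$selected))),
        thresholds = list(minPeptides = 2,
                          sigRule = config$integration$sigRule,
                          preset = en$preset))
    if (!is.null(outdir)) {
        writeAbundance(prot$se, outfile("abundance.tsv"))
        writeGmt(collection, outfile("gene_sets.gmt"))
        writeNeurochem(chem$table, outfile("neurochem.csv"))
        writeGroundTruth(prot$truth, outfile("truth_proteome.json"))
        writeGroundTruth(chem$truth, outfile("truth_neurochem.json"))
        for (region in names(diffResults))
            write.table(diffResults[[region]],
                        outfile(paste0("differential_", region, ".tsv")),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(gseaTab, outfile("gsea.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(actTab, outfile("activation.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(calls, outfile("direction_calls.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(moduleCalls, outfile("module_calls.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        jsonlite::write_json(report, outfile("report.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(list(report = report, moduleCalls = moduleCalls,
                   gsea = gseaTab, activations = actTab,
                   directionCalls = calls, diffResults = diffResults,
                   truth = list(proteome = prot$truth,
                                neurochem = chem$truth),
                   collection = collection))
}
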