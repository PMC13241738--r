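#' Brain-region, group and analyte vocabularies
#'
#' Fixed label vocabularies for the factorial study design: seven brain
#' regions (olfactory bulb, anterior cortex, striatum, hippocampus, thalamus,
#' substantia nigra, cerebellum), WT/TG genotypes, ages 4 and 7 months, and
#' the eleven-analyte HPLC-ECD monoamine panel (transmitters, their acid
#' metabolites and precursor amino acids).
#'
#' @return Character (or numeric, for ages) vector of labels.
#' @export
brainRegions <- function() c("OB", "Ctx", "STR", "Hip", "Tha", "SN", "CB")

#' @rdname brainRegions
#' @export
genotypeLevels <- function() c("WT", "TG")

#' @rdname brainRegions
#' @export
ageLevels <- function() c(4, 7)

#' @rdname brainRegions
#' @export
analytePanel <- function() {
    c("VMA", "NE", "Epi", "DOPAC", "DA", "5HIAA", "HVA", "3MT", "5HT",
      "TRP", "TYR")
}

# Deterministic child seed for a named random stream, so every stage draws
# from an independent stream reproducibly derived from one master seed.
# Kept below 2^31 - 1.
childSeed <- function(seed, stream) {
    h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
    (as.numeric(seed) * 7919 + h * 104729) %% 2147483647
}

# Evaluate a significance rule against a differential result data.frame.
# A rule is either a function(result) -> logical, or a list(alpha=, on=)
# where `on` is "p" (raw p) or "q" (BH-adjusted).
evalSigRule <- function(result, sigRule = list(alpha = 0.05, on = "p")) {
    if (is.function(sigRule)) {
        keep <- sigRule(result)
        if (!is.logical(keep) || length(keep) != nrow(result))
            stop("a significance-rule function must return one logical per protein")
        return(keep)
    }
    on <- match.arg(sigRule$on %||% "p", c("p", "q"))
    alpha <- sigRule$alpha %||% 0.05
    result[[on]] < alpha
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sidak family-wise adjustment
#'
#' Adjusts p-values for a family of m comparisons as
#' \eqn{p_{adj} = 1 - (1 - p)^m}, the correction used for simple-effect
#' contrasts after two-way ANOVA.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @param m family size; defaults to \code{length(p)}.
#' @return Adjusted p-values, capped at 1.
#' @examples
#' sidakAdjust(0.01, m = 3)  # 1 - 0.99^3 = 0.029701
#' @export
sidakAdjust <- function(p, m = length(p)) {
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    if (m < 1) stop("family size m must be >= 1")
    pmin(1, 1 - (1 - p)^m)
}

#' Benjamini-Hochberg adjustment with input validation
#'
#' Standard step-up false-discovery-rate adjustment with monotone
#' enforcement, as applied across proteins and across gene-ontology terms.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return BH-adjusted q-values in (0, 1].
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}
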