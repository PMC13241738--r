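#' @importFrom stats lm coef pt aggregate
NULL

#' Concentration from detector peak areas
#'
#' With a single standard, concentration follows by proportionality of peak
#' areas; with two or more standards an ordinary least-squares calibration
#' line (area on concentration) is fitted and inverted at the sample area.
#' A sample area outside the calibrated range is still quantified but
#' carries an \code{extrapolated} attribute (and a warning).
#'
#' @param sampleArea detector peak area of the sample.
#' @param standardAreas peak areas of the calibration standards.
#' @param standardConcs known standard concentrations (same order).
#' @return Estimated concentration, with attribute \code{extrapolated}.
#' @examples
#' quantifyFromPeaks(50, 100, 20)                  # 10
#' quantifyFromPeaks(100, c(0, 100), c(0, 20))     # 20
#' @export
quantifyFromPeaks <- function(sampleArea, standardAreas, standardConcs) {
    if (length(standardAreas) != length(standardConcs) ||
        !length(standardAreas))
        stop("need at least one (area, concentration) standard pair")
    if (sampleArea <= 0 || any(standardAreas < 0))
        stop("peak areas must be positive")
    if (length(standardAreas) == 1L) {
        # single-point proportionality: the whole positive axis is in range
        conc <- sampleArea / standardAreas * standardConcs
        attr(conc, "extrapolated") <- FALSE
        return(conc)
    } else {
        fit <- lm(standardAreas ~ standardConcs)
        b <- coef(fit)
        if (abs(b[2]) < .Machine$double.eps)
            stop("degenerate calibration: zero slope")
        conc <- unname((sampleArea - b[1]) / b[2])
    }
    extrap <- sampleArea < min(standardAreas) ||
        sampleArea > max(standardAreas)
    if (extrap)
        warning("sample area outside the calibrated range; extrapolating")
    attr(conc, "extrapolated") <- extrap
    conc
}

#' Normalize analyte amount to tissue protein content
#'
#' @param amount analyte mass (e.g. ng).
#' @param proteinMg tissue protein mass in mg (> 0).
#' @return Concentration per mg protein.
#' @export
normalizeToProtein <- function(amount, proteinMg) {
    if (any(proteinMg <= 0)) stop("protein mass must be positive")
    amount / proteinMg
}

#' Censoring status of neurochemical cells
#'
#' Classifies each (analyte, region, genotype, age) cell as
#' \code{"undetected"} (all replicates below the detection limit),
#' \code{"quantified"} (none below), or \code{"partially_censored"}.
#'
#' @param table long-format neurochemical table (see
#'   \code{\link{simulateNeurochem}}).
#' @param cell optional list/row with \code{analyte}, \code{region},
#'   \code{genotype}, \code{age_months} to query a single cell.
#' @return With \code{cell}, a single status string (error if the cell is
#'   empty); otherwise a data.frame of statuses for all populated cells.
#' @export
censorSummary <- function(table, cell = NULL) {
    if (!is.null(cell)) {
        rows <- table$analyte == cell$analyte & table$region == cell$region &
            table$genotype == cell$genotype &
            table$age_months == cell$age_months
        if (!any(rows)) stop("empty cell requested")
        flag <- table$below_lod[rows]
        return(if (all(flag)) "undetected"
               else if (!any(flag)) "quantified" else "partially_censored")
    }
    agg <- aggregate(below_lod ~ analyte + region + genotype + age_months,
                     data = table,
                     FUN = function(f) c(n = length(f), nc = sum(f)))
    st <- agg$below_lod
    status <- ifelse(st[, "nc"] == st[, "n"], "undetected",
                     ifelse(st[, "nc"] == 0, "quantified",
                            "partially_censored"))
    data.frame(agg[, c("analyte", "region", "genotype", "age_months")],
               status = status)
}

#' Two-way ANOVA with Sidak-adjusted simple-effect contrasts
#'
#' Fits a two-factor fixed-effects ANOVA with interaction for one analyte
#' and tests the requested simple effects (7-month vs 4-month difference
#' within each level of the crossing factor) against the pooled residual
#' mean square, adjusting the contrast family by the Sidak correction
#' \eqn{p_{adj} = 1 - (1 - p)^m}. Records flagged below the detection limit
#' are substituted by LOD/2 (standard left-censoring practice); cells with
#' every replicate censored are excluded from the model and propagated as
#' undetected.
#'
#' @param table long-format neurochemical table.
#' @param analyte analyte to test.
#' @param factors the two crossed factors: \code{c("region", "age_months")}
#'   (default; one family of per-region age contrasts within a fixed
#'   genotype) or \code{c("genotype", "age_months")} (fixed region).
#' @param genotype,region the fixed stratum, depending on \code{factors}.
#' @param lod per-analyte detection limit; default taken from the table's
#'   \code{lod} attribute.
#' @return list with \code{contrasts}: data.frame (analyte, level, effect =
#'   mean 7 mo - mean 4 mo, t, df, pRaw, pAdj, status), \code{anova}: the
#'   model ANOVA table, and \code{mse}. If every cell is censored the
#'   analyte is skipped: all levels return status \code{"undetected"} with
#'   NA statistics.
#' @export
twoWayAnovaSidak <- function(table, analyte,
                             factors = c("region", "age_months"),
                             genotype = "TG", region = NULL,
                             lod = NULL) {
    stopifnot(length(factors) == 2, "age_months" %in% factors)
    crossFactor <- setdiff(factors, "age_months")
    dat <- table[table$analyte == analyte, , drop = FALSE]
    if (crossFactor == "region") {
        dat <- dat[dat$genotype == genotype, , drop = FALSE]
    } else {
        if (is.null(region)) stop("fix a region for the genotype x age model")
        dat <- dat[dat$region == region, , drop = FALSE]
    }
    if (!nrow(dat)) stop("no records for analyte '", analyte, "'")

    if (is.null(lod)) {
        lods <- attr(table, "lod")
        lod <- if (!is.null(lods)) unname(lods[analyte]) else 0
    }
    dat$value <- ifelse(dat$below_lod, lod / 2, dat$value_ng_per_mg)

    levels1 <- unique(dat[[crossFactor]])
    # censor bookkeeping per cell; wholly censored cells leave the model
    cellKey <- interaction(dat[[crossFactor]], dat$age_months, drop = TRUE)
    wholly <- tapply(dat$below_lod, cellKey, all)
    dat$cens <- wholly[as.character(cellKey)]
    model <- dat[!dat$cens, , drop = FALSE]

    emptyRow <- function(lev, status) data.frame(
        analyte = analyte, level = lev, effect = NA_real_, t = NA_real_,
        df = NA_real_, pRaw = NA_real_, pAdj = NA_real_, status = status)

    if (!nrow(model) ||
        length(unique(model[[crossFactor]])) < 2 ||
        length(unique(model$age_months)) < 2) {
        out <- do.call(rbind, lapply(levels1, emptyRow, status = "undetected"))
        return(list(contrasts = out, anova = NULL, mse = NA_real_))
    }

    f1 <- factor(model[[crossFactor]])
    f2 <- factor(model$age_months)
    fit <- lm(model$value ~ f1 * f2)
    an <- stats::anova(fit)
    mse <- an["Residuals", "Mean Sq"]
    dfRes <- an["Residuals", "Df"]

    rows <- list()
    for (lev in levels1) {
        sub <- model[model[[crossFactor]] == lev, ]
        y4 <- sub$value[sub$age_months == min(table$age_months)]
        y7 <- sub$value[sub$age_months == max(table$age_months)]
        if (length(y4) < 2 || length(y7) < 2) {
            rows[[as.character(lev)]] <- emptyRow(lev, "undetected")
            next
        }
        eff <- mean(y7) - mean(y4)
        tt <- eff / sqrt(mse * (1 / length(y4) + 1 / length(y7)))
        p <- 2 * pt(-abs(tt), dfRes)
        rows[[as.character(lev)]] <- data.frame(
            analyte = analyte, level = lev, effect = eff, t = tt, df = dfRes,
            pRaw = p, pAdj = NA_real_, status = "tested")
    }
    out <- do.call(rbind, rows)
    tested <- out$status == "tested"
    m <- sum(tested)
    if (m > 0) out$pAdj[tested] <- sidakAdjust(out$pRaw[tested], m = m)
    rownames(out) <- NULL
    list(contrasts = out, anova = an, mse = mse)
}

#' Direction call for one adjusted contrast
#'
#' \code{"up"} if the Sidak-adjusted p is below alpha with positive effect,
#' \code{"down"} with negative effect, \code{"flat"} otherwise;
#' \code{"undetected"} cells carry no p-value.
#'
#' @param contrasts a contrast data.frame from
#'   \code{\link{twoWayAnovaSidak}}.
#' @param alpha significance level (default 0.05).
#' @return The data.frame with a \code{direction} column.
#' @export
directionCall <- function(contrasts, alpha = 0.05) {
    dir <- rep("flat", nrow(contrasts))
    dir[contrasts$status == "undetected"] <- "undetected"
    sig <- contrasts$status == "tested" & !is.na(contrasts$pAdj) &
        contrasts$pAdj < alpha
    dir[sig & contrasts$effect > 0] <- "up"
    dir[sig & contrasts$effect < 0] <- "down"
    contrasts$direction <- dir
    contrasts
}

#' Per-(region, analyte) direction calls for the whole panel
#'
#' Runs the per-region age contrast family (two-way region x age ANOVA with
#' Sidak adjustment, 7 vs 4 months within each region) for every analyte in
#' one genotype and returns the combined direction-call table.
#'
#' @param table long-format neurochemical table.
#' @param genotype genotype stratum (default \code{"TG"}).
#' @param alpha significance level.
#' @param lod optional per-analyte detection-limit override.
#' @return data.frame: analyte, region, genotype, direction, effect,
#'   adjusted_p.
#' @export
neurochemDirectionCalls <- function(table, genotype = "TG", alpha = 0.05,
                                    lod = NULL) {
    out <- list()
    for (an in unique(table$analyte)) {
        lodAn <- if (!is.null(lod)) unname(lod[an]) else NULL
        res <- twoWayAnovaSidak(table, an, genotype = genotype, lod = lodAn)
        cc <- directionCall(res$contrasts, alpha = alpha)
        out[[an]] <- data.frame(analyte = an, region = cc$level,
                                genotype = genotype,
                                direction = cc$direction,
                                effect = cc$effect, adjusted_p = cc$pAdj)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
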