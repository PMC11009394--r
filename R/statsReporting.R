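# Numerical post-processing: group comparisons, multiple-testing control,
# efficiency-corrected qPCR ratios, stretch-membrane strain geometry,
# volcano-threshold filtering, intensity-in-mask summaries.

#' Compare experimental groups
#'
#' Two groups: two-sided unpaired t test (Student pooled-variance by
#' default, Welch optionally). More than two groups: one-way ANOVA followed
#' by all pairwise unpaired t tests with Benjamini-Hochberg adjustment
#' across the pairs.
#'
#' @param groups named list of numeric vectors, each of length >= 2
#' @param varEqual pooled-variance t tests (\code{FALSE} = Welch)
#' @return object of class \code{GroupComparison}: per-group summary
#'   (n, mean, sd, sem), the test name, statistic and p value, and for
#'   multi-group designs the ANOVA p plus the BH-adjusted pairwise table
#' @export
compareGroups <- function(groups, varEqual = TRUE) {
    stopifnot(is.list(groups), length(groups) >= 2L)
    if (is.null(names(groups)) || any(!nzchar(names(groups))))
        names(groups) <- paste0("group", seq_along(groups))
    ns <- vapply(groups, length, 0L)
    if (any(ns < 2L))
        stop("every group needs n >= 2: ",
             paste(names(groups)[ns < 2L], collapse = ", "))
    summ <- data.frame(
        group = names(groups), n = ns,
        mean = vapply(groups, mean, 0),
        sd = vapply(groups, stats::sd, 0))
    summ$sem <- summ$sd / sqrt(summ$n)
    out <- list(summary = summ, varEqual = varEqual)
    if (length(groups) == 2L) {
        tt <- stats::t.test(groups[[1L]], groups[[2L]],
                            var.equal = varEqual)
        out$test <- if (varEqual) "unpaired t test (pooled)"
                    else "Welch t test"
        out$statistic <- unname(tt$statistic)
        out$p <- tt$p.value
    } else {
        vals <- unlist(groups, use.names = FALSE)
        fac <- factor(rep(names(groups), ns), levels = names(groups))
        fit <- stats::aov(vals ~ fac)
        an <- summary(fit)[[1L]]
        out$test <- "one-way ANOVA + pairwise t tests (BH)"
        out$statistic <- an[["F value"]][1L]
        out$p <- an[["Pr(>F)"]][1L]
        pairs <- utils::combn(names(groups), 2L)
        pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ])
        res <- apply(pairs, 2L, function(g) {
            tt <- stats::t.test(groups[[g[1L]]], groups[[g[2L]]],
                                var.equal = varEqual)
            c(unname(tt$statistic), tt$p.value)
        })
        pw$t <- res[1L, ]
        pw$p <- res[2L, ]
        pw$p_adj <- bhAdjust(pw$p)
        out$pairwise <- pw
    }
    class(out) <- "GroupComparison"
    out
}

#' @export
print.GroupComparison <- function(x, ...) {
    cat("Group comparison:", x$test, "\n")
    print(x$summary, row.names = FALSE)
    cat(sprintf("statistic = %.4g, p = %.4g\n", x$statistic, x$p))
    if (!is.null(x$pairwise)) {
        cat("pairwise (BH-adjusted):\n")
        print(x$pairwise, row.names = FALSE)
    }
    invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p values, monotone, clipped to 1, in input order.
#'
#' @param p vector of p values in [0, 1]
#' @return adjusted p values
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Efficiency-corrected expression ratio (Pfaffl model)
#'
#' ratio = E_target^dCt_target / E_ref^dCt_ref, with dCt = Ct(control) -
#' Ct(sample) and amplification efficiencies between 1 (no amplification)
#' and ~2.2.
#'
#' @param eTarget,eRef amplification efficiencies in [1, 2.2]
#' @param dCtTarget,dCtRef Ct differences (control - sample)
#' @return the expression ratio
#' @examples pfafflRatio(2, 1, 2, 0) # 2
#' @export
pfafflRatio <- function(eTarget, dCtTarget, eRef, dCtRef) {
    if (eTarget < 1 || eTarget > 2.2 || eRef < 1 || eRef > 2.2)
        stop("efficiencies must lie in [1, 2.2]")
    eTarget^dCtTarget / eRef^dCtRef
}

#' Stretch-membrane strain geometry (spherical-cap model)
#'
#' A circular membrane of radius \code{a} deflected at its centre by
#' \code{h} gains relative area (h/a)^2 under the spherical-cap model; the
#' mean linear strain is sqrt(1 + dA/A) - 1. The area-to-strain conversion
#' is model-independent.
#'
#' @param h centre deflection in mm (>= 0)
#' @param a membrane radius in mm (> 0)
#' @return a [MembraneGeometry-class]
#' @examples
#' membraneStrain(6, 18.09) # ~11% area increase, ~5% linear strain
#' @export
membraneStrain <- function(h, a) {
    if (!is.finite(a) || a <= 0) stop("membrane radius must be positive")
    if (!is.finite(h) || h < 0) stop("cap height must be >= 0")
    dA <- (h / a)^2
    new("MembraneGeometry", capHeight = h, radius = a,
        areaIncrease = dA, linearStrain = strainFromArea(dA))
}

#' @rdname membraneStrain
#' @param areaIncrease relative area increase dA/A
#' @export
strainFromArea <- function(areaIncrease) {
    stopifnot(all(areaIncrease >= 0))
    sqrt(1 + areaIncrease) - 1
}

#' @rdname membraneStrain
#' @param strain mean linear strain
#' @export
areaFromStrain <- function(strain) {
    stopifnot(all(strain >= 0))
    (1 + strain)^2 - 1
}

#' Volcano-threshold filter of a differential-abundance table
#'
#' Classifies records as up-regulated (FC >= \code{fcMin} and
#' p <= \code{pMax}), down-regulated (FC <= 1/\code{fcMin} and
#' p <= \code{pMax}) or not significant; thresholds are inclusive and the
#' down threshold is the reciprocal of the up threshold (symmetric on the
#' log scale).
#'
#' @param table data.frame with columns \code{id}, \code{fold_change} (or
#'   \code{log2fc} with \code{logFC = TRUE}) and \code{p_value}
#' @param fcMin linear fold-change threshold
#' @param pMax p-value threshold
#' @param logFC interpret the fold-change column as log2
#' @return list with \code{nUp}, \code{nDown} and \code{table} (annotated
#'   with a \code{direction} column)
#' @export
volcanoFilter <- function(table, fcMin = 1.5, pMax = 0.05, logFC = FALSE) {
    stopifnot(fcMin > 1, pMax > 0)
    fcCol <- if (logFC) "log2fc" else "fold_change"
    need <- c("id", fcCol, "p_value")
    if (!all(need %in% names(table)))
        stop("table must have columns: ", paste(need, collapse = ", "))
    fc <- if (logFC) 2^table[[fcCol]] else table[[fcCol]]
    bad <- which(!is.finite(fc) | fc <= 0)
    if (length(bad))
        stop("non-positive fold change in row ", bad[1L],
             " (id ", table$id[bad[1L]], ")")
    p <- table$p_value
    dir <- rep("ns", nrow(table))
    dir[fc >= fcMin & p <= pMax] <- "up"
    dir[fc <= 1 / fcMin & p <= pMax] <- "down"
    out <- table
    out$direction <- dir
    list(nUp = sum(dir == "up"), nDown = sum(dir == "down"), table = out)
}

#' Mean intensity within a mask
#'
#' @param img 2D intensity matrix
#' @param mask logical/binary matrix of the same shape, non-empty
#' @return arithmetic mean of \code{img} over mask pixels
#' @export
meanIntensityInMask <- function(img, mask) {
    if (!all(dim(img) == dim(mask)))
        stop("mask and channel differ in shape")
    if (!any(mask > 0)) stop("empty mask")
    mean(img[mask > 0])
}
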