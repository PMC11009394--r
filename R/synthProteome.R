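# Synthetic differential-abundance tables with planted regulation.

#' Generate a proteome table with planted up/down regulation
#'
#' Produces a table of protein records (id, linear fold change, p value) in
#' which exactly \code{nUp} rows satisfy FC >= \code{fcThreshold} and
#' p <= \code{pThreshold}, exactly \code{nDown} satisfy
#' FC <= 1/\code{fcThreshold} and p <= \code{pThreshold}, and every other
#' row strictly fails at least one criterion (either its fold change lies
#' strictly inside the reciprocal band, or its p value strictly exceeds the
#' threshold). Row order is shuffled.
#'
#' @param nProteins total number of rows
#' @param nUp planted up-regulated rows
#' @param nDown planted down-regulated rows
#' @param fcThreshold linear fold-change threshold (> 1)
#' @param pThreshold p-value threshold
#' @param seed RNG seed
#' @return list with \code{table} (a [resultTable()] with columns
#'   \code{id, fold_change, p_value}) and \code{truth}
#'   ([GroundTruth-class]; scalars \code{n_up}, \code{n_down}; objects
#'   carry the planted per-row direction)
#' @export
synthProteomeTable <- function(nProteins = 2000L, nUp = 71L, nDown = 105L,
                               fcThreshold = 1.5, pThreshold = 0.05,
                               seed = 1L) {
    nProteins <- as.integer(nProteins)
    nUp <- as.integer(nUp); nDown <- as.integer(nDown)
    if (nUp + nDown > nProteins)
        stop("contradictory counts: nUp + nDown exceeds nProteins")
    stopifnot(fcThreshold > 1, pThreshold > 0, pThreshold < 1)
    withSeed(seed, {
        nNs <- nProteins - nUp - nDown
        dir <- c(rep("up", nUp), rep("down", nDown), rep("ns", nNs))
        fc <- numeric(nProteins)
        p <- numeric(nProteins)
        iUp <- seq_len(nUp)
        iDown <- nUp + seq_len(nDown)
        iNs <- nUp + nDown + seq_len(max(nNs, 0L))
        if (nUp > 0L) {
            fc[iUp] <- fcThreshold * exp(stats::rexp(nUp, rate = 2.5))
            p[iUp] <- stats::runif(nUp, 0, pThreshold)
        }
        if (nDown > 0L) {
            fc[iDown] <- 1 / (fcThreshold * exp(stats::rexp(nDown, rate = 2.5)))
            p[iDown] <- stats::runif(nDown, 0, pThreshold)
        }
        if (nNs > 0L) {
            # half fail the fold-change band, half fail the p threshold
            failFc <- stats::runif(nNs) < 0.5
            lo <- 1 / fcThreshold
            fc[iNs] <- ifelse(failFc,
                exp(stats::runif(nNs, log(lo) * 0.98, log(fcThreshold) * 0.98)),
                exp(stats::rnorm(nNs, sd = 0.6)))
            p[iNs] <- ifelse(failFc,
                stats::runif(nNs, 0, 1),
                stats::runif(nNs, pThreshold + 1e-9, 1))
        }
        ord <- sample.int(nProteins)
        df <- data.frame(
            id = sprintf("P%05d", seq_len(nProteins)),
            fold_change = fc[ord],
            p_value = p[ord])
        truthDir <- dir[ord]
        tab <- resultTable(df, provenance = list(
            generator = "synthProteomeTable", seed = seed,
            n_up = nUp, n_down = nDown,
            fc_threshold = fcThreshold, p_threshold = pThreshold))
        truth <- GroundTruth(
            objects = data.frame(id = df$id, direction = truthDir),
            scalars = list(n_up = nUp, n_down = nDown,
                           fc_threshold = fcThreshold,
                           p_threshold = pThreshold))
        list(table = tab, truth = truth)
    })
}
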