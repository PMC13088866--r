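#' Additive pathway score per cell
#'
#' The pathway score of a cell is the plain sum of its normalized expression
#' values over the genes of the set — deliberately an unweighted additive
#' score rather than a background-corrected module score. Set genes absent
#' from the matrix contribute 0 and are reported once.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}, or a
#'   numeric gene-by-cell matrix of normalized expression.
#' @param genes character vector of gene symbols forming the set.
#' @return numeric per-cell score vector (named by cell).
#' @examples
#' sce <- normalizeLog(simulateKidney(SimParams(nCells = 50,
#'                                              nBackgroundGenes = 20)))
#' g <- scorePathway(sce, defaultGeneSets()$glycolysis)
#' summary(g)
#' @export
scorePathway <- function(sce, genes) {
    x <- if (methods::is(sce, "SummarizedExperiment"))
        SummarizedExperiment::assay(sce, "logcounts") else sce
    present <- intersect(genes, rownames(x))
    if (!length(present))
        stop("none of the set genes are present in the matrix")
    absent <- setdiff(genes, present)
    if (length(absent))
        message("set genes absent from matrix (contribute 0): ",
                paste(absent, collapse = ", "))
    s <- Matrix::colSums(x[present, , drop = FALSE])
    stats::setNames(as.numeric(s), colnames(x))
}

#' Four-state metabolic classification
#'
#' Cells are classified from their glycolysis and OXPHOS pathway scores and
#' mitochondrial percentage by a fixed rule cascade. With
#' G and O the \code{qHigh} quantiles of the two scores over the classified
#' cells:
#' \enumerate{
#'   \item \code{percent_mt > mtHigh} and both scores below their thresholds
#'     -> \code{Dorm_Mt_high};
#'   \item OXPHOS score >= O and glycolysis < G -> \code{OXPHOS_high};
#'   \item glycolysis >= G and OXPHOS < O -> \code{Glyc};
#'   \item otherwise (including both-high) -> \code{Intermediate}.
#' }
#' The quantile thresholds make the rule scale-free; both cutoffs are
#' configurable. Constant score vectors yield all-Intermediate with a
#' warning.
#'
#' @param glyc,oxphos per-cell pathway scores (aligned vectors).
#' @param percentMT per-cell mitochondrial percentage.
#' @param qHigh quantile defining "high" scores (default 0.60).
#' @param mtHigh mitochondrial percentage threshold (default 25).
#' @return factor with levels \code{OXPHOS_high}, \code{Glyc},
#'   \code{Dorm_Mt_high}, \code{Intermediate}.
#' @export
classifyState <- function(glyc, oxphos, percentMT, qHigh = 0.60,
                          mtHigh = 25) {
    stopifnot(length(glyc) == length(oxphos),
              length(glyc) == length(percentMT))
    lv <- c("OXPHOS_high", "Glyc", "Dorm_Mt_high", "Intermediate")
    if (stats::sd(glyc) == 0 && stats::sd(oxphos) == 0) {
        warning("constant pathway scores: all cells set to Intermediate")
        return(factor(rep("Intermediate", length(glyc)), levels = lv))
    }
    G <- stats::quantile(glyc, qHigh, names = FALSE)
    O <- stats::quantile(oxphos, qHigh, names = FALSE)
    state <- rep("Intermediate", length(glyc))
    r2 <- oxphos >= O & glyc < G
    r3 <- glyc >= G & oxphos < O
    state[r2] <- "OXPHOS_high"
    state[r3] <- "Glyc"
    r1 <- percentMT > mtHigh & glyc < G & oxphos < O
    state[r1] <- "Dorm_Mt_high"
    factor(state, levels = lv)
}

#' Score pathways and classify metabolic states on an experiment
#'
#' Adds \code{glyc_score}, \code{oxphos_score} and \code{metabolic_state} to
#' \code{colData}.
#'
#' @param sce SCE with \code{logcounts} and QC metrics
#'   ([computeQCMetrics()]).
#' @param geneSets named list with \code{glycolysis} and \code{oxphos} sets
#'   (default [defaultGeneSets()]).
#' @inheritParams classifyState
#' @return the annotated SCE.
#' @export
addMetabolicCalls <- function(sce, geneSets = defaultGeneSets(),
                              qHigh = 0.60, mtHigh = 25) {
    sce$glyc_score <- scorePathway(sce, geneSets$glycolysis)
    sce$oxphos_score <- scorePathway(sce, geneSets$oxphos)
    sce$metabolic_state <- classifyState(sce$glyc_score, sce$oxphos_score,
                                         sce$percent_mt, qHigh, mtHigh)
    sce
}

#' Per-cluster expression profile of individual metabolic enzymes
#'
#' Mean normalized expression and percentage of expressing cells (count > 0)
#' per cluster for a panel of enzymes, the table behind violin/dot displays.
#' Missing enzymes yield zero rows with a warning.
#'
#' @param sce SCE with \code{counts} and \code{logcounts}.
#' @param clusters per-cell cluster factor.
#' @param enzymes enzyme symbols (default [metabolicEnzymes()]).
#' @return data.frame with \code{cluster}, \code{enzyme}, \code{mean_expr},
#'   \code{pct_expressing}.
#' @export
enzymeProfile <- function(sce, clusters = sce$cluster,
                          enzymes = metabolicEnzymes()) {
    clusters <- droplevels(as.factor(clusters))
    x <- SummarizedExperiment::assay(sce, "logcounts")
    cnt <- SummarizedExperiment::assay(sce, "counts")
    absent <- setdiff(enzymes, rownames(x))
    if (length(absent))
        warning("enzymes absent from matrix (profiled as 0): ",
                paste(absent, collapse = ", "))
    out <- expand.grid(cluster = levels(clusters), enzyme = enzymes,
                       stringsAsFactors = FALSE)
    out$mean_expr <- 0
    out$pct_expressing <- 0
    for (cl in levels(clusters)) {
        sel <- clusters == cl
        for (en in setdiff(enzymes, absent)) {
            i <- out$cluster == cl & out$enzyme == en
            out$mean_expr[i] <- mean(x[en, sel])
            out$pct_expressing[i] <- 100 * mean(cnt[en, sel] > 0)
        }
    }
    out
}
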