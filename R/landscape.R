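#' Importance of a gene across groups
#'
#' Importance is the population variance of the per-group mean normalized
#' expression, divided by the global mean expression plus a fixed
#' stabilizer (epsilon = 0.01). High values flag genes whose expression level
#' shifts strongly across clusters or trajectory stages; a gene with equal
#' group means has importance exactly 0.
#'
#' @param expr numeric per-cell normalized expression of the gene.
#' @param groups per-cell grouping factor (>= 2 groups).
#' @return non-negative scalar importance.
#' @examples
#' computeImportance(c(0, 0, 2, 2), factor(c("a", "a", "b", "b")))
#' @export
computeImportance <- function(expr, groups) {
    groups <- droplevels(as.factor(groups))
    if (nlevels(groups) < 2) stop("need at least 2 groups")
    gm <- tapply(expr, groups, mean)
    v <- mean((gm - mean(gm))^2)          # population variance of group means
    v / (mean(expr) + 0.01)
}

#' Conservation of a gene across clusters
#'
#' Conservation is the fraction of clusters in which the gene is detected
#' (raw count > 0) in at least \code{detectFrac} of the cluster's cells. A
#' gene robustly detected everywhere scores 1; a gene absent everywhere
#' scores 0.
#'
#' @param detected logical per-cell detection vector (count > 0).
#' @param clusters per-cell cluster factor (>= 2 clusters).
#' @param detectFrac within-cluster detection-rate threshold (default 0.5).
#' @return scalar in [0, 1].
#' @export
computeConservation <- function(detected, clusters, detectFrac = 0.5) {
    clusters <- droplevels(as.factor(clusters))
    if (nlevels(clusters) < 2) stop("need at least 2 clusters")
    rates <- tapply(detected, clusters, mean)
    mean(rates >= detectFrac)
}

#' Importance-versus-conservation functional landscape
#'
#' One row per evaluated gene, ranking injury-variable drivers (high
#' importance) against constitutively expressed conserved genes (high
#' conservation). Importance is measured across cell states: by default the
#' metabolic-state grouping when present (the level at which conservation
#' and variability are contrasted), falling back to clusters; pass
#' pseudotime-stage bins as \code{groups} for the trajectory-binned variant.
#' Conservation is always measured across clusters.
#'
#' @param sce SCE with \code{counts} and \code{logcounts}.
#' @param clusters per-cell cluster factor (conservation grouping, and the
#'   importance fallback).
#' @param genes genes to evaluate (default: all genes in the matrix).
#' @param groups importance grouping override (e.g. [stageQuantiles()]
#'   bins); default \code{sce$metabolic_state} when available, else
#'   \code{clusters}.
#' @param detectFrac conservation detection threshold (default 0.5).
#' @return data.frame with \code{gene}, \code{importance},
#'   \code{conservation}, sorted by importance descending.
#' @export
buildLandscape <- function(sce, clusters = sce$cluster,
                           genes = rownames(sce), groups = NULL,
                           detectFrac = 0.5) {
    if (!length(genes)) stop("empty gene subset")
    if (is.null(groups) && methods::is(sce, "SummarizedExperiment") &&
        "metabolic_state" %in%
            colnames(SummarizedExperiment::colData(sce)))
        groups <- sce$metabolic_state
    genes <- intersect(genes, rownames(sce))
    x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts")[genes, ,
                                                                 drop = FALSE])
    det <- as.matrix(SummarizedExperiment::assay(sce, "counts")[genes, ,
                                                                drop = FALSE]) > 0
    clusters <- droplevels(as.factor(clusters))
    impGroups <- if (is.null(groups)) clusters else droplevels(
        as.factor(groups))
    # vectorized group means
    gmeans <- vapply(levels(impGroups), function(g)
        rowMeans(x[, impGroups == g, drop = FALSE]), numeric(nrow(x)))
    imp <- apply(gmeans, 1, function(m) mean((m - mean(m))^2)) /
        (rowMeans(x) + 0.01)
    rates <- vapply(levels(clusters), function(cl)
        rowMeans(det[, clusters == cl, drop = FALSE]), numeric(nrow(det)))
    cons <- rowMeans(rates >= detectFrac)
    out <- data.frame(gene = genes, importance = unname(imp),
                      conservation = unname(cons), row.names = NULL)
    out[order(-out$importance, out$gene), ]
}
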