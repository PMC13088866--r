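#' Mean marker scores per cluster and candidate type
#'
#' score(cluster, type) = mean over the type's marker genes of the mean
#' normalized expression in the cluster. Markers absent from the matrix
#' contribute 0 and are reported once via a message.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param clusters factor of per-cell cluster labels (default
#'   \code{sce$cluster}).
#' @param catalog named list of marker gene vectors (default
#'   [defaultMarkerCatalog()]).
#' @return numeric matrix, clusters in rows, types in columns.
#' @export
scoreClusterMarkers <- function(sce, clusters = sce$cluster,
                                catalog = defaultMarkerCatalog()) {
    x <- SummarizedExperiment::assay(sce, "logcounts")
    clusters <- droplevels(as.factor(clusters))
    if (any(table(clusters) == 0)) stop("empty cluster level")
    missing <- setdiff(unlist(catalog), rownames(x))
    if (length(missing))
        message("markers absent from matrix (scored as 0): ",
                paste(missing, collapse = ", "))
    cl_means <- vapply(levels(clusters), function(cl)
        Matrix::rowMeans(x[, clusters == cl, drop = FALSE]),
        numeric(nrow(x)))
    out <- matrix(0, nlevels(clusters), length(catalog),
                  dimnames = list(levels(clusters), names(catalog)))
    for (ty in names(catalog)) {
        present <- intersect(catalog[[ty]], rownames(x))
        vals <- if (length(present))
            colSums(cl_means[present, , drop = FALSE]) else 0
        out[, ty] <- vals / length(catalog[[ty]])   # absent markers count as 0
    }
    out
}

#' Assign a cell type to each cluster by marker-score argmax
#'
#' The winning type must beat the runner-up by at least \code{minMargin};
#' otherwise the cluster is "Unassigned". Exact ties go to the
#' lexicographically first type name.
#'
#' @param scoreMatrix cluster-by-type matrix from [scoreClusterMarkers()].
#' @param minMargin minimum top-minus-second score gap (default 0.05).
#' @return named character vector, one type per cluster.
#' @export
assignTypes <- function(scoreMatrix, minMargin = 0.05) {
    stopifnot(all(is.finite(scoreMatrix)))
    sm <- scoreMatrix[, order(colnames(scoreMatrix)), drop = FALSE]
    apply(sm, 1, function(s) {
        top <- which.max(s)                       # first max: lexicographic
        second <- if (length(s) > 1) max(s[-top]) else -Inf
        if (s[top] - second < minMargin) "Unassigned" else colnames(sm)[top]
    })
}

#' Annotate cells through their clusters
#'
#' Convenience wrapper: scores markers, assigns cluster-level types, and
#' broadcasts them to cells as \code{colData(sce)$cell_type}.
#'
#' @inheritParams scoreClusterMarkers
#' @inheritParams assignTypes
#' @return SCE with \code{cell_type} added; the cluster-level table is in
#'   \code{metadata(sce)$annotation}.
#' @export
annotateCells <- function(sce, clusters = sce$cluster,
                          catalog = defaultMarkerCatalog(),
                          minMargin = 0.05) {
    scores <- scoreClusterMarkers(sce, clusters, catalog)
    types <- assignTypes(scores, minMargin)
    sce$cell_type <- unname(types[as.character(clusters)])
    S4Vectors::metadata(sce)$annotation <- data.frame(
        cluster = rownames(scores), marker_type = types,
        row.names = NULL)
    sce
}

#' Reference-based cluster annotation by centroid correlation
#'
#' Each cluster centroid (mean \code{logcounts}) is compared with every
#' reference centroid by Spearman correlation over the shared genes; the
#' best-correlated reference type is returned. A constant query centroid
#' yields "Unassigned" with NA correlation.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param clusters per-cell cluster factor.
#' @param referenceCentroids gene-by-type numeric matrix of reference mean
#'   expression profiles.
#' @return data.frame with \code{cluster}, \code{reference_type},
#'   \code{correlation}.
#' @export
referencePredict <- function(sce, clusters = sce$cluster,
                             referenceCentroids) {
    x <- SummarizedExperiment::assay(sce, "logcounts")
    shared <- intersect(rownames(x), rownames(referenceCentroids))
    if (length(shared) < 10)
        stop("fewer than 10 genes shared with the reference")
    clusters <- droplevels(as.factor(clusters))
    ref <- referenceCentroids[shared, , drop = FALSE]
    res <- lapply(levels(clusters), function(cl) {
        cen <- Matrix::rowMeans(x[shared, clusters == cl, drop = FALSE])
        if (stats::sd(cen) == 0)
            return(data.frame(cluster = cl, reference_type = "Unassigned",
                              correlation = NA_real_))
        cors <- apply(ref, 2, function(r)
            suppressWarnings(stats::cor(cen, r, method = "spearman")))
        cors[is.na(cors)] <- -Inf
        best <- which.max(cors)
        data.frame(cluster = cl, reference_type = colnames(ref)[best],
                   correlation = cors[best])
    })
    do.call(rbind, res)
}

#' Ground-truth centroid matrix from a simulated experiment
#'
#' Builds a gene-by-type matrix of mean \code{logcounts} per true cell type,
#' usable as a self-consistent reference for [referencePredict()].
#'
#' @param sce simulated SCE with \code{logcounts} and \code{true_type}.
#' @return gene-by-type numeric matrix.
#' @export
truthCentroids <- function(sce) {
    x <- SummarizedExperiment::assay(sce, "logcounts")
    types <- sort(unique(sce$true_type))
    vapply(types, function(ty)
        Matrix::rowMeans(x[, sce$true_type == ty, drop = FALSE]),
        numeric(nrow(x)))
}

#' @noRd
#' Vectorized two-sided Wilcoxon rank-sum (normal approximation with tie and
#' continuity corrections, matching stats::wilcox.test(exact = FALSE)).
#' `ranks`: gene-by-cell matrix of within-gene ranks; `tieterm`: per-gene
#' sum(t^3 - t) over tie groups; `inGroup`: logical cell mask.
.rankSumP <- function(ranks, tieterm, inGroup) {
    n <- ncol(ranks)
    n1 <- sum(inGroup)
    n2 <- n - n1
    U <- rowSums(ranks[, inGroup, drop = FALSE]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tieterm / (n * (n - 1)))
    corr <- sign(U - mu) * 0.5
    z <- (U - mu - corr) / sqrt(sigma2)
    p <- 2 * pmin(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
    p <- pmin(p, 1)
    p[sigma2 <= 0] <- 1
    p
}

#' One-vs-rest differential expression per cluster
#'
#' For every cluster with at least \code{minCells} cells, tests each gene with
#' a two-sided Wilcoxon rank-sum (cluster vs all other cells) on normalized
#' expression, adjusts p-values within cluster by Benjamini-Hochberg, and
#' reports natural-log fold changes of cluster mean vs rest mean plus the
#' percentage of expressing cells inside and outside. Rows are ordered by
#' ascending p then descending absolute fold change within each cluster.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param clusters per-cell cluster factor (>= 2 clusters required).
#' @param minCells minimum cluster size to test (default 3); smaller clusters
#'   are skipped with a warning.
#' @param pseudo pseudo-mean added inside the log-ratio (default 1e-4).
#' @return data.frame with columns \code{gene}, \code{cluster},
#'   \code{log_fold_change}, \code{p_value}, \code{fdr}, \code{pct_in},
#'   \code{pct_out}.
#' @export
rankGenes <- function(sce, clusters = sce$cluster, minCells = 3,
                      pseudo = 1e-4) {
    x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
    clusters <- droplevels(as.factor(clusters))
    if (nlevels(clusters) < 2) stop("need at least 2 clusters")
    sizes <- table(clusters)
    small <- names(sizes)[sizes < minCells]
    if (length(small))
        warning("skipping cluster(s) with fewer than ", minCells, " cells: ",
                paste(small, collapse = ", "))
    ranks <- t(apply(x, 1, rank))
    tieterm <- apply(x, 1, function(row) {
        tt <- table(row)
        sum(tt^3 - tt)
    })
    detected <- x > 0
    out <- lapply(setdiff(levels(clusters), small), function(cl) {
        inG <- clusters == cl
        p <- .rankSumP(ranks, tieterm, inG)
        m_in <- rowMeans(x[, inG, drop = FALSE])
        m_out <- rowMeans(x[, !inG, drop = FALSE])
        df <- data.frame(
            gene = rownames(x), cluster = cl,
            log_fold_change = log(m_in + pseudo) - log(m_out + pseudo),
            p_value = p,
            fdr = stats::p.adjust(p, method = "BH"),
            pct_in = 100 * rowMeans(detected[, inG, drop = FALSE]),
            pct_out = 100 * rowMeans(detected[, !inG, drop = FALSE]),
            row.names = NULL)
        df[order(df$p_value, -abs(df$log_fold_change)), ]
    })
    do.call(rbind, out)
}
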