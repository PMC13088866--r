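#' Compute per-cell quality-control metrics
#'
#' Adds the standard QC metrics to \code{colData}: \code{n_feature} (genes
#' with count > 0), \code{n_count} (total counts), \code{percent_mt}
#' (percentage of counts on "MT-"-prefixed genes) and \code{percent_ribo}
#' ("RPS"/"RPL"-prefixed genes). Cells with zero total counts get
#' \code{percent_mt = percent_ribo = 0} and are flagged in \code{qc_empty}.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay.
#' @param mitoGenes,riboGenes optional explicit gene symbol vectors; defaults
#'   are the symbol-prefix conventions above.
#' @return \code{sce} with QC columns appended to \code{colData}.
#' @examples
#' sce <- simulateKidney(SimParams(nCells = 100, nBackgroundGenes = 50))
#' sce <- computeQCMetrics(sce)
#' summary(sce$percent_mt)
#' @export
computeQCMetrics <- function(sce,
                             mitoGenes = grep("^MT-", rownames(sce),
                                              value = TRUE),
                             riboGenes = grep("^RP[SL]", rownames(sce),
                                              value = TRUE)) {
    counts <- methods::as(SummarizedExperiment::assay(sce, "counts"),
                          "CsparseMatrix")
    if (any(counts@x < 0)) stop("counts must be non-negative")
    bad <- setdiff(c(mitoGenes, riboGenes), rownames(sce))
    if (length(bad))
        stop("mito/ribo genes absent from the count matrix: ",
             paste(bad, collapse = ", "))
    n_count <- Matrix::colSums(counts)
    n_feature <- Matrix::colSums(counts > 0)
    mt <- if (length(mitoGenes))
        Matrix::colSums(counts[mitoGenes, , drop = FALSE]) else 0
    rb <- if (length(riboGenes))
        Matrix::colSums(counts[riboGenes, , drop = FALSE]) else 0
    tot <- ifelse(n_count > 0, n_count, 1)  # empty cells: 0 by convention
    sce$n_feature <- unname(as.integer(n_feature))
    sce$n_count <- unname(n_count)
    sce$percent_mt <- unname(100 * mt / tot)
    sce$percent_ribo <- unname(100 * rb / tot)
    sce$qc_empty <- unname(n_count == 0)
    sce
}

#' Cell filter mask and per-criterion removal report
#'
#' A cell is kept iff \code{min_features <= n_feature <= max_features},
#' \code{percent_mt <= max_percent_mt} and \code{n_count >= min_counts}.
#' Removals are attributed to the first failing criterion in that order. The
#' defaults are conventional kidney scRNA-seq values; the underlying study
#' thresholds being unstated, they are deliberately explicit and overridable.
#'
#' @param metrics data.frame (or \code{colData}) with columns
#'   \code{n_feature}, \code{n_count}, \code{percent_mt}.
#' @param minFeatures,maxFeatures detected-gene bounds (default 200, 8000).
#' @param maxPercentMT mitochondrial percentage ceiling (default 50).
#' @param minCounts total-count floor (default 500).
#' @return list with \code{keep} (logical mask) and \code{report}
#'   (data.frame criterion/removed, plus a kept row).
#' @export
qcFilterMask <- function(metrics, minFeatures = 200, maxFeatures = 8000,
                         maxPercentMT = 50, minCounts = 500) {
    if (minFeatures >= maxFeatures)
        stop("minFeatures must be smaller than maxFeatures")
    metrics <- as.data.frame(metrics)
    low_f <- metrics$n_feature < minFeatures
    high_f <- !low_f & metrics$n_feature > maxFeatures
    high_mt <- !low_f & !high_f & metrics$percent_mt > maxPercentMT
    low_c <- !low_f & !high_f & !high_mt & metrics$n_count < minCounts
    keep <- !(low_f | high_f | high_mt | low_c)
    if (!any(keep)) warning("filter removes every cell")
    report <- data.frame(
        criterion = c("low_features", "high_features", "high_percent_mt",
                      "low_counts", "kept"),
        cells = c(sum(low_f), sum(high_f), sum(high_mt), sum(low_c),
                  sum(keep)))
    list(keep = keep, report = report)
}

#' Filter cells by QC thresholds
#'
#' Applies [qcFilterMask()] and subsets the experiment; the removal report is
#' stored in \code{metadata(sce)$filter_report}. Filtering is idempotent.
#'
#' @inheritParams qcFilterMask
#' @param sce a \code{SingleCellExperiment} processed by
#'   [computeQCMetrics()].
#' @return The filtered \code{SingleCellExperiment}.
#' @export
filterCells <- function(sce, minFeatures = 200, maxFeatures = 8000,
                        maxPercentMT = 50, minCounts = 500) {
    if (!"n_feature" %in% colnames(SummarizedExperiment::colData(sce)))
        stop("run computeQCMetrics() first")
    fm <- qcFilterMask(SummarizedExperiment::colData(sce),
                       minFeatures = minFeatures, maxFeatures = maxFeatures,
                       maxPercentMT = maxPercentMT, minCounts = minCounts)
    out <- sce[, fm$keep]
    S4Vectors::metadata(out)$filter_report <- fm$report
    out
}

#' Depth-normalize and log-transform counts
#'
#' Scales every cell to a common total of \code{scaleFactor} counts and
#' applies the natural-log \code{log(1 + x)} transform, storing the result as
#' the \code{logcounts} assay.
#'
#' @param sce a filtered \code{SingleCellExperiment} (no all-zero cells).
#' @param scaleFactor common post-scaling total (default 10,000).
#' @return \code{sce} with a sparse \code{logcounts} assay added.
#' @examples
#' sce <- simulateKidney(SimParams(nCells = 50, nBackgroundGenes = 20))
#' sce <- normalizeLog(sce)
#' @export
normalizeLog <- function(sce, scaleFactor = 1e4) {
    counts <- methods::as(SummarizedExperiment::assay(sce, "counts"),
                          "CsparseMatrix")
    tot <- Matrix::colSums(counts)
    if (any(tot == 0))
        stop("all-zero cells present; filter cells before normalizing")
    norm <- counts %*% Matrix::Diagonal(x = scaleFactor / tot)
    norm@x <- log1p(norm@x)
    dimnames(norm) <- dimnames(counts)
    SummarizedExperiment::assay(sce, "logcounts") <- norm
    sce
}
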