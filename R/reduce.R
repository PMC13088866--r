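#' Select highly variable genes by standardized variance
#'
#' Variance-stabilizing selection: per-gene mean and variance of raw counts
#' are computed, a loess trend is fitted to log10(variance) against
#' log10(mean), counts are standardized against the trend-expected standard
#' deviation (clipped at sqrt(n cells)), and genes are ranked by the variance
#' of the clipped standardized values. Ties are broken lexicographically by
#' gene symbol.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay and at
#'   least two cells.
#' @param nTop number of genes to select (default 2000); capped at the number
#'   of genes.
#' @param loessSpan span of the mean-variance trend fit (default 0.3).
#' @return data.frame with one row per gene: \code{gene}, \code{mean},
#'   \code{variance}, \code{std_variance}, \code{rank}, \code{selected}.
#' @examples
#' sce <- simulateKidney(SimParams(nCells = 120, nBackgroundGenes = 60))
#' hv <- selectHVGs(sce, nTop = 50)
#' head(hv[hv$selected, "gene"])
#' @export
selectHVGs <- function(sce, nTop = 2000, loessSpan = 0.3) {
    counts <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
    n <- ncol(counts)
    if (n < 2) stop("need at least 2 cells")
    mu <- rowMeans(counts)
    v <- rowSums((counts - mu)^2) / (n - 1)
    if (all(v == 0)) stop("constant matrix: no gene has variance")

    std_var <- numeric(nrow(counts))
    fitted_ok <- v > 0 & mu > 0
    fit <- stats::loess(log10(v[fitted_ok]) ~ log10(mu[fitted_ok]),
                        span = loessSpan, degree = 2)
    exp_sd <- sqrt(10^stats::predict(fit, log10(mu[fitted_ok])))
    clip <- sqrt(n)
    z <- (counts[fitted_ok, , drop = FALSE] - mu[fitted_ok]) / exp_sd
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    std_var[fitted_ok] <- rowSums((z - rowMeans(z))^2) / (n - 1)

    ord <- order(-std_var, rownames(counts))
    rk <- integer(length(ord)); rk[ord] <- seq_along(ord)
    nSel <- min(nTop, nrow(counts))
    data.frame(gene = rownames(counts), mean = mu, variance = v,
               std_variance = std_var, rank = rk,
               selected = rk <= nSel, row.names = rownames(counts))
}

#' @noRd
hvgGenes <- function(hvgs) hvgs$gene[hvgs$selected][order(
    hvgs$rank[hvgs$selected])]

#' Principal component analysis on the variable-gene submatrix
#'
#' Genes are centered and scaled to unit variance before decomposition (zero
#' variance genes are dropped with a message); components are returned in
#' decreasing explained-variance order. For large matrices a truncated SVD
#' (irlba) computes the leading components; explained-variance proportions
#' use the analytic total variance of the scaled data.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{logcounts} assay.
#' @param hvgs output of [selectHVGs()] (or a character vector of genes).
#' @param kMax number of components to compute (default 50).
#' @param name reducedDim slot to fill (default \code{"PCA"}).
#' @return \code{sce} with \code{reducedDim(sce, name)} set and a list in
#'   \code{metadata(sce)} (named after the slot, lower-case) holding
#'   \code{variance} (component variances), \code{total_variance} and
#'   \code{prop_variance}.
#' @export
runPCA <- function(sce, hvgs, kMax = 50, name = "PCA") {
    genes <- if (is.character(hvgs)) hvgs else hvgGenes(hvgs)
    genes <- intersect(genes, rownames(sce))
    x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts")[genes, ,
                                                                 drop = FALSE])
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) {
        message("dropping ", sum(sds == 0), " zero-variance gene(s) from PCA")
        x <- x[sds > 0, , drop = FALSE]
    }
    if (kMax > min(dim(x)))
        stop("kMax exceeds the rank bound min(genes, cells) = ", min(dim(x)))
    xs <- t(scale(t(x)))                       # genes standardized
    n <- ncol(xs)
    total_var <- nrow(xs)                      # unit-variance genes
    if (min(dim(xs)) > 3 * kMax + 10) {
        set.seed(1L)                           # irlba init; fixed internally
        sv <- irlba::irlba(t(xs), nv = kMax)
        scores <- sv$u %*% diag(sv$d)
        compvar <- sv$d^2 / (n - 1)
    } else {
        pr <- stats::prcomp(t(xs), center = FALSE, scale. = FALSE)
        k <- min(kMax, ncol(pr$x))
        scores <- pr$x[, seq_len(k), drop = FALSE]
        compvar <- pr$sdev[seq_len(k)]^2
    }
    rownames(scores) <- colnames(sce)
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
    SingleCellExperiment::reducedDim(sce, name) <- scores
    S4Vectors::metadata(sce)[[tolower(name)]] <- list(
        variance = compvar, total_variance = total_var,
        prop_variance = compvar / total_var,
        n_genes = nrow(xs), n_cells = n)
    sce
}

#' Automatic dimensionality from the random-matrix noise edge
#'
#' Applies [chooseKElbow()] with the marginal-variance cut placed at the
#' Marchenko-Pastur upper edge \eqn{(1 + \sqrt{p/n})^2} of the scaled data —
#' the variance a pure-noise component would reach — so the selected
#' components are exactly those rising above the noise bulk, independent of
#' how many genes went into the decomposition.
#'
#' @param pca the list stored by [runPCA()] in
#'   \code{metadata(sce)$pca}.
#' @param kMin,kMax clamp bounds (defaults 5 and 50).
#' @return integer \code{k_selected}.
#' @export
chooseKAuto <- function(pca, kMin = 5, kMax = 50) {
    cut <- (1 + sqrt(pca$n_genes / pca$n_cells))^2
    chooseKElbow(pca$variance, dropThreshold = cut / pca$total_variance,
                 kMin = kMin, kMax = kMax,
                 totalVariance = pca$total_variance)
}

#' Elbow rule for the number of principal components
#'
#' Explicit operationalization of the elbow plot: the selected dimensionality
#' is the smallest \code{k} such that the variance of component \code{k + 1}
#' falls below \code{dropThreshold} times the total variance, clamped to
#' \code{[kMin, kMax]}. Scale-invariant and deterministic.
#'
#' @param explainedVariance non-increasing vector of component variances.
#' @param dropThreshold marginal-variance threshold as a fraction of total
#'   variance (default 0.002, placing the cut just above the random-matrix
#'   noise bulk at typical gene counts).
#' @param kMin,kMax clamp bounds (defaults 5 and 50).
#' @param totalVariance total variance to normalize against; defaults to
#'   \code{sum(explainedVariance)} (pass the analytic total when only leading
#'   components are available).
#' @return integer \code{k_selected}.
#' @examples
#' chooseKElbow(c(10, 5, 2, 0.01, 0.01, 0.01), kMin = 2)
#' @export
chooseKElbow <- function(explainedVariance, dropThreshold = 0.002,
                         kMin = 5, kMax = 50,
                         totalVariance = sum(explainedVariance)) {
    stopifnot(length(explainedVariance) >= 2)
    cut <- dropThreshold * totalVariance
    below <- which(explainedVariance < cut)
    k <- if (length(below)) below[1] - 1L else length(explainedVariance)
    as.integer(min(max(k, kMin), min(kMax, length(explainedVariance))))
}

#' @noRd
#' kNN graph with shared-nearest-neighbor Jaccard weights (or raw distances).
.knnGraph <- function(pc, nNeighbors, weighting = c("snn", "distance")) {
    weighting <- match.arg(weighting)
    n <- nrow(pc)
    if (n <= nNeighbors) stop("fewer cells than nNeighbors + 1")
    d <- as.matrix(stats::dist(pc))
    nn <- t(apply(d, 1, function(row) order(row)[2:(nNeighbors + 1)]))
    from <- rep(seq_len(n), each = nNeighbors)
    to <- as.vector(t(nn))
    if (weighting == "snn") {
        adj <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
        adj <- pmax(adj, Matrix::t(adj))            # symmetric kNN membership
        shared <- Matrix::tcrossprod(adj)
        edges <- unique(cbind(pmin(from, to), pmax(from, to)))
        sh <- shared[edges]
        w <- sh / (2 * nNeighbors - sh)              # Jaccard on neighborhoods
        g <- igraph::graph_from_edgelist(edges, directed = FALSE)
        igraph::E(g)$weight <- w
    } else {
        edges <- cbind(pmin(from, to), pmax(from, to))
        keep <- !duplicated(edges)
        edges <- edges[keep, , drop = FALSE]
        w <- d[edges]
        g <- igraph::graph_from_edgelist(edges, directed = FALSE)
        igraph::E(g)$weight <- w
    }
    if (igraph::vcount(g) < n)
        g <- igraph::add_vertices(g, n - igraph::vcount(g))
    g
}

#' Graph-based clustering of cells in PC space
#'
#' Builds a k-nearest-neighbor graph (Euclidean in the leading \code{k}
#' principal components) with shared-nearest-neighbor Jaccard edge weights
#' and applies Leiden modularity optimization at the given resolution.
#' Cluster labels are contiguous integers from 0, relabeled by decreasing
#' cluster size.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{"PCA"} reducedDim,
#'   or a numeric cell-by-PC matrix.
#' @param k number of principal components to use (default: all available).
#' @param nNeighbors neighbors in the kNN graph (default 30; large
#'   neighborhoods keep continuous populations coherent at this resolution).
#' @param resolution Leiden resolution (default 0.8, the primary analysis
#'   setting).
#' @param seed RNG seed for the community search.
#' @return If given an SCE, the SCE with a \code{cluster} factor in
#'   \code{colData}; otherwise the factor itself.
#' @export
clusterCells <- function(sce, k = NULL, nNeighbors = 30, resolution = 0.8,
                         seed = 1) {
    pc <- if (methods::is(sce, "SingleCellExperiment"))
        SingleCellExperiment::reducedDim(sce, "PCA") else as.matrix(sce)
    if (!is.null(k)) pc <- pc[, seq_len(k), drop = FALSE]
    g <- .knnGraph(pc, nNeighbors, "snn")
    set.seed(seed)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 10)
    memb <- igraph::membership(cl)
    sizes <- sort(table(memb), decreasing = TRUE)
    relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
    lab <- factor(relab[as.character(memb)],
                  levels = seq_along(sizes) - 1L)
    if (methods::is(sce, "SingleCellExperiment")) {
        sce$cluster <- lab
        sce
    } else lab
}

#' Two-dimensional UMAP embedding
#'
#' @param sce a \code{SingleCellExperiment} with a \code{"PCA"} reducedDim,
#'   or a cell-by-PC matrix.
#' @param k number of components to embed (default: all).
#' @param nNeighbors UMAP neighborhood size (default 15).
#' @param seed RNG seed; identical seeds give identical coordinates.
#' @return SCE with \code{reducedDim(sce, "UMAP")} set, or the coordinate
#'   matrix.
#' @export
embedUMAP <- function(sce, k = NULL, nNeighbors = 15, seed = 1) {
    pc <- if (methods::is(sce, "SingleCellExperiment"))
        SingleCellExperiment::reducedDim(sce, "PCA") else as.matrix(sce)
    if (!is.null(k)) pc <- pc[, seq_len(k), drop = FALSE]
    set.seed(seed)
    coords <- uwot::umap(pc, n_neighbors = min(nNeighbors, nrow(pc) - 1),
                         n_threads = 1, n_sgd_threads = 0, batch = TRUE)
    colnames(coords) <- c("UMAP1", "UMAP2")
    rownames(coords) <- rownames(pc)
    if (methods::is(sce, "SingleCellExperiment")) {
        SingleCellExperiment::reducedDim(sce, "UMAP") <- coords
        sce
    } else coords
}
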