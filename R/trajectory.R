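#' Choose the trajectory root cluster
#'
#' The root is the PT-annotated cluster with the highest fraction of
#' OXPHOS-high cells (the healthy, oxidative starting point of the injury
#' trajectory); ties go to the larger cluster, then the lower label.
#'
#' @param clusters per-cell cluster factor.
#' @param cellTypes per-cell annotated type (PT clusters are those whose
#'   cells carry type "PT").
#' @param states per-cell metabolic state factor from [classifyState()].
#' @param minCells smallest cluster eligible as root (default 20); splinter
#'   clusters of a handful of cells would otherwise win the OXPHOS-fraction
#'   argmax by chance. Ignored if no PT cluster reaches the bound.
#' @return the root cluster label (character).
#' @export
chooseRoot <- function(clusters, cellTypes, states, minCells = 20) {
    clusters <- droplevels(as.factor(clusters))
    cl_type <- tapply(as.character(cellTypes), clusters,
                      function(v) names(sort(table(v), decreasing = TRUE))[1])
    pt_cl <- names(cl_type)[cl_type == "PT"]
    if (!length(pt_cl)) stop("no PT-annotated cluster")
    big <- pt_cl[table(clusters)[pt_cl] >= minCells]
    if (length(big)) pt_cl <- big
    frac <- vapply(pt_cl, function(cl)
        mean(states[clusters == cl] == "OXPHOS_high"), 0)
    size <- as.vector(table(clusters)[pt_cl])
    ord <- order(-frac, -size, suppressWarnings(as.numeric(pt_cl)), pt_cl)
    pt_cl[ord[1]]
}

#' Graph-distance pseudotime from a root cluster
#'
#' Pseudotime is the mean shortest-path distance from a small ensemble of
#' root cells over the k-nearest-neighbor graph (Euclidean edge lengths in
#' PC space) of the trajectory compartment, rescaled to [0, 1]. Root cells
#' are the \code{nRoots} compartment cells nearest the root anchor (the root
#' cluster's centroid, or its OXPHOS-high centroid when states are given);
#' averaging over an ensemble removes the idiosyncrasy of any single root
#' cell. Components disconnected from the root's are warned about and
#' measured from their own entry point (their cell closest to the primary
#' root in PC space).
#'
#' @param sce SCE with a \code{"PCA"} reducedDim, or a cell-by-PC matrix.
#' @param clusters per-cell cluster factor.
#' @param rootCluster label of the root cluster ([chooseRoot()]).
#' @param compartment logical mask of cells on the trajectory (default: all
#'   cells; the pipeline restricts to PT-annotated cells).
#' @param k number of PCs to use (default all).
#' @param nNeighbors kNN graph neighborhood (default 30).
#' @param states optional per-cell metabolic states; when given,
#'   dormant/mitochondrial-high cells — displaced off the injury manifold by
#'   their mitochondrial program — are assigned the median pseudotime of their
#'   \code{nProject} nearest non-dormant compartment cells (projection onto
#'   the unstressed manifold).
#' @param anchorScore optional per-cell score of differentiated health
#'   (higher = closer to the trajectory origin), typically mean segment-
#'   marker expression; the root anchor is then the centroid of the root
#'   cluster's top-decile cells instead of the whole-cluster centroid, which
#'   matters when the tubular compartment forms a single cluster whose
#'   centroid sits mid-gradient. Deliberately independent of the metabolic
#'   pathway scores so that a flat dataset cannot acquire a spurious
#'   pseudotime-metabolism correlation.
#' @param smooth number of neighborhood-averaging (diffusion) rounds applied
#'   to the raw graph distances (default 1; 0 disables).
#' @param nProject neighbors used for the dormant-cell projection
#'   (default 10).
#' @param nRoots size of the root-cell ensemble (default 10).
#' @return numeric per-cell pseudotime in [0, 1]; NA outside the compartment.
#' @export
computePseudotime <- function(sce, clusters, rootCluster,
                              compartment = NULL, k = NULL,
                              nNeighbors = 30, states = NULL, smooth = 1,
                              nProject = 10, nRoots = 10,
                              anchorScore = NULL) {
    pc <- if (methods::is(sce, "SingleCellExperiment"))
        SingleCellExperiment::reducedDim(sce, "PCA") else as.matrix(sce)
    if (!is.null(k)) pc <- pc[, seq_len(k), drop = FALSE]
    n <- nrow(pc)
    if (is.null(compartment)) compartment <- rep(TRUE, n)
    idx <- which(compartment)
    if (length(idx) < 50) stop("trajectory compartment has fewer than 50 cells")
    sub <- pc[idx, , drop = FALSE]
    cl_sub <- as.character(clusters)[idx]
    root_cells <- cl_sub == as.character(rootCluster)
    if (!any(root_cells)) stop("root cluster absent from the compartment")
    anchor <- root_cells
    if (!is.null(anchorScore)) {
        sc <- anchorScore[idx]
        hi <- sc >= stats::quantile(sc[root_cells], 0.9)
        if (any(root_cells & hi)) anchor <- root_cells & hi
    }
    centroid <- colMeans(sub[anchor, , drop = FALSE])
    d2root <- colSums((t(sub) - centroid)^2)
    cand <- which(anchor)
    roots <- cand[order(d2root[cand])[seq_len(min(nRoots, length(cand)))]]
    root <- roots[1]

    g <- .knnGraph(sub, nNeighbors, "distance")
    comp <- igraph::components(g)$membership
    dist_all <- rep(NA_real_, length(idx))
    for (cm in unique(comp)) {
        members <- which(comp == cm)
        if (comp[root] == cm) {
            rts <- roots[comp[roots] == cm]
            dm <- igraph::distances(g, v = rts, to = members,
                                    weights = igraph::E(g)$weight)
            dist_all[members] <- colMeans(dm)
        } else {
            d2r <- colSums((t(sub[members, , drop = FALSE]) - sub[root, ])^2)
            entry <- members[which.min(d2r)]
            dist_all[members] <- as.numeric(
                igraph::distances(g, v = entry, to = members,
                                  weights = igraph::E(g)$weight))
        }
    }
    if (length(unique(comp)) > 1)
        warning(length(unique(comp)) - 1,
                " component(s) disconnected from the root; ",
                "measured from their own entry points")
    if (smooth > 0) {
        adj <- igraph::as_adj_list(g)
        for (r in seq_len(smooth))
            dist_all <- vapply(seq_along(dist_all), function(i)
                mean(c(dist_all[i], dist_all[adj[[i]]])), 0)
    }
    if (!is.null(states)) {
        dorm <- as.character(states)[idx] == "Dorm_Mt_high"
        if (any(dorm) && sum(!dorm) >= nProject) {
            nd <- which(!dorm)
            # neighbor search ignores the dormancy-displacement axes (PCs
            # whose dormant-vs-rest standardized mean difference is large),
            # so dormant cells match non-dormant cells of similar injury
            # stage rather than similar mitochondrial load
            smd <- abs(colMeans(sub[dorm, , drop = FALSE]) -
                       colMeans(sub[nd, , drop = FALSE])) /
                   apply(sub[nd, , drop = FALSE], 2, stats::sd)
            keep <- smd < 0.5
            if (!any(keep)) keep <- rep(TRUE, ncol(sub))
            ord_val <- vapply(which(dorm), function(i) {
                d2 <- colSums((t(sub[nd, keep, drop = FALSE]) -
                               sub[i, keep])^2)
                stats::median(dist_all[nd[order(d2)[seq_len(nProject)]]])
            }, 0)
            # the projected values order the dormant cells; their marginal
            # is quantile-mapped onto the non-dormant distribution so that
            # dormancy itself carries no systematic early/late placement
            dist_all[which(dorm)] <- stats::quantile(
                dist_all[nd],
                probs = rank(ord_val, ties.method = "average") /
                    (length(ord_val) + 1),
                names = FALSE)
        }
    }
    rng <- max(dist_all)
    pt_sub <- if (rng > 0) dist_all / rng else dist_all
    out <- rep(NA_real_, n)
    out[idx] <- pt_sub
    if (!is.null(rownames(pc))) names(out) <- rownames(pc)
    out
}

#' Trajectory feature space excluding the metabolic readout genes
#'
#' Recomputes principal components on the variable genes minus the
#' glycolysis and OXPHOS score sets and the mitochondrial ("MT-") genes,
#' storing them as \code{reducedDim(sce, "TRAJ")}. Inferring pseudotime in
#' this space keeps the downstream claim — that metabolic programs shift
#' along the injury trajectory — non-circular: the ordering is driven by
#' dedifferentiation and damage-response expression, never by the metabolic
#' scores themselves, so a dataset without an injury gradient cannot acquire
#' a spurious pseudotime-metabolism association.
#'
#' @param sce SCE with \code{logcounts}.
#' @param hvgs [selectHVGs()] output (or a character vector).
#' @param geneSets metabolic sets to exclude (default [defaultGeneSets()]).
#' @param kMax components to compute (default 50).
#' @return \code{sce} with a \code{"TRAJ"} reducedDim.
#' @export
runTrajectoryPCA <- function(sce, hvgs, geneSets = defaultGeneSets(),
                             kMax = 50) {
    genes <- if (is.character(hvgs)) hvgs else hvgGenes(hvgs)
    drop <- c(unlist(geneSets), grep("^MT-", rownames(sce), value = TRUE))
    genes <- setdiff(genes, drop)
    runPCA(sce, genes, kMax = kMax, name = "TRAJ")
}

#' Segment-marker anchor score
#'
#' Mean normalized expression of the PT segment markers per cell — a
#' differentiated-health score used to anchor the trajectory root at the
#' healthy end of the dedifferentiation axis.
#'
#' @param sce SCE with \code{logcounts}.
#' @param genes marker genes (default the PT segment panel).
#' @return numeric per-cell score.
#' @export
markerAnchorScore <- function(sce, genes = defaultMarkerCatalog()$PT) {
    present <- intersect(genes, rownames(sce))
    if (!length(present)) stop("no anchor marker genes present")
    Matrix::colMeans(
        SummarizedExperiment::assay(sce, "logcounts")[present, ,
                                                      drop = FALSE])
}

#' Stretch pseudotime within clusters
#'
#' Min-max rescales pseudotime to [0, 1] separately within each cluster, the
#' per-cluster "stretched pseudotime" view of temporal heterogeneity.
#' Singleton and constant-pseudotime clusters map to 0.5. Rank order within
#' each cluster is preserved exactly.
#'
#' @param pseudotime per-cell pseudotime (NA allowed).
#' @param clusters per-cell cluster factor.
#' @return per-cell stretched pseudotime (NA where pseudotime is NA).
#' @examples
#' stretchPseudotime(c(2, 4, 6), factor(c(1, 1, 1)))
#' @export
stretchPseudotime <- function(pseudotime, clusters) {
    out <- rep(NA_real_, length(pseudotime))
    for (cl in unique(as.character(clusters))) {
        sel <- which(as.character(clusters) == cl & !is.na(pseudotime))
        if (!length(sel)) next
        v <- pseudotime[sel]
        rng <- max(v) - min(v)
        out[sel] <- if (length(v) < 2 || rng == 0) 0.5 else
            (v - min(v)) / rng
    }
    out
}

#' Discretize pseudotime into trajectory-stage quantiles
#'
#' Optional staging of the trajectory into \code{n} equal-frequency quantile
#' bins (stages 1..n).
#'
#' @param pseudotime per-cell pseudotime.
#' @param n number of stages (default 5).
#' @return integer stage per cell (NA where pseudotime is NA).
#' @export
stageQuantiles <- function(pseudotime, n = 5) {
    ok <- !is.na(pseudotime)
    br <- stats::quantile(pseudotime[ok], probs = seq(0, 1, length.out = n + 1))
    br[1] <- -Inf; br[length(br)] <- Inf
    out <- rep(NA_integer_, length(pseudotime))
    out[ok] <- as.integer(cut(pseudotime[ok], breaks = unique(br)))
    out
}

#' Binned expression dynamics of a gene along pseudotime
#'
#' Equal-width bins over [0, 1]; per-bin mean and standard deviation of
#' normalized expression. Empty bins are reported with n = 0.
#'
#' @param sce SCE with \code{logcounts} (or a gene-by-cell matrix).
#' @param pseudotime per-cell pseudotime (NA cells are excluded).
#' @param gene gene symbol.
#' @param nBins number of bins (default 20).
#' @return data.frame with \code{bin}, \code{center}, \code{mean}, \code{sd},
#'   \code{n}.
#' @export
geneDynamics <- function(sce, pseudotime, gene, nBins = 20) {
    x <- if (methods::is(sce, "SummarizedExperiment"))
        SummarizedExperiment::assay(sce, "logcounts") else sce
    if (!gene %in% rownames(x)) stop("gene not present: ", gene)
    ok <- !is.na(pseudotime)
    if (sum(ok) < nBins) stop("fewer cells with pseudotime than bins")
    expr <- as.numeric(x[gene, ok])
    pt <- pseudotime[ok]
    br <- seq(0, 1, length.out = nBins + 1)
    bin <- pmin(pmax(findInterval(pt, br, rightmost.closed = TRUE), 1), nBins)
    out <- data.frame(bin = seq_len(nBins),
                      center = (br[-1] + br[-length(br)]) / 2,
                      mean = NA_real_, sd = NA_real_, n = 0L)
    for (b in seq_len(nBins)) {
        sel <- bin == b
        out$n[b] <- sum(sel)
        if (any(sel)) {
            out$mean[b] <- mean(expr[sel])
            out$sd[b] <- stats::sd(expr[sel])
        }
    }
    out
}
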