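#' Proportional composition table
#'
#' Counts and fractions of a categorical cell attribute, optionally within a
#' grouping column. Fractions sum to 1 within each group; rows are ordered by
#' descending count.
#'
#' @param cellTable data.frame of per-cell attributes.
#' @param by category column (e.g. \code{cell_type}, \code{metabolic_state}).
#' @param within optional grouping column (e.g. \code{cluster}); NULL for a
#'   global table.
#' @return data.frame with \code{group} (or "all"), \code{category},
#'   \code{count}, \code{fraction}.
#' @examples
#' composition(data.frame(t = c("PT", "PT", "Endo")), "t")
#' @export
composition <- function(cellTable, by, within = NULL) {
    if (!by %in% colnames(cellTable)) stop("unknown column: ", by)
    if (!is.null(within) && !within %in% colnames(cellTable))
        stop("unknown column: ", within)
    grp <- if (is.null(within)) rep("all", nrow(cellTable)) else
        as.character(cellTable[[within]])
    tab <- as.data.frame(table(group = grp,
                               category = as.character(cellTable[[by]])),
                         stringsAsFactors = FALSE)
    colnames(tab)[3] <- "count"
    tab <- tab[tab$count > 0 | TRUE, ]
    tot <- tapply(tab$count, tab$group, sum)
    tab$fraction <- tab$count / as.vector(tot[tab$group])
    tab[order(tab$group, -tab$count, tab$category), ]
}

#' Parse a flat key-value configuration file
#'
#' Reads the pipeline's configuration dialect: \code{[section]} headers,
#' \code{key = value} lines, \code{#} comments. Values may be quoted strings,
#' numbers, \code{true}/\code{false}, or comma-separated arrays in
#' \code{[ ]}.
#'
#' @param path configuration file path.
#' @return nested named list (section -> key -> value).
#' @export
readConfigFile <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    out <- list()
    section <- "global"
    parse_scalar <- function(v) {
        v <- trimws(v)
        if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
        if (v %in% c("true", "false")) return(v == "true")
        num <- suppressWarnings(as.numeric(v))
        if (!is.na(num)) return(num)
        v
    }
    for (ln in lines) {
        if (grepl("^\\[.*\\]$", ln)) {
            section <- gsub("^\\[|\\]$", "", ln)
            if (is.null(out[[section]])) out[[section]] <- list()
        } else if (grepl("=", ln, fixed = TRUE)) {
            key <- trimws(sub("=.*$", "", ln))
            val <- trimws(sub("^[^=]*=", "", ln))
            parsed <- if (grepl("^\\[.*\\]$", val)) {
                items <- strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]]
                items <- items[nzchar(trimws(items))]
                vals <- lapply(items, parse_scalar)
                if (all(vapply(vals, is.numeric, TRUE)))
                    unlist(vals) else vapply(vals, as.character, "")
            } else parse_scalar(val)
            out[[section]][[key]] <- parsed
        } else {
            stop("cannot parse config line: ", ln)
        }
    }
    out
}

#' Write a flat key-value configuration file
#'
#' Inverse of [readConfigFile()] for scalar and flat-array values.
#'
#' @param config nested named list (section -> key -> value).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeConfigFile <- function(config, path) {
    fmt <- function(v) {
        one <- function(x) {
            if (is.character(x)) sprintf('"%s"', x)
            else if (is.logical(x)) tolower(as.character(x))
            else format(x, digits = 15)
        }
        if (length(v) > 1) sprintf("[%s]",
                                   paste(vapply(v, one, ""), collapse = ", "))
        else one(v)
    }
    lines <- character()
    for (section in names(config)) {
        lines <- c(lines, sprintf("[%s]", section))
        for (key in names(config[[section]]))
            lines <- c(lines, sprintf("%s = %s", key,
                                      fmt(config[[section]][[key]])))
        lines <- c(lines, "")
    }
    writeLines(lines, path)
    invisible(path)
}

#' @noRd
.cfg <- function(config, section, key, default) {
    v <- config[[section]][[key]]
    if (is.null(v)) default else v
}

#' @noRd
.writeTSV <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

#' Run the full analysis pipeline
#'
#' Executes, in order: QC and filtering, normalization, HVG selection, PCA
#' with elbow-based dimensionality, Leiden clustering and UMAP, marker-based
#' annotation, one-vs-rest differential expression, metabolic scoring and
#' four-state classification, PT pseudotime with per-cluster stretching,
#' the importance/conservation landscape, ligand-receptor scoring, the
#' random-forest classifier, and composition reporting. Each stage writes its
#' tabular outputs under \code{outDir}; a JSON run summary records every
#' parameter, the seed and package version. Stage failures abort with a
#' stage-named error, preserving completed outputs.
#'
#' @param config nested list (as from [readConfigFile()]); recognised
#'   sections/keys are documented in the package vignette. When
#'   \code{config$input$dir} is absent the experiment is simulated from the
#'   \code{[simulate]} section.
#' @param outDir output directory (default \code{config$output$dir} or
#'   \code{"sctubule_out"}).
#' @param stages character vector selecting stages, a subset of
#'   \code{c("qc", "cluster", "annotate", "metabolic", "trajectory",
#'   "landscape", "cellcomm", "classify", "report")}; later stages require
#'   earlier ones in the same call.
#' @param sce optional pre-loaded \code{SingleCellExperiment} overriding the
#'   input section.
#' @return invisibly, a list with the final SCE and the paths written.
#' @export
runPipeline <- function(config = list(), outDir = NULL, stages = NULL,
                        sce = NULL) {
    all_stages <- c("qc", "cluster", "annotate", "metabolic", "trajectory",
                    "landscape", "cellcomm", "classify", "report")
    if (is.null(stages)) stages <- .cfg(config, "run", "stages", all_stages)
    stages <- match.arg(stages, all_stages, several.ok = TRUE)
    if (is.null(outDir))
        outDir <- .cfg(config, "output", "dir", "sctubule_out")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    seed <- as.integer(.cfg(config, "run", "seed", 1))
    paths <- character()
    emit <- function(df, name) {
        p <- file.path(outDir, name)
        .writeTSV(df, p)
        paths <<- c(paths, p)
    }
    stage <- function(name, expr) {
        if (!name %in% stages) return(invisible(NULL))
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    if (is.null(sce)) {
        indir <- .cfg(config, "input", "dir", NULL)
        sce <- if (!is.null(indir)) readExperiment(indir) else {
            params <- simParamsFromConfig(config)
            if (is.null(config$simulate$seed))
                params@seed <- seed
            simulateKidney(params)
        }
    }

    hv <- NULL; pt <- NULL
    stage("qc", {
        sce <- computeQCMetrics(sce)
        emit(cbind(barcode = colnames(sce),
                   as.data.frame(SummarizedExperiment::colData(sce)[,
                       c("n_feature", "n_count", "percent_mt",
                         "percent_ribo")])), "qc_metrics.tsv")
        sce <- filterCells(sce,
            minFeatures = .cfg(config, "qc", "min_features", 200),
            maxFeatures = .cfg(config, "qc", "max_features", 8000),
            maxPercentMT = .cfg(config, "qc", "max_percent_mt", 50),
            minCounts = .cfg(config, "qc", "min_counts", 500))
        emit(S4Vectors::metadata(sce)$filter_report, "filter_report.tsv")
        sce <- normalizeLog(sce,
            scaleFactor = .cfg(config, "qc", "scale_factor", 1e4))
    })
    stage("cluster", {
        hv <- selectHVGs(sce, nTop = .cfg(config, "cluster", "n_hvgs", 2000))
        kmax <- .cfg(config, "cluster", "k_max", 50)
        sce <- runPCA(sce, hv, kMax = min(kmax, min(dim(sce)) - 1))
        pv <- S4Vectors::metadata(sce)$pca
        drop_thr <- .cfg(config, "cluster", "drop_threshold", NULL)
        k <- if (is.null(drop_thr)) chooseKAuto(pv, kMax = kmax) else
            chooseKElbow(pv$variance, dropThreshold = drop_thr,
                         kMax = kmax, totalVariance = pv$total_variance)
        S4Vectors::metadata(sce)$k_selected <- k
        emit(data.frame(component = seq_along(pv$variance),
                        variance = pv$variance,
                        prop_variance = pv$prop_variance),
             "pca_variance.tsv")
        sce <- clusterCells(sce, k = k,
            nNeighbors = .cfg(config, "cluster", "n_neighbors", 30),
            resolution = .cfg(config, "cluster", "resolution", 0.8),
            seed = seed)
        sce <- embedUMAP(sce, k = k, seed = seed)
        emit(data.frame(barcode = colnames(sce), cluster = sce$cluster),
             "clusters.tsv")
        emit(cbind(data.frame(barcode = colnames(sce)),
                   as.data.frame(
                       SingleCellExperiment::reducedDim(sce, "UMAP"))),
             "embedding.tsv")
    })
    stage("annotate", {
        sce <- annotateCells(sce,
            minMargin = .cfg(config, "annotate", "min_margin", 0.05))
        ann <- S4Vectors::metadata(sce)$annotation
        ref <- .cfg(config, "annotate", "reference", NULL)
        if (!is.null(ref)) {
            centroids <- as.matrix(utils::read.delim(ref, row.names = 1))
            rp <- referencePredict(sce, sce$cluster, centroids)
            ann <- merge(ann, rp, by = "cluster")
        }
        emit(ann, "annotations.tsv")
        dge <- rankGenes(sce)
        for (cl in unique(dge$cluster))
            utils::write.csv(dge[dge$cluster == cl, ],
                             file.path(outDir, paste0("dge_", cl, ".csv")),
                             row.names = FALSE)
        paths <- c(paths, file.path(outDir, paste0("dge_",
                                                    unique(dge$cluster),
                                                    ".csv")))
    })
    stage("metabolic", {
        sce <- addMetabolicCalls(sce,
            qHigh = .cfg(config, "metabolic", "q_high", 0.60),
            mtHigh = .cfg(config, "metabolic", "mt_high", 25))
        emit(data.frame(barcode = colnames(sce),
                        glyc = sce$glyc_score, oxphos = sce$oxphos_score,
                        percent_mt = sce$percent_mt,
                        state = sce$metabolic_state),
             "metabolic_scores.tsv")
        emit(enzymeProfile(sce), "enzyme_profile.tsv")
    })
    stage("trajectory", {
        root <- chooseRoot(sce$cluster, sce$cell_type, sce$metabolic_state)
        compartment <- sce$cell_type == "PT"
        k <- S4Vectors::metadata(sce)$k_selected
        sce <- runTrajectoryPCA(sce, hv,
                                kMax = min(50, min(dim(sce)) - 1))
        kt <- min(k, ncol(SingleCellExperiment::reducedDim(sce, "TRAJ")))
        pt <- computePseudotime(
            SingleCellExperiment::reducedDim(sce, "TRAJ")[, seq_len(kt),
                                                          drop = FALSE],
            sce$cluster, root, compartment = compartment,
            states = sce$metabolic_state,
            anchorScore = markerAnchorScore(sce))
        stretched <- stretchPseudotime(pt, sce$cluster)
        sce$pseudotime <- pt
        sce$stretched_pseudotime <- stretched
        S4Vectors::metadata(sce)$root_cluster <- root
        emit(data.frame(barcode = colnames(sce), pseudotime = pt,
                        stretched = stretched, cluster = sce$cluster),
             "pseudotime.tsv")
        for (gene in .cfg(config, "trajectory", "dynamics_genes",
                          c("SLC34A1", "ANXA1")))
            if (gene %in% rownames(sce)) {
                dyn <- geneDynamics(sce, pt, gene,
                    nBins = .cfg(config, "trajectory", "n_bins", 20))
                utils::write.csv(dyn,
                    file.path(outDir, paste0("dynamics_", gene, ".csv")),
                    row.names = FALSE)
                paths <- c(paths,
                            file.path(outDir,
                                      paste0("dynamics_", gene, ".csv")))
            }
    })
    stage("landscape", {
        land <- buildLandscape(sce)
        p <- file.path(outDir, "landscape.csv")
        utils::write.csv(land, p, row.names = FALSE)
        paths <- c(paths, p)
    })
    stage("cellcomm", {
        pairs_path <- .cfg(config, "cellcomm", "pairs", NULL)
        pairs <- if (is.null(pairs_path)) defaultLRPairs() else
            readLRPairs(pairs_path)
        rec <- scoreInteractions(sce, sce$cell_type, pairs)
        p <- file.path(outDir, "interactions.csv")
        utils::write.csv(rec, p, row.names = FALSE)
        paths <- c(paths, p)
    })
    stage("classify", {
        labels <- .cfg(config, "classify", "label_column", "metabolic_state")
        feats <- makeFeatures(sce, hv,
                              SummarizedExperiment::colData(sce)[[labels]])
        rep <- crossValidate(feats$x, feats$y,
            nTrees = .cfg(config, "classify", "n_trees", 500),
            nFolds = .cfg(config, "classify", "n_folds", 5),
            seed = seed)
        lc <- learningCurve(feats$x, feats$y,
            fractions = .cfg(config, "classify", "fractions",
                             c(0.25, 0.5, 0.75, 1)),
            nTrees = .cfg(config, "classify", "n_trees", 500), seed = seed)
        p <- file.path(outDir, "classifier_report.json")
        jsonlite::write_json(list(
            auc = rep$auc, pr_auc = rep$pr_auc, fold_auc = rep$fold_auc,
            per_class_auc = as.list(rep$per_class_auc),
            confusion = as.data.frame(rep$confusion)),
            p, auto_unbox = TRUE, digits = NA)
        utils::write.csv(lc, file.path(outDir, "learning_curve.csv"),
                         row.names = FALSE)
        roc <- do.call(rbind, lapply(names(rep$roc_curves), function(cl)
            cbind(class = cl, rep$roc_curves[[cl]])))
        utils::write.csv(roc, file.path(outDir, "roc_curves.csv"),
                         row.names = FALSE)
        paths <- c(paths, p, file.path(outDir, "learning_curve.csv"),
                    file.path(outDir, "roc_curves.csv"))
    })
    stage("report", {
        ct <- as.data.frame(SummarizedExperiment::colData(sce))
        if ("cell_type" %in% colnames(ct))
            emit(composition(ct, "cell_type"), "composition_types.tsv")
        if ("metabolic_state" %in% colnames(ct)) {
            emit(composition(ct, "metabolic_state"),
                 "composition_states.tsv")
            if ("cluster" %in% colnames(ct))
                emit(composition(ct, "metabolic_state", "cluster"),
                     "composition_states_by_cluster.tsv")
        }
        summary <- list(
            package_version = as.character(utils::packageVersion("scTubule")),
            seed = seed, stages = stages, config = config,
            n_cells_kept = ncol(sce), n_genes = nrow(sce))
        p <- file.path(outDir, "run_summary.json")
        jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                             null = "null")
        paths <- c(paths, p)
    })
    invisible(list(sce = sce, paths = paths, hvgs = hv))
}
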