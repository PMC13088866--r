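#' Write a simulated (or real) experiment to disk
#'
#' Persists the experiment in the standard exchange layout: sparse counts as
#' Matrix Market \code{matrix.mtx}, gene sidecar \code{genes.tsv} (symbol and,
#' when present, program), cell sidecar \code{barcodes.tsv}, plus ground-truth
#' tables \code{truth_cells.tsv} / \code{truth_genes.tsv} and the generator
#' parameters as a flat key-value \code{params.cfg} when the object came from
#' [simulateKidney()].
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
writeExperiment <- function(sce, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(methods::as(
        SummarizedExperiment::assay(sce, "counts"), "CsparseMatrix"),
        file.path(dir, "matrix.mtx"))
    rd <- as.data.frame(SummarizedExperiment::rowData(sce))
    genes <- data.frame(gene = rownames(sce))
    if ("program" %in% colnames(rd)) genes$program <- rd$program
    utils::write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(barcode = colnames(sce)),
                       file.path(dir, "barcodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(sce))
    truth_cols <- intersect(c("true_type", "true_state", "true_pseudotime"),
                            colnames(cd))
    if (length(truth_cols)) {
        utils::write.table(
            cbind(data.frame(barcode = colnames(sce)), cd[, truth_cols,
                                                          drop = FALSE]),
            file.path(dir, "truth_cells.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
    }
    if ("program" %in% colnames(rd))
        utils::write.table(
            data.frame(gene = rownames(sce), program = rd$program),
            file.path(dir, "truth_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
    params <- S4Vectors::metadata(sce)$params
    if (!is.null(params))
        writeConfigFile(simParamsToConfig(params),
                        file.path(dir, "params.cfg"))
    invisible(dir)
}

#' Read an experiment from Matrix Market + TSV sidecars
#'
#' @param dir directory containing \code{matrix.mtx}, \code{genes.tsv} and
#'   \code{barcodes.tsv} (and optionally the truth sidecars written by
#'   [writeExperiment()]).
#' @return A \code{SingleCellExperiment} with a sparse integer \code{counts}
#'   assay.
#' @export
readExperiment <- function(dir) {
    counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                          "CsparseMatrix")
    genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                               stringsAsFactors = FALSE)
    barcodes <- utils::read.delim(file.path(dir, "barcodes.tsv"),
                                  stringsAsFactors = FALSE)
    if (nrow(genes) != nrow(counts) || nrow(barcodes) != ncol(counts))
        stop("sidecar dimensions do not match matrix.mtx")
    dimnames(counts) <- list(genes$gene, barcodes$barcode)
    rd <- S4Vectors::DataFrame(genes, row.names = genes$gene)
    cd <- S4Vectors::DataFrame(row.names = barcodes$barcode)
    truth_path <- file.path(dir, "truth_cells.tsv")
    if (file.exists(truth_path)) {
        truth <- utils::read.delim(truth_path, stringsAsFactors = FALSE)
        stopifnot(identical(truth$barcode, barcodes$barcode))
        for (cc in setdiff(colnames(truth), "barcode")) cd[[cc]] <- truth[[cc]]
    }
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), rowData = rd, colData = cd)
}

#' @noRd
simParamsToConfig <- function(params) {
    list(simulate = list(
        n_cells = params@nCells,
        type_names = names(params@typeProportions),
        type_proportions = unname(params@typeProportions),
        n_background_genes = params@nBackgroundGenes,
        marker_effect = params@markerEffect,
        metabolic_effect = params@metabolicEffect,
        injury_gradient_strength = params@injuryGradientStrength,
        mito_stress_fraction = params@mitoStressFraction,
        nb_mean = params@nbMean,
        nb_dispersion = params@nbDispersion,
        dropout_rate = params@dropoutRate,
        seed = params@seed))
}

#' @noRd
simParamsFromConfig <- function(config) {
    s <- config$simulate
    if (is.null(s)) s <- list()
    defaults <- SimParams()
    getv <- function(key, slot) if (!is.null(s[[key]])) s[[key]] else
        methods::slot(defaults, slot)
    props <- if (!is.null(s$type_names))
        stats::setNames(as.numeric(s$type_proportions),
                        as.character(s$type_names))
    else defaults@typeProportions
    SimParams(
        nCells = getv("n_cells", "nCells"),
        typeProportions = props,
        nBackgroundGenes = getv("n_background_genes", "nBackgroundGenes"),
        markerEffect = getv("marker_effect", "markerEffect"),
        metabolicEffect = getv("metabolic_effect", "metabolicEffect"),
        injuryGradientStrength = getv("injury_gradient_strength",
                                      "injuryGradientStrength"),
        mitoStressFraction = getv("mito_stress_fraction",
                                  "mitoStressFraction"),
        nbMean = getv("nb_mean", "nbMean"),
        nbDispersion = getv("nb_dispersion", "nbDispersion"),
        dropoutRate = getv("dropout_rate", "dropoutRate"),
        seed = getv("seed", "seed"))
}
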