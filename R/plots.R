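#' UMAP embedding colored by a cell attribute
#'
#' @param sce SCE with a \code{"UMAP"} reducedDim.
#' @param colourBy name of a \code{colData} column.
#' @return a ggplot object.
#' @export
plotUMAP <- function(sce, colourBy = "cluster") {
    um <- SingleCellExperiment::reducedDim(sce, "UMAP")
    df <- data.frame(UMAP1 = um[, 1], UMAP2 = um[, 2],
                     value = SummarizedExperiment::colData(sce)[[colourBy]])
    ggplot2::ggplot(df, ggplot2::aes(.data$UMAP1, .data$UMAP2,
                                     colour = .data$value)) +
        ggplot2::geom_point(size = 0.4) +
        ggplot2::labs(colour = colourBy) +
        ggplot2::theme_classic()
}

#' Glycolysis-versus-OXPHOS quadrant scatter colored by metabolic state
#'
#' @param sce SCE after [addMetabolicCalls()].
#' @return a ggplot object.
#' @export
plotStateScatter <- function(sce) {
    df <- data.frame(glyc = sce$glyc_score, oxphos = sce$oxphos_score,
                     state = sce$metabolic_state)
    ggplot2::ggplot(df, ggplot2::aes(.data$glyc, .data$oxphos,
                                     colour = .data$state)) +
        ggplot2::geom_point(size = 0.4) +
        ggplot2::labs(x = "glycolysis score", y = "OXPHOS score") +
        ggplot2::theme_classic()
}

#' Stacked-bar composition plot
#'
#' @param comp a [composition()] table (use \code{within} for stacked bars
#'   per group).
#' @return a ggplot object.
#' @export
plotComposition <- function(comp) {
    ggplot2::ggplot(comp, ggplot2::aes(.data$group, .data$fraction,
                                       fill = .data$category)) +
        ggplot2::geom_col() +
        ggplot2::theme_classic()
}

#' Binned gene dynamics along pseudotime
#'
#' @param dyn a [geneDynamics()] table.
#' @param gene label for the title.
#' @return a ggplot object.
#' @export
plotGeneDynamics <- function(dyn, gene = "") {
    df <- dyn[dyn$n > 0, ]
    ggplot2::ggplot(df, ggplot2::aes(.data$center, .data$mean)) +
        ggplot2::geom_ribbon(ggplot2::aes(
            ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
            alpha = 0.25) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "pseudotime", y = "normalized expression",
                      title = gene) +
        ggplot2::theme_classic()
}
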