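#' Simulation parameters for the synthetic kidney scRNA-seq generator
#'
#' S4 container for every knob of the count-matrix simulator. Defaults encode
#' the study conditions the package is designed around: 3000 cells, seven renal
#' cell types with a ~70% proximal-tubule (PT) majority, strong planted marker
#' and metabolic effects, and an injury pseudotime gradient within PT.
#'
#' @slot nCells number of cells to simulate.
#' @slot typeProportions named numeric vector of cell-type fractions; must sum
#'   to 1 (within 1e-9). Cell counts per type follow deterministic
#'   largest-remainder rounding so the realized composition is exact.
#' @slot nBackgroundGenes number of unstructured background genes.
#' @slot markerEffect fold-change (>= 1) applied to a type's marker genes in
#'   cells of that type.
#' @slot metabolicEffect fold-change (>= 1) setting the dynamic range of the
#'   planted glycolysis/OXPHOS programs and of the mitochondrial boost in
#'   dormant cells.
#' @slot injuryGradientStrength rate (>= 0) of the log-linear injury gradient
#'   in PT cells: glycolysis genes gain, PT markers and OXPHOS genes lose
#'   expression along true pseudotime. 0 disables the gradient.
#' @slot mitoStressFraction fraction of PT cells planted as
#'   dormant/mitochondrial-high.
#' @slot nbMean baseline negative-binomial mean per gene.
#' @slot nbDispersion negative-binomial size (dispersion) parameter; variance
#'   is mu + mu^2/size.
#' @slot dropoutRate probability in [0, 1) that any count is zeroed.
#' @slot seed integer seed; identical parameters give bit-identical output.
#'
#' @seealso [SimParams()], [simulateKidney()], [buildGenePanel()]
#' @exportClass SimParams
setClass("SimParams", slots = c(
    nCells = "integer",
    typeProportions = "numeric",
    nBackgroundGenes = "integer",
    markerEffect = "numeric",
    metabolicEffect = "numeric",
    injuryGradientStrength = "numeric",
    mitoStressFraction = "numeric",
    nbMean = "numeric",
    nbDispersion = "numeric",
    dropoutRate = "numeric",
    seed = "integer"
))

setValidity("SimParams", function(object) {
    msg <- character()
    if (object@nCells < 1L)
        msg <- c(msg, "nCells must be a positive integer")
    p <- object@typeProportions
    if (is.null(names(p)) || any(!nzchar(names(p))) || anyDuplicated(names(p)))
        msg <- c(msg, "typeProportions must have unique non-empty names")
    if (any(p < 0) || any(p > 1))
        msg <- c(msg, "typeProportions must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-9)
        msg <- c(msg, "typeProportions must sum to 1 (within 1e-9)")
    if (object@nBackgroundGenes < 0L)
        msg <- c(msg, "nBackgroundGenes must be non-negative")
    if (object@markerEffect < 1)
        msg <- c(msg, "markerEffect must be >= 1")
    if (object@metabolicEffect < 1)
        msg <- c(msg, "metabolicEffect must be >= 1")
    if (object@injuryGradientStrength < 0)
        msg <- c(msg, "injuryGradientStrength must be >= 0")
    if (object@mitoStressFraction < 0 || object@mitoStressFraction > 1)
        msg <- c(msg, "mitoStressFraction must lie in [0, 1]")
    if (object@nbMean <= 0)
        msg <- c(msg, "nbMean must be positive")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion must be positive")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
        msg <- c(msg, "dropoutRate must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' @param nCells number of cells (default 3000).
#' @param typeProportions named fractions per cell type; the default mirrors a
#'   diseased-kidney composition with a 70% proximal-tubule majority.
#' @param nBackgroundGenes background genes without planted structure.
#' @param markerEffect,metabolicEffect,injuryGradientStrength,mitoStressFraction
#'   planted-effect sizes; see [SimParams-class].
#' @param nbMean,nbDispersion,dropoutRate negative-binomial noise model.
#' @param seed integer RNG seed.
#'
#' @return A validated [SimParams-class] object.
#' @examples
#' sp <- SimParams(nCells = 500, seed = 7)
#' sp
#' @export
SimParams <- function(nCells = 3000,
                      typeProportions = c(PT = 0.70, Endo = 0.08, Fib = 0.07,
                                          Mac = 0.05, Peri = 0.04, Podo = 0.03,
                                          TC = 0.03),
                      nBackgroundGenes = 1200,
                      markerEffect = 8,
                      metabolicEffect = 6,
                      injuryGradientStrength = 1.4,
                      mitoStressFraction = 0.10,
                      nbMean = 1,
                      nbDispersion = 5,
                      dropoutRate = 0.05,
                      seed = 1) {
    methods::new("SimParams",
        nCells = as.integer(nCells),
        typeProportions = typeProportions,
        nBackgroundGenes = as.integer(nBackgroundGenes),
        markerEffect = as.numeric(markerEffect),
        metabolicEffect = as.numeric(metabolicEffect),
        injuryGradientStrength = as.numeric(injuryGradientStrength),
        mitoStressFraction = as.numeric(mitoStressFraction),
        nbMean = as.numeric(nbMean),
        nbDispersion = as.numeric(nbDispersion),
        dropoutRate = as.numeric(dropoutRate),
        seed = as.integer(seed))
}

#' @describeIn SimParams-class compact display of the parameter set.
#' @param object a \code{SimParams} object.
#' @export
setMethod("show", "SimParams", function(object) {
    cat("SimParams:", object@nCells, "cells,",
        length(object@typeProportions), "cell types\n")
    cat("  proportions:",
        paste(names(object@typeProportions), signif(object@typeProportions, 3),
              sep = "=", collapse = ", "), "\n")
    cat("  markerEffect =", object@markerEffect,
        " metabolicEffect =", object@metabolicEffect,
        " injuryGradientStrength =", object@injuryGradientStrength, "\n")
    cat("  mitoStressFraction =", object@mitoStressFraction,
        " NB(mean =", object@nbMean, ", size =", object@nbDispersion,
        ") dropout =", object@dropoutRate, " seed =", object@seed, "\n")
    invisible(NULL)
})
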