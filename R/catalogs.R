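#' Default renal cell-type marker catalog
#'
#' Canonical marker genes for the major renal cell types handled by the
#' annotation stage. The proximal-tubule set is the segment-marker panel
#' (SLC34A1, SLC5A2, LRP2, CUBN, ALDOB, GATM); the remaining sets are
#' field-standard markers supplied as package defaults and replaceable via
#' [readMarkerCatalog()].
#'
#' @return Named list of character vectors (type -> marker gene symbols).
#' @examples
#' names(defaultMarkerCatalog())
#' @export
defaultMarkerCatalog <- function() {
    list(
        PT   = c("SLC34A1", "SLC5A2", "LRP2", "CUBN", "ALDOB", "GATM"),
        Endo = c("PECAM1", "FLT1", "KDR", "EMCN", "CDH5"),
        Fib  = c("COL1A1", "COL1A2", "PDGFRA", "DCN", "LUM"),
        Peri = c("PDGFRB", "RGS5", "NOTCH3", "MYH11", "ACTA2"),
        Podo = c("NPHS1", "NPHS2", "PODXL", "WT1", "SYNPO"),
        Mac  = c("CD68", "CD14", "CSF1R", "LYZ", "ITGAM"),
        TC   = c("CD3E", "CD3D", "CD2", "IL7R", "TRAC")
    )
}

#' Default metabolic gene sets
#'
#' Custom gene sets used by the additive pathway scoring: a glycolysis set
#' containing the core enzymes GPI, ENO1, HK1, LDHA and LDHB, and an
#' OXPHOS/TCA set containing IDH1 and IDH2, each extended with additional
#' pathway members. Replaceable via [readGeneSets()].
#'
#' @return Named list with elements \code{glycolysis} and \code{oxphos}.
#' @examples
#' lengths(defaultGeneSets())
#' @export
defaultGeneSets <- function() {
    list(
        glycolysis = c("GPI", "ENO1", "HK1", "LDHA", "LDHB",
                       "PFKL", "PKM", "ALDOA", "GAPDH", "PGK1"),
        oxphos = c("IDH1", "IDH2", "CS", "SDHA", "FH",
                   "MDH2", "NDUFS1", "COX5A", "UQCRC1", "ATP5F1A")
    )
}

#' Glycolytic and TCA enzymes profiled individually
#'
#' @return Character vector of the seven enzyme symbols.
#' @export
metabolicEnzymes <- function() {
    c("GPI", "ENO1", "HK1", "LDHA", "LDHB", "IDH1", "IDH2")
}

#' Default ligand-receptor pair catalog
#'
#' A small catalog of ligand-receptor pairs relevant to kidney injury and
#' fibrosis signaling, shipped as a TSV under \code{inst/extdata}. Intended as
#' a starting point; real analyses should supply their own catalog via
#' [readLRPairs()].
#'
#' @return data.frame with columns \code{ligand} and \code{receptor}.
#' @examples
#' head(defaultLRPairs())
#' @export
defaultLRPairs <- function() {
    readLRPairs(system.file("extdata", "lr_pairs.tsv", package = "scTubule",
                            mustWork = TRUE))
}

#' Read a marker catalog from TSV
#'
#' @param path TSV with columns \code{type} and \code{gene}.
#' @return Named list of character vectors.
#' @export
readMarkerCatalog <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("type", "gene") %in% colnames(tab)))
    split(tab$gene, tab$type)
}

#' Read gene sets from TSV
#'
#' @param path TSV with columns \code{set_name} and \code{gene}.
#' @return Named list of character vectors.
#' @export
readGeneSets <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("set_name", "gene") %in% colnames(tab)))
    sets <- split(tab$gene, tab$set_name)
    bad <- vapply(sets, anyDuplicated, 0L) > 0L
    if (any(bad))
        stop("duplicate gene symbols within set(s): ",
             paste(names(sets)[bad], collapse = ", "))
    sets
}

#' Read ligand-receptor pairs from TSV
#'
#' @param path TSV with columns \code{ligand} and \code{receptor}.
#' @return data.frame with unique, non-empty pairs.
#' @export
readLRPairs <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("ligand", "receptor") %in% colnames(tab)))
    if (any(!nzchar(tab$ligand)) || any(!nzchar(tab$receptor)))
        stop("ligand and receptor symbols must be non-empty")
    if (anyDuplicated(paste(tab$ligand, tab$receptor)))
        stop("duplicated ligand-receptor pairs in catalog")
    tab[, c("ligand", "receptor")]
}
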