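#' Build the simulated gene panel
#'
#' Assembles the gene universe of the simulator and assigns every gene to
#' exactly one program: type markers for each cell type in
#' \code{typeProportions} (the PT set being the six segment markers),
#' glycolysis and OXPHOS/TCA enzyme programs, mitochondrial ("MT-" prefixed)
#' and ribosomal ("RPS"/"RPL" prefixed) genes, one uniformly expressed
#' conserved gene (MALAT1), one injury-variable gene (ANXA1), and
#' \code{nBackgroundGenes} unstructured background genes.
#'
#' Baseline negative-binomial means are attached per gene, scaled from
#' \code{nbMean}: program and enzyme genes sit above background so that
#' pathway sums carry signal, mitochondrial genes are set so that a healthy
#' cell has a mitochondrial fraction of roughly 7%, and MALAT1 is a high
#' expressor detected in essentially every cell.
#'
#' @param params a [SimParams-class] object.
#' @return data.frame with columns \code{gene}, \code{program},
#'   \code{base_mean}; one row per gene, programs forming a partition.
#' @examples
#' panel <- buildGenePanel(SimParams(nCells = 100))
#' table(panel$program)
#' @export
buildGenePanel <- function(params) {
    methods::validObject(params)
    markers <- defaultMarkerCatalog()
    types <- names(params@typeProportions)
    mu0 <- params@nbMean

    rows <- list()
    add <- function(genes, program, base) {
        rows[[length(rows) + 1L]] <<- data.frame(
            gene = genes, program = program, base_mean = base,
            stringsAsFactors = FALSE)
    }
    # type-enriched ligands/receptors folded into the type programs so that
    # communication scoring has realistic sender/receiver structure
    lr_extra <- list(
        PT = c("TGFBR1", "TGFBR2", "MET", "TNFRSF1A"),
        Fib = c("TGFB1", "HGF", "PDGFA"),
        Endo = c("PDGFB", "JAG1"),
        Podo = c("VEGFA"),
        Mac = c("TNF", "CCL2"))
    for (ty in types) {
        gs <- markers[[ty]]
        if (is.null(gs))  # unknown type: synthesize marker symbols
            gs <- sprintf("%s.MK%d", toupper(ty), seq_len(5))
        # each type carries its canonical markers plus a broader program of
        # auxiliary type genes, mirroring the transcriptome-wide differences
        # between real cell types; all are near-silent outside the type
        extra <- lr_extra[[ty]]
        gs <- c(gs, extra,
                sprintf("%s.P%02d", toupper(ty),
                        seq_len(25 - length(extra))))
        add(gs, paste0("type_marker:", ty), 0.3 * mu0)
    }
    sets <- defaultGeneSets()
    add(sets$glycolysis, "glycolysis", 3 * mu0)
    add(sets$oxphos, "oxphos", 3 * mu0)
    add(c("MT-ND1", "MT-ND2", "MT-ND4", "MT-CO1", "MT-CO2", "MT-CO3",
          "MT-ATP6", "MT-CYB"), "mito", 15 * mu0)
    add(c("RPS2", "RPS3", "RPS6", "RPS18", "RPS27",
          "RPL3", "RPL5", "RPL10", "RPL13", "RPL28"), "ribo", 5 * mu0)
    add("MALAT1", "conserved", 20 * mu0)
    # damage-response module induced along the injury gradient: ANXA1 (the
    # most variable injury gene) plus canonical injured-PT markers
    add("ANXA1", "injury_variable", 2 * mu0)
    add(c("HAVCR1", "LCN2", "VCAM1", "SOX9", "KRT8", "KRT18", "CD24",
          "CD44", "TPM1", "S100A6"), "injury_variable", 1.5 * mu0)
    if (params@nBackgroundGenes > 0L)
        add(sprintf("BG%04d", seq_len(params@nBackgroundGenes)),
            "background", mu0)

    panel <- do.call(rbind, rows)
    dup <- panel$gene[duplicated(panel$gene)]
    if (length(dup))
        stop("duplicate gene symbols in panel: ",
             paste(unique(dup), collapse = ", "))
    rownames(panel) <- panel$gene
    panel
}

#' Largest-remainder apportionment of cells to types
#'
#' Deterministic rounding of \code{proportions * n}: each type gets the floor
#' of its quota, and the remaining cells go to the largest fractional
#' remainders (ties broken by type name).
#'
#' @param n total number of cells.
#' @param proportions named fractions summing to 1.
#' @return Named integer vector summing to \code{n}.
#' @export
largestRemainder <- function(n, proportions) {
    quota <- proportions * n
    base <- floor(quota)
    rem <- n - sum(base)
    frac <- quota - base
    if (rem > 0) {
        ord <- order(-frac, names(proportions))
        base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    }
    stats::setNames(as.integer(base), names(proportions))
}

#' Simulate a kidney-like scRNA-seq count matrix with ground truth
#'
#' Draws a sparse gene-by-cell count matrix from a negative-binomial model
#' with multiplicative planted effects, and records the full latent truth:
#'
#' \itemize{
#'   \item Cell types follow [largestRemainder()] apportionment of
#'     \code{typeProportions}, so the realized composition is exact.
#'   \item Marker genes of a cell's type have their mean multiplied by
#'     \code{markerEffect}.
#'   \item Every PT cell carries a true injury pseudotime \eqn{t ~ U(0,1)}.
#'     Along \eqn{t}, glycolysis genes scale by
#'     \eqn{m^{g (t - 1/2)}} and OXPHOS genes by \eqn{m^{-g (t - 1/2)}}
#'     (with \eqn{m} = \code{metabolicEffect}, \eqn{g} =
#'     \code{injuryGradientStrength}); PT segment markers decay as
#'     \eqn{e^{-g (t - 1/2)}}, modelling dedifferentiation; the
#'     injury-variable gene ANXA1 rises as \eqn{m^{1.5 g (t - 1/2)}} and the
#'     broader damage-response module as \eqn{m^{g (t - 1/2)}}.
#'   \item A \code{mitoStressFraction} subset of PT cells is planted as
#'     dormant/mitochondrial-high: MT- genes multiplied by
#'     \code{metabolicEffect}, both metabolic programs divided by it.
#'   \item MALAT1 has equal expected expression in every cell.
#'   \item Counts are NB(\code{nbMean}-scaled mean, size =
#'     \code{nbDispersion}) then zeroed with probability \code{dropoutRate}.
#' }
#'
#' True metabolic states label dormant cells \code{Dorm_Mt_high}; remaining PT
#' cells are \code{Glyc} for \eqn{t \ge 0.65}, \code{OXPHOS_high} for
#' \eqn{t \le 0.35}, else \code{Intermediate}; non-PT cells are
#' \code{Intermediate}.
#'
#' @param params a [SimParams-class] object; all randomness derives from
#'   \code{params@seed}.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   \code{counts} assay; \code{rowData} columns \code{gene}, \code{program},
#'   \code{base_mean}; \code{colData} columns \code{true_type},
#'   \code{true_state}, \code{true_pseudotime} (NA outside PT); and the
#'   parameters in \code{metadata(sce)$params}.
#' @examples
#' sce <- simulateKidney(SimParams(nCells = 200, nBackgroundGenes = 50))
#' table(sce$true_type)
#' @export
simulateKidney <- function(params) {
    methods::validObject(params)
    panel <- buildGenePanel(params)
    nc <- params@nCells
    types <- names(params@typeProportions)
    if (nc < length(types))
        stop("n_cells (", nc, ") is smaller than the number of cell types (",
             length(types), ")")

    set.seed(params@seed)
    counts_per_type <- largestRemainder(nc, params@typeProportions)
    cell_type <- rep(types, counts_per_type)

    is_pt <- cell_type == "PT"
    n_pt <- sum(is_pt)
    t_true <- rep(NA_real_, nc)
    t_true[is_pt] <- stats::runif(n_pt)

    dormant <- rep(FALSE, nc)
    if (n_pt > 0 && params@mitoStressFraction > 0) {
        n_dorm <- round(params@mitoStressFraction * n_pt)
        dormant[sample(which(is_pt), n_dorm)] <- TRUE
    }

    state <- rep("Intermediate", nc)
    state[is_pt & !dormant & t_true >= 0.65] <- "Glyc"
    state[is_pt & !dormant & t_true <= 0.35] <- "OXPHOS_high"
    state[dormant] <- "Dorm_Mt_high"

    ng <- nrow(panel)
    mu <- matrix(rep(panel$base_mean, nc), nrow = ng, ncol = nc)

    # type-marker boost
    for (ty in types) {
        gsel <- panel$program == paste0("type_marker:", ty)
        csel <- cell_type == ty
        if (any(gsel) && any(csel))
            mu[gsel, csel] <- mu[gsel, csel] * params@markerEffect
    }

    g <- params@injuryGradientStrength
    m <- params@metabolicEffect
    glyc_g <- panel$program == "glycolysis"
    oxph_g <- panel$program == "oxphos"
    mito_g <- panel$program == "mito"
    # segment markers dedifferentiate along the gradient; the auxiliary PT
    # program (shared tubular identity) stays stable
    ptmk_g <- panel$gene %in% defaultMarkerCatalog()$PT
    anxa_g <- panel$gene == "ANXA1"
    inj_g <- panel$program == "injury_variable" & !anxa_g

    if (n_pt > 0) {
        tc <- t_true[is_pt] - 0.5
        up <- m^(g * tc)            # glycolysis gain along injury
        mu[glyc_g, is_pt] <- mu[glyc_g, is_pt] *
            rep(up, each = sum(glyc_g))
        mu[oxph_g, is_pt] <- mu[oxph_g, is_pt] *
            rep(1 / up, each = sum(oxph_g))
        mu[ptmk_g, is_pt] <- mu[ptmk_g, is_pt] *
            rep(exp(-g * tc), each = sum(ptmk_g))
        mu[anxa_g, is_pt] <- mu[anxa_g, is_pt] *
            rep(m^(1.5 * g * tc), each = sum(anxa_g))
        mu[inj_g, is_pt] <- mu[inj_g, is_pt] *
            rep(m^(g * tc), each = sum(inj_g))
    }
    if (any(dormant)) {
        # dormancy scales both metabolic programs down globally (scores low)
        # while keeping the residual injury-gradient modulation
        mu[mito_g, dormant] <- mu[mito_g, dormant] * m
        mu[glyc_g, dormant] <- mu[glyc_g, dormant] / m
        mu[oxph_g, dormant] <- mu[oxph_g, dormant] / m
    }

    cnt <- stats::rnbinom(length(mu), mu = mu, size = params@nbDispersion)
    if (params@dropoutRate > 0)
        cnt[stats::runif(length(cnt)) < params@dropoutRate] <- 0L
    counts <- Matrix::Matrix(matrix(cnt, nrow = ng, ncol = nc), sparse = TRUE)
    dimnames(counts) <- list(panel$gene,
                             sprintf("cell_%05d", seq_len(nc)))

    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(panel, row.names = panel$gene),
        colData = S4Vectors::DataFrame(
            true_type = cell_type,
            true_state = state,
            true_pseudotime = t_true,
            row.names = colnames(counts)))
    S4Vectors::metadata(sce)$params <- params
    sce
}
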