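#' Ligand-receptor coexpression scores across type pairs
#'
#' For every ordered (sender, receiver) type combination and every catalog
#' pair whose ligand and receptor are both present, the interaction score is
#' the product of the mean normalized ligand expression in the sender type
#' and the mean normalized receptor expression in the receiver type — the
#' minimal coexpression statistic behind the dot-plot display. The expressing
#' fraction is the smaller of the sender's ligand-positive and the receiver's
#' receptor-positive cell fractions.
#'
#' @param sce SCE with \code{counts} and \code{logcounts}.
#' @param cellTypes per-cell type labels (>= 2 types).
#' @param pairs data.frame with \code{ligand} and \code{receptor} columns
#'   (default [defaultLRPairs()]); pairs with missing genes are skipped with
#'   a message.
#' @return data.frame with \code{sender}, \code{receiver}, \code{ligand},
#'   \code{receptor}, \code{score}, \code{frac_expressing} and a \code{p_perm}
#'   column initialized to NA (see [permutationTest()]).
#' @export
scoreInteractions <- function(sce, cellTypes = sce$cell_type,
                              pairs = defaultLRPairs()) {
    x <- SummarizedExperiment::assay(sce, "logcounts")
    cnt <- SummarizedExperiment::assay(sce, "counts")
    types <- droplevels(as.factor(cellTypes))
    if (nlevels(types) < 2) stop("need at least 2 cell types")
    if (any(table(types) == 0)) stop("cell type with zero cells")
    ok <- pairs$ligand %in% rownames(x) & pairs$receptor %in% rownames(x)
    if (any(!ok))
        message("skipping ", sum(!ok), " pair(s) with genes absent from ",
                "the matrix")
    pairs <- pairs[ok, , drop = FALSE]
    if (!nrow(pairs)) stop("no ligand-receptor pair has both genes present")
    gs <- unique(c(pairs$ligand, pairs$receptor))
    mexpr <- vapply(levels(types), function(ty)
        Matrix::rowMeans(x[gs, types == ty, drop = FALSE]), numeric(length(gs)))
    mdet <- vapply(levels(types), function(ty)
        Matrix::rowMeans(cnt[gs, types == ty, drop = FALSE] > 0),
        numeric(length(gs)))
    rownames(mexpr) <- rownames(mdet) <- gs
    grid <- expand.grid(sender = levels(types), receiver = levels(types),
                        pair = seq_len(nrow(pairs)),
                        stringsAsFactors = FALSE)
    out <- data.frame(
        sender = grid$sender, receiver = grid$receiver,
        ligand = pairs$ligand[grid$pair], receptor = pairs$receptor[grid$pair],
        stringsAsFactors = FALSE)
    out$score <- mexpr[cbind(out$ligand, out$sender)] *
        mexpr[cbind(out$receptor, out$receiver)]
    out$frac_expressing <- pmin(mdet[cbind(out$ligand, out$sender)],
                                mdet[cbind(out$receptor, out$receiver)])
    out$p_perm <- NA_real_
    out
}

#' Permutation p-value for one ligand-receptor interaction
#'
#' Null: cell-type labels shuffled across all cells. The p-value is
#' (1 + number of permuted scores >= observed) / (1 + nPerm), so an observed
#' score of 0 gives p = 1 by construction.
#'
#' @param sce SCE with \code{logcounts}.
#' @param cellTypes per-cell type labels.
#' @param ligand,receptor gene symbols.
#' @param sender,receiver type labels.
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param seed RNG seed.
#' @return scalar p-value.
#' @export
permutationTest <- function(sce, cellTypes, ligand, receptor, sender,
                            receiver, nPerm = 1000, seed = 1) {
    if (nPerm < 100) stop("nPerm must be at least 100")
    x <- SummarizedExperiment::assay(sce, "logcounts")
    lig <- as.numeric(x[ligand, ])
    rec <- as.numeric(x[receptor, ])
    types <- as.character(cellTypes)
    s_mask <- types == sender
    r_mask <- types == receiver
    obs <- mean(lig[s_mask]) * mean(rec[r_mask])
    set.seed(seed)
    n <- length(types)
    perm <- vapply(seq_len(nPerm), function(i) {
        sh <- sample.int(n)
        mean(lig[sh[s_mask]]) * mean(rec[sh[r_mask]])
    }, 0)
    (1 + sum(perm >= obs)) / (1 + nPerm)
}

#' Matrix-form dot-plot table of interaction records
#'
#' Lossless reshape: rows are ligand-receptor pairs, columns are
#' "sender->receiver" type combinations; returns one matrix for the score
#' (dot color) and one for the expressing fraction (dot size).
#'
#' @param records output of [scoreInteractions()].
#' @return list with matrices \code{score} and \code{frac_expressing}.
#' @export
dotplotTable <- function(records) {
    pr <- paste(records$ligand, records$receptor, sep = "_")
    tp <- paste(records$sender, records$receiver, sep = "->")
    prl <- unique(pr); tpl <- unique(tp)
    sc <- matrix(NA_real_, length(prl), length(tpl),
                 dimnames = list(prl, tpl))
    fr <- sc
    sc[cbind(pr, tp)] <- records$score
    fr[cbind(pr, tp)] <- records$frac_expressing
    list(score = sc, frac_expressing = fr)
}
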