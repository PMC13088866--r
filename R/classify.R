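#' Feature matrix and labels for cell-state classification
#'
#' Features are normalized expression restricted to the selected highly
#' variable genes, in HVG rank order. Classes with fewer members than
#' \code{nFolds} cannot be stratified and are dropped with a warning.
#'
#' @param sce SCE with \code{logcounts}.
#' @param hvgs [selectHVGs()] output (or a character vector of genes).
#' @param labels per-cell class labels (e.g. metabolic state or final type).
#' @param nFolds intended number of CV folds (default 5).
#' @return list with \code{x} (cell-by-gene matrix), \code{y} (factor) and
#'   \code{genes}.
#' @export
makeFeatures <- function(sce, hvgs, labels, nFolds = 5) {
    genes <- if (is.character(hvgs)) hvgs else hvgGenes(hvgs)
    genes <- genes[genes %in% rownames(sce)]
    if (anyNA(labels)) stop("labels must be present for every cell")
    y <- droplevels(as.factor(labels))
    small <- names(which(table(y) < nFolds))
    keep <- !(y %in% small)
    if (length(small))
        warning("dropping class(es) smaller than nFolds: ",
                paste(small, collapse = ", "))
    y <- droplevels(y[keep])
    if (nlevels(y) < 2) stop("fewer than 2 classes remain")
    x <- t(as.matrix(
        SummarizedExperiment::assay(sce, "logcounts")[genes, keep,
                                                      drop = FALSE]))
    list(x = x, y = y, genes = genes)
}

#' @noRd
#' Stratified fold assignment: within each class, shuffled cells are dealt
#' round-robin into folds.
.stratifiedFolds <- function(y, nFolds, seed) {
    set.seed(seed)
    fold <- integer(length(y))
    for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    fold
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney form of the binary AUC; ties in scores are handled by
#' average ranks.
#'
#' @param scores predicted scores (higher = more positive).
#' @param positive logical vector marking positive cases.
#' @return scalar AUC in [0, 1].
#' @export
binaryAUC <- function(scores, positive) {
    n1 <- sum(positive); n0 <- sum(!positive)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores)
    (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @noRd
#' Macro one-vs-rest ROC AUC from a class-probability matrix.
.macroAUC <- function(prob, y) {
    aucs <- vapply(colnames(prob), function(cl)
        binaryAUC(prob[, cl], y == cl), 0)
    mean(aucs, na.rm = TRUE)
}

#' @noRd
#' Average precision (area under the precision-recall curve).
.prAUC <- function(scores, positive) {
    n1 <- sum(positive)
    if (n1 == 0) return(NA_real_)
    ord <- order(scores, decreasing = TRUE)
    tp <- cumsum(positive[ord])
    prec <- tp / seq_along(tp)
    sum(prec[positive[ord]]) / n1
}

#' @noRd
#' ROC curve points (fpr, tpr) for one class.
.rocPoints <- function(scores, positive) {
    ord <- order(scores, decreasing = TRUE)
    tp <- cumsum(positive[ord]); fp <- cumsum(!positive[ord])
    data.frame(threshold = scores[ord],
               fpr = fp / max(sum(!positive), 1),
               tpr = tp / max(sum(positive), 1))
}

#' @noRd
.fitForest <- function(x, y, nTrees, mtry, seed) {
    m <- if (identical(mtry, "default")) floor(sqrt(ncol(x))) else mtry
    ranger::ranger(x = x, y = y, num.trees = nTrees, mtry = m,
                   probability = TRUE, seed = seed, num.threads = 1)
}

#' Cross-validated random-forest cell-state classifier
#'
#' Stratified k-fold cross-validation of a random forest (default 500 trees,
#' mtry = floor(sqrt(p))). Held-out class probabilities are pooled across
#' folds for the headline macro one-vs-rest ROC AUC and PR AUC; per-fold
#' macro AUCs capture dispersion. Per-class ROC and PR curves and the pooled
#' confusion matrix are included in the report.
#'
#' @param x cell-by-feature matrix ([makeFeatures()]).
#' @param y class factor.
#' @param nTrees number of trees (default 500).
#' @param mtry \code{"default"} (floor(sqrt(p))) or an integer.
#' @param nFolds folds (default 5).
#' @param seed RNG seed governing folds and forests.
#' @param average \code{"macro"} (unweighted mean of per-class one-vs-rest
#'   AUCs) or \code{"micro"} (all class-probability/indicator pairs pooled).
#' @return list of class \code{"ClassifierReport"}: \code{auc} (pooled macro
#'   ROC AUC), \code{pr_auc}, \code{fold_auc}, \code{per_class_auc},
#'   \code{roc_curves}, \code{pr_curves} (per-class), \code{confusion},
#'   \code{prob} (pooled held-out probabilities), \code{y}.
#' @export
crossValidate <- function(x, y, nTrees = 500, mtry = "default", nFolds = 5,
                          seed = 1, average = c("macro", "micro")) {
    average <- match.arg(average)
    y <- droplevels(as.factor(y))
    if (any(table(y) < nFolds))
        stop("every class needs at least nFolds members; see makeFeatures()")
    fold <- .stratifiedFolds(y, nFolds, seed)
    prob <- matrix(NA_real_, length(y), nlevels(y),
                   dimnames = list(NULL, levels(y)))
    fold_auc <- numeric(nFolds)
    for (f in seq_len(nFolds)) {
        tr <- fold != f
        fit <- .fitForest(x[tr, , drop = FALSE], y[tr], nTrees, mtry,
                          seed + f)
        p <- stats::predict(fit, x[!tr, , drop = FALSE])$predictions
        prob[!tr, colnames(p)] <- p
        fold_auc[f] <- .macroAUC(prob[!tr, , drop = FALSE], y[!tr])
    }
    per_class <- vapply(levels(y), function(cl)
        binaryAUC(prob[, cl], y == cl), 0)
    auc <- if (average == "macro") mean(per_class, na.rm = TRUE) else
        binaryAUC(as.vector(prob),
                  as.vector(outer(y, levels(y), "==")))
    pr_class <- vapply(levels(y), function(cl)
        .prAUC(prob[, cl], y == cl), 0)
    pred <- factor(levels(y)[max.col(prob, ties.method = "first")],
                   levels = levels(y))
    structure(list(
        auc = auc,
        pr_auc = mean(pr_class, na.rm = TRUE),
        fold_auc = fold_auc,
        per_class_auc = per_class,
        per_class_pr_auc = pr_class,
        roc_curves = lapply(stats::setNames(nm = levels(y)), function(cl)
            .rocPoints(prob[, cl], y == cl)),
        pr_curves = lapply(stats::setNames(nm = levels(y)), function(cl) {
            ord <- order(prob[, cl], decreasing = TRUE)
            pos <- (y == cl)[ord]
            data.frame(recall = cumsum(pos) / sum(pos),
                       precision = cumsum(pos) / seq_along(pos))
        }),
        confusion = table(truth = y, predicted = pred),
        prob = prob, y = y,
        nTrees = nTrees, nFolds = nFolds, seed = seed),
        class = "ClassifierReport")
}

#' @exportS3Method base::print
print.ClassifierReport <- function(x, ...) {
    cat("ClassifierReport:", length(x$y), "cells,",
        nlevels(x$y), "classes,", x$nTrees, "trees,",
        x$nFolds, "-fold CV\n", sep = " ")
    cat("  pooled macro ROC AUC:", round(x$auc, 4),
        "  PR AUC:", round(x$pr_auc, 4), "\n")
    cat("  per-fold macro AUC:",
        paste(round(x$fold_auc, 3), collapse = ", "), "\n")
    invisible(x)
}

#' Learning curve over training-set fractions
#'
#' A stratified 80/20 split is held fixed; for each requested fraction the
#' training portion is subsampled (stratified), a forest is fitted, and the
#' macro AUC is measured on the untouched test portion, repeated
#' \code{nRepeats} times. Fractions at which a class vanishes from the
#' subsample are reported as NA.
#'
#' @inheritParams crossValidate
#' @param fractions ascending training fractions in (0, 1] (default
#'   0.25/0.5/0.75/1).
#' @param nRepeats subsampling repeats per fraction (default 3).
#' @return data.frame with \code{fraction}, \code{mean_auc}, \code{sd_auc}.
#' @export
learningCurve <- function(x, y, fractions = c(0.25, 0.5, 0.75, 1),
                          nTrees = 500, mtry = "default", nRepeats = 3,
                          seed = 1) {
    stopifnot(all(fractions > 0), all(fractions <= 1),
              !is.unsorted(fractions))
    y <- droplevels(as.factor(y))
    fold <- .stratifiedFolds(y, 5, seed)        # fold 5 is the test split
    test <- fold == 5
    out <- data.frame(fraction = fractions, mean_auc = NA_real_,
                      sd_auc = NA_real_)
    tr_idx <- which(!test)
    for (i in seq_along(fractions)) {
        fr <- fractions[i]
        aucs <- numeric(0)
        for (r in seq_len(nRepeats)) {
            set.seed(seed + 1000 * i + r)
            sub <- unlist(lapply(levels(y), function(cl) {
                cls <- tr_idx[y[tr_idx] == cl]
                sample(cls, max(1, round(fr * length(cls))))
            }))
            if (nlevels(droplevels(y[sub])) < nlevels(y)) next
            fit <- .fitForest(x[sub, , drop = FALSE], y[sub], nTrees, mtry,
                              seed + 1000 * i + r)
            p <- stats::predict(fit, x[test, , drop = FALSE])$predictions
            aucs <- c(aucs, .macroAUC(p, y[test]))
        }
        if (length(aucs)) {
            out$mean_auc[i] <- mean(aucs)
            out$sd_auc[i] <- if (length(aucs) > 1) stats::sd(aucs) else 0
        }
    }
    out
}

#' Has the learning curve plateaued?
#'
#' @param curve [learningCurve()] output.
#' @param tol AUC gap below which the last step counts as flat (default
#'   0.01).
#' @return logical.
#' @export
plateauReached <- function(curve, tol = 0.01) {
    m <- curve$mean_auc[!is.na(curve$mean_auc)]
    if (length(m) < 2) return(NA)
    abs(m[length(m)] - m[length(m) - 1]) < tol
}
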