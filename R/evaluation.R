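#' Accuracy and per-fold precision/recall
#'
#' Accuracy is the fraction of test items assigned their true fold.
#' Precision and recall are computed separately per fold — precision is
#' true positives over true plus false positives, recall is true
#' positives over true positives plus false negatives — and averaged
#' unweighted across folds. Folds with a zero denominator for a metric
#' (never predicted, or never true) are excluded from that metric's
#' average, and the exclusion counts are reported. A rejected item
#' (\code{NO_CLASSIFICATION}) is a false negative for its true fold and
#' a true positive for nothing.
#'
#' @param predictions character vector of predicted folds, possibly
#'   containing \code{"NO_CLASSIFICATION"}, or a classification result
#'   data.frame with a \code{predicted_fold} column.
#' @param truths character vector of true folds, aligned with
#'   \code{predictions}.
#' @param fold_universe optional character vector of folds to tabulate;
#'   defaults to the union of truths and (non-sentinel) predictions.
#'   Folds that never occur are excluded from both averages by the
#'   zero-denominator rule, so widening the universe never changes the
#'   macro values.
#' @return list with \code{accuracy}, \code{macro_precision},
#'   \code{macro_recall}, \code{n}, \code{n_excluded_precision},
#'   \code{n_excluded_recall} and \code{per_fold} (a data.frame with
#'   columns \code{fold}, \code{n_true}, \code{n_predicted}, \code{tp},
#'   \code{precision}, \code{recall}, \code{included_in_P_avg},
#'   \code{included_in_R_avg}).
#' @export
evaluateFolds <- function(predictions, truths, fold_universe = NULL) {
    if (is.data.frame(predictions)) predictions <- predictions$predicted_fold
    predictions <- as.character(predictions)
    truths <- as.character(truths)
    if (length(predictions) != length(truths))
        .stopf("predictions (%d) and truths (%d) must align",
            length(predictions), length(truths))
    folds <- sort(unique(c(truths,
        setdiff(predictions, "NO_CLASSIFICATION"),
        as.character(fold_universe))))
    tp <- vapply(folds, function(f)
        sum(predictions == f & truths == f), numeric(1))
    nPred <- vapply(folds, function(f) sum(predictions == f), numeric(1))
    nTrue <- vapply(folds, function(f) sum(truths == f), numeric(1))
    prec <- ifelse(nPred > 0, tp / nPred, NA_real_)
    rec <- ifelse(nTrue > 0, tp / nTrue, NA_real_)
    perFold <- data.frame(fold = folds, n_true = nTrue, n_predicted = nPred,
        tp = tp, precision = prec, recall = rec,
        included_in_P_avg = nPred > 0, included_in_R_avg = nTrue > 0,
        stringsAsFactors = FALSE, row.names = NULL)
    list(accuracy = mean(predictions == truths),
        macro_precision = mean(prec[nPred > 0]),
        macro_recall = mean(rec[nTrue > 0]),
        n = length(truths),
        n_excluded_precision = sum(nPred == 0),
        n_excluded_recall = sum(nTrue == 0),
        per_fold = perFold)
}

#' Metrics restricted to orphan folds
#'
#' Orphan folds have exactly one training example; classifying into them
#' is the hardest case for any fold-recognition method. The sub-report
#' restricts the metric definitions of \code{\link{evaluateFolds}} to
#' test items whose true fold is orphan, computed from the same full
#' classification run (not a re-run on a reduced problem).
#'
#' @param predictions,truths as in \code{\link{evaluateFolds}}.
#' @param train_label_counts named integer vector (or table) of training
#'   examples per fold.
#' @return an \code{\link{evaluateFolds}} report restricted to orphan
#'   folds, plus \code{orphan_folds} and \code{empty} (TRUE when no
#'   orphan fold has a test item).
#' @export
orphanSubreport <- function(predictions, truths, train_label_counts) {
    if (is.data.frame(predictions)) predictions <- predictions$predicted_fold
    predictions <- as.character(predictions)
    truths <- as.character(truths)
    counts <- unclass(train_label_counts)
    orphans <- names(counts)[counts == 1L]
    sel <- truths %in% orphans
    if (!any(sel))
        return(list(empty = TRUE, orphan_folds = orphans, n = 0L))
    rep <- evaluateFolds(predictions[sel], truths[sel],
        fold_universe = orphans)
    c(list(empty = FALSE, orphan_folds = orphans), rep)
}

#' k-fold cross-validation in the feature space
#'
#' Randomly partitions the rows of a raw score matrix into \code{k}
#' parts (seeded uniform shuffle, non-stratified by default). For each
#' part, standardization parameters and the classifier are fitted on the
#' remaining rows only — the standardization is refit inside every fold,
#' so no test information leaks into the transform — and the held-out
#' part is predicted. Predictions are pooled across parts and evaluated
#' once.
#'
#' @param matrix a \linkS4class{ScoreMatrix} of raw scores.
#' @param labels fold label per row.
#' @param k number of parts (default 10).
#' @param classifier \code{"nn"}, \code{"svm"} or \code{"combined"}.
#' @param seed integer seed for the partition.
#' @param stratified logical; when \code{TRUE}, folds are spread across
#'   parts so far as their counts allow.
#' @param min_examples large-fold cutoff for the SVM phases.
#' @param distance_threshold optional rejection threshold for
#'   \code{"nn"}.
#' @return list with the pooled \code{\link{evaluateFolds}} report under
#'   \code{report}, plus \code{predictions} (pooled data.frame with
#'   \code{domain_id}, \code{truth}, \code{predicted_fold},
#'   \code{part}) and \code{k}, \code{seed}.
#' @export
crossValidate <- function(matrix, labels, k = 10L,
        classifier = c("nn", "svm", "combined"), seed = 1L,
        stratified = FALSE, min_examples = 10L,
        distance_threshold = NULL) {
    classifier <- match.arg(classifier)
    stopifnot(methods::is(matrix, "ScoreMatrix"))
    labels <- as.character(labels)
    n <- nrow(matrix@scores)
    if (length(labels) != n) .stopf("labels must align with rows")
    k <- as.integer(k)
    if (k < 2L) .stopf("k must be >= 2")
    if (k > n) .stopf("k (%d) exceeds the number of records (%d)", k, n)
    set.seed(seed)
    part <- if (stratified) {
        p <- integer(n)
        for (f in unique(labels)) {
            idx <- sample(which(labels == f))
            p[idx] <- rep_len(sample(k), length(idx))
        }
        p
    } else {
        sample(rep_len(seq_len(k), n))
    }
    pooled <- vector("list", k)
    for (i in seq_len(k)) {
        testIdx <- which(part == i)
        trainIdx <- which(part != i)
        trainRaw <- ScoreMatrix(matrix@scores[trainIdx, , drop = FALSE])
        testRaw <- ScoreMatrix(matrix@scores[testIdx, , drop = FALSE])
        std <- standardizeTrainTest(trainRaw, testRaw)
        pred <- switch(classifier,
            nn = classifyNN(trainNN(std$train, labels[trainIdx]),
                std$test, distance_threshold)$predicted_fold,
            svm = classifySVM(trainSVM(std$train, labels[trainIdx],
                min_examples = min_examples), std$test)$predicted_fold,
            combined = {
                svm <- trainSVM(std$train, labels[trainIdx],
                    min_examples = min_examples)
                smallIdx <- labels[trainIdx] %in% svm@smallFolds
                if (!any(smallIdx))
                    .stopf("combined cross-validation requires at least one small fold in every training part")
                smallFeat <- std$train
                smallFeat@scores <-
                    std$train@scores[smallIdx, , drop = FALSE]
                nnSmall <- trainNN(smallFeat, labels[trainIdx][smallIdx])
                classifyCombined(svm, nnSmall, std$test)$predicted_fold
            })
        pooled[[i]] <- data.frame(
            domain_id = rownames(matrix@scores)[testIdx],
            truth = labels[testIdx], predicted_fold = pred,
            part = i, stringsAsFactors = FALSE)
    }
    pooled <- do.call(rbind, pooled)
    list(report = evaluateFolds(pooled$predicted_fold, pooled$truth),
        predictions = pooled, k = k, seed = seed)
}
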