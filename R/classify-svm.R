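#' Train a one-vs-all linear SVM over large folds
#'
#' Fits one binary linear max-margin classifier per "large" fold (a fold
#' with at least \code{min_examples} training rows) against all other
#' training rows, each with misclassification penalty C = 1/N, N being
#' that fold's number of positive examples. Folds below
#' \code{min_examples} are excluded from the model and reported in the
#' \code{smallFolds} slot (the combined classifier routes them to a
#' nearest-neighbour fallback). Weight vectors and offsets are extracted
#' from the fitted machines so prediction is plain linear algebra.
#'
#' The backend is libsvm (\pkg{e1071}) with a linear kernel, no internal
#' rescaling, and convergence tolerance recorded in the model metadata.
#'
#' @param train a \linkS4class{PessMatrix} of standardized training rows.
#' @param labels fold label per row.
#' @param min_examples minimum positives for a fold to get its own
#'   decision function (default 10).
#' @param tolerance solver convergence tolerance (default 1e-4).
#' @param scale_by_norm logical; when \code{TRUE} (default) confidences
#'   are geometric signed distances, decision values divided by the
#'   weight-vector norm; when \code{FALSE}, raw decision values (for
#'   parity with solvers that report them directly).
#' @return an \linkS4class{SVMModel}.
#' @export
trainSVM <- function(train, labels, min_examples = 10L, tolerance = 1e-4,
        scale_by_norm = TRUE) {
    stopifnot(methods::is(train, "PessMatrix"))
    labels <- as.character(labels)
    X <- train@scores
    if (length(labels) != nrow(X))
        .stopf("labels (%d) must align with training rows (%d)",
            length(labels), nrow(X))
    counts <- table(labels)
    large <- sort(names(counts)[counts >= min_examples])
    small <- sort(names(counts)[counts < min_examples])
    if (!length(large))
        .stopf("no fold has >= %d training examples; use the 1NN classifier alone",
            min_examples)
    if (!length(small) && length(large) == 1L)
        .stopf("one-vs-all needs negative examples: all training rows belong to fold %s",
            large)
    W <- matrix(0, length(large), ncol(X),
        dimnames = list(large, colnames(X)))
    b <- numeric(length(large))
    npos <- integer(length(large))
    for (i in seq_along(large)) {
        f <- large[i]
        y <- factor(ifelse(labels == f, "pos", "neg"),
            levels = c("pos", "neg"))
        n <- sum(y == "pos")
        fit <- e1071::svm(X, y, kernel = "linear", scale = FALSE,
            cost = 1 / n, tolerance = tolerance)
        w <- drop(crossprod(fit$coefs, fit$SV))
        off <- -fit$rho
        # libsvm's decision sign depends on label order; orient so that
        # positives score higher on average than negatives
        dv <- X %*% w + off
        if (mean(dv[y == "pos"]) < mean(dv[y == "neg"])) {
            w <- -w; off <- -off
        }
        W[i, ] <- w
        b[i] <- off
        npos[i] <- n
    }
    methods::new("SVMModel", weights = W, offsets = b, counts = npos,
        cost = 1 / npos, smallFolds = small, templates = colnames(X),
        metadata = list(solver = "libsvm (e1071)", kernel = "linear",
            tolerance = tolerance, min_examples = as.integer(min_examples),
            confidence = if (scale_by_norm) "signed_distance"
                else "decision_value",
            scale_by_norm = scale_by_norm))
}

#' Per-fold signed distances to the SVM hyperplanes
#'
#' @param model an \linkS4class{SVMModel}.
#' @param queries a \linkS4class{PessMatrix} with the model's column
#'   order.
#' @return numeric matrix, one row per query and one column per large
#'   fold (lexicographic order): signed distance to that fold's
#'   hyperplane (or the raw decision value when the model was trained
#'   with \code{scale_by_norm = FALSE}).
#' @export
svmConfidences <- function(model, queries) {
    stopifnot(methods::is(model, "SVMModel"),
        methods::is(queries, "PessMatrix"))
    .assertColumnsMatch(colnames(queries@scores), model@templates, "query")
    dv <- queries@scores %*% t(model@weights) +
        rep(model@offsets, each = nrow(queries@scores))
    if (isTRUE(model@metadata$scale_by_norm)) {
        norms <- sqrt(rowSums(model@weights^2))
        norms[norms == 0] <- 1
        dv <- sweep(dv, 2L, norms, "/")
    }
    dv
}

#' Classify queries with the one-vs-all SVM
#'
#' Each query is assigned the fold whose hyperplane gives the highest
#' signed distance; the confidence may be negative (every decision
#' function votes against), in which case acceptance is the caller's
#' decision — the combined classifier passes such queries to the
#' nearest-neighbour fallback. Confidence ties are broken by
#' lexicographic fold label.
#'
#' @inheritParams svmConfidences
#' @return data.frame with columns \code{domain_id},
#'   \code{predicted_fold} and \code{svm_confidence}.
#' @export
classifySVM <- function(model, queries) {
    conf <- svmConfidences(model, queries)
    # columns are in lexicographic fold order, so the first max wins ties
    best <- apply(conf, 1L, which.max)
    data.frame(domain_id = rownames(queries@scores),
        predicted_fold = colnames(conf)[best],
        svm_confidence = conf[cbind(seq_len(nrow(conf)), best)],
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-phase combined SVM + nearest-neighbour classification
#'
#' Phase 1: every query goes to the one-vs-all SVM over large folds; any
#' query with a strictly positive best confidence takes that fold
#' (\code{phase = "svm"}). Phase 2: the remaining queries are passed to a
#' nearest-neighbour model trained only on the small-fold rows (the
#' "other" pool) and take their nearest neighbour's fold
#' (\code{phase = "nn"}). Every query is labelled.
#'
#' @param svm an \linkS4class{SVMModel}.
#' @param nn_small an \linkS4class{NNModel} trained only on folds absent
#'   from \code{svm} (overlap is a configuration error).
#' @param queries a \linkS4class{PessMatrix}.
#' @return a data.frame in the \code{\link{classifyNN}} result format;
#'   \code{svm_confidence} carries each query's best signed distance,
#'   \code{nn_distance} is \code{NA} for queries settled in phase 1.
#' @export
classifyCombined <- function(svm, nn_small, queries) {
    stopifnot(methods::is(svm, "SVMModel"), methods::is(nn_small, "NNModel"))
    overlap <- intersect(rownames(svm@weights), unique(nn_small@labels))
    if (length(overlap))
        .stopf("configuration error: fold(s) present in both the SVM and the small-fold 1NN model: %s",
            paste(overlap, collapse = ", "))
    conf <- svmConfidences(svm, queries)
    best <- apply(conf, 1L, which.max)
    bestConf <- conf[cbind(seq_len(nrow(conf)), best)]
    out <- data.frame(domain_id = rownames(queries@scores),
        predicted_fold = colnames(conf)[best],
        nn_distance = NA_real_, svm_confidence = bestConf,
        phase = "svm", stringsAsFactors = FALSE, row.names = NULL)
    fallback <- which(!(bestConf > 0))
    if (length(fallback)) {
        qs <- queries
        qs@scores <- queries@scores[fallback, , drop = FALSE]
        nn <- classifyNN(nn_small, qs)
        out$predicted_fold[fallback] <- nn$predicted_fold
        out$nn_distance[fallback] <- nn$nn_distance
        out$phase[fallback] <- "nn"
    }
    out
}
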