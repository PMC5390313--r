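#' Train a first-nearest-neighbour fold classifier
#'
#' A lazy classifier: stores the standardized training coordinates and
#' labels verbatim. Because nothing is fitted, adding new training data
#' needs no retraining (see \code{\link{appendTraining}}) — the property
#' that lets the model grow with every new fold representative.
#'
#' @param train a \linkS4class{PessMatrix} of standardized training rows.
#' @param labels fold label per training row (character, or anything
#'   coercible).
#' @param params optional \linkS4class{StandardizationParams} used to
#'   build \code{train}, kept for end-to-end classification of raw
#'   queries.
#' @return an \linkS4class{NNModel}.
#' @export
trainNN <- function(train, labels, params = NULL) {
    stopifnot(methods::is(train, "PessMatrix"))
    labels <- as.character(labels)
    if (length(labels) != nrow(train@scores))
        .stopf("labels (%d) must align with training rows (%d)",
            length(labels), nrow(train@scores))
    if (nrow(train@scores) == 0L) .stopf("empty training set")
    methods::new("NNModel", features = train, labels = labels,
        params = params)
}

#' Append training rows to a nearest-neighbour model
#'
#' @param model an \linkS4class{NNModel}.
#' @param rows a \linkS4class{PessMatrix} with the model's column order.
#' @param labels fold label per appended row.
#' @return the extended model; existing rows are untouched.
#' @export
appendTraining <- function(model, rows, labels) {
    stopifnot(methods::is(model, "NNModel"), methods::is(rows, "PessMatrix"))
    .assertColumnsMatch(colnames(rows@scores),
        colnames(model@features@scores), "appended rows")
    labels <- as.character(labels)
    if (length(labels) != nrow(rows@scores))
        .stopf("labels must align with appended rows")
    feat <- model@features
    feat@scores <- rbind(model@features@scores, rows@scores)
    methods::new("NNModel", features = feat,
        labels = c(model@labels, labels), params = model@params)
}

#' Classify queries by the nearest training neighbour
#'
#' Each query receives the fold of its Euclidean-nearest training row
#' (distances in the standardized feature space). With a
#' \code{distance_threshold}, only queries whose nearest neighbour is
#' strictly closer than the threshold are classified; the rest are
#' rejected to \code{NO_CLASSIFICATION} (the boundary case
#' \code{distance == threshold} is rejected). Distance ties are broken
#' by the lowest training row index.
#'
#' @param model an \linkS4class{NNModel}.
#' @param queries a \linkS4class{PessMatrix} with the model's column
#'   order.
#' @param distance_threshold positive numeric or \code{NULL} (no
#'   rejection).
#' @return a data.frame with columns \code{domain_id},
#'   \code{predicted_fold} (\code{"NO_CLASSIFICATION"} when rejected),
#'   \code{nn_distance}, \code{svm_confidence} (\code{NA} here) and
#'   \code{phase} (\code{"nn"} or \code{"rejected"}).
#' @export
classifyNN <- function(model, queries, distance_threshold = NULL) {
    stopifnot(methods::is(model, "NNModel"), methods::is(queries, "PessMatrix"))
    .assertColumnsMatch(colnames(queries@scores),
        colnames(model@features@scores), "query")
    D <- .crossDist(queries@scores, model@features@scores)
    idx <- .rowArgmin(D)
    nnDist <- D[cbind(seq_len(nrow(D)), idx)]
    fold <- model@labels[idx]
    phase <- rep("nn", length(fold))
    if (!is.null(distance_threshold)) {
        stopifnot(is.numeric(distance_threshold), distance_threshold > 0)
        rej <- nnDist >= distance_threshold     # classify iff strictly closer
        fold[rej] <- "NO_CLASSIFICATION"
        phase[rej] <- "rejected"
    }
    data.frame(domain_id = rownames(queries@scores),
        predicted_fold = fold, nn_distance = nnDist,
        svm_confidence = NA_real_, phase = phase,
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify raw queries end to end with a nearest-neighbour model
#'
#' Standardizes raw scores with the model's stored training parameters,
#' then calls \code{\link{classifyNN}}.
#'
#' @param model an \linkS4class{NNModel} carrying standardization
#'   parameters.
#' @param raw a \linkS4class{ScoreMatrix} of raw query scores.
#' @param distance_threshold as in \code{\link{classifyNN}}.
#' @return see \code{\link{classifyNN}}.
#' @export
classifyRawNN <- function(model, raw, distance_threshold = NULL) {
    if (is.null(model@params))
        .stopf("model carries no standardization parameters; standardize queries yourself and use classifyNN()")
    q <- applyStandardization(raw, model@params)
    classifyNN(model, q, distance_threshold)
}
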